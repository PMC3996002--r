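test_that("FG and memoized engines agree with the plain table cell by cell", {
  expect_identical(maxPairs(fgFold(rnaSequence("ACGU"), q = 2)), 2)
  for (cfg in list(c(16L, 2L), c(50L, 3L), c(50L, 5L), c(64L, 3L))) {
    n <- cfg[1L]; q <- cfg[2L]
    sq <- randomRnaSequence(n, 3L)
    ref <- scoreMatrix(twoVectorFold(sq, q))
    expect_identical(scoreMatrix(fgFold(sq, q)), ref)
    expect_identical(scoreMatrix(partialMemoFold(sq, q)), ref)
    expect_identical(scoreMatrix(fullMemoFold(sq, q)), ref)
  }
})

test_that("FG tables one expansion per completed row group, even repeated", {
  for (cfg in list(c(20L, 2L), c(64L, 3L), c(30L, 4L))) {
    n <- cfg[1L]; q <- cfg[2L]
    fr <- fgFold(randomRnaSequence(n, 5L), q)
    st <- opStats(fr)
    gmax <- (n + 1L) %/% q - 1L     # groups with all q columns inside 1..n
    expected <- sum(vapply(seq_len(max(gmax, 0L)), function(g) g * q, numeric(1)))
    expect_identical(st$completedRowGroups, expected)
    expect_identical(st$fgEntries, expected * 2^q)
    # tabled value minus the group-initial cell reproduces the pair maximum
    D <- fr@score
    for (g in seq_len(max(gmax, 0L))) for (i in c(1L, g * q)) {
      hcells <- D[i, (g * q + 1L):(g * q + q)]
      h <- encodeHorizontal(hcells)
      for (v in c(0L, 2L)) {
        orc <- groupCombinationOracle(decodeHorizontal(0, h$code, q),
                                      decodeVertical(0, v, q))
        expect_identical(fr@tables$fgVal[i, g + 1L, v + 1L] - h$initial,
                         orc$max)
        expect_identical(fr@tables$fgArg[i, g + 1L, v + 1L], orc$argmax)
      }
    }
  }
})

test_that("partial memoization expands each new horizontal code exactly once", {
  # an all-A sequence has a constant zero table: one distinct h code
  allA <- rnaSequence(strrep("A", 32L))
  fr <- partialMemoFold(allA, q = 4)
  expect_identical(opStats(fr)$memoEntries, 16)
  expect_identical(opStats(fr)$distinctHCodes, 1L)

  for (seed in 1:5) {
    sq <- randomRnaSequence(64, 20L + seed)
    st <- opStats(partialMemoFold(sq, 3))
    expect_identical(st$memoEntries, st$distinctHCodes * 2^3)
    expect_lte(st$memoEntries, 2^6)
  }
})

test_that("complete memoization stores exactly the queried pairs", {
  short <- randomRnaSequence(5, 2)
  expect_identical(opStats(fullMemoFold(short, q = 8))$memoEntries, 0)

  for (seed in 1:5) {
    sq <- randomRnaSequence(64, 30L + seed)
    full <- opStats(fullMemoFold(sq, 3))
    part <- opStats(partialMemoFold(sq, 3))
    expect_lte(full$memoEntries, part$memoEntries)
    expect_lte(part$memoEntries, 2^6)
    expect_lte(full$memoEntries, full$tableLookups)
  }
})

test_that("memoized entries equal the group-combination oracle", {
  q <- 3L
  for (engine in list(partialMemoFold, fullMemoFold)) {
    fr <- engine(randomRnaSequence(50, 8), q)
    filled <- which(!is.na(fr@tables$memoMax))
    set.seed(1)
    for (idx in sample(filled, min(200L, length(filled)))) {
      h <- (idx - 1L) %/% 2L^q
      v <- (idx - 1L) %% 2L^q
      orc <- groupCombinationOracle(decodeHorizontal(0, h, q),
                                    decodeVertical(0, v, q))
      expect_identical(fr@tables$memoMax[idx], orc$max)
      expect_identical(fr@tables$memoArg[idx], orc$argmax)
    }
  }
})

test_that("variant engines produce valid optimal tracebacks", {
  for (seed in 1:5) {
    sq <- randomRnaSequence(40, 90L + seed)
    for (engine in list(fgFold, partialMemoFold, fullMemoFold))
      expectValidWitness(engine(sq, 3), sq)
  }
})
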