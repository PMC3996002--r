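test_that("difference-vector codec encodes the definitional examples", {
  h <- encodeHorizontal(c(2, 2, 3, 3))
  expect_identical(h$initial, 2)
  expect_identical(h$code, 4L)            # v = (0,0,1,0)
  expect_identical(encodeHorizontal(c(5, 5, 5, 5))$code, 0L)
  expect_identical(encodeHorizontal(c(0, 1, 2, 3))$code, 14L)  # v = (0,1,1,1)

  v <- encodeVertical(c(3, 3, 2, 2))
  expect_identical(v$code, 4L)            # vbar = (0,0,-1,0)
  expect_identical(encodeVertical(c(4, 4, 4, 4))$code, 0L)
  expect_identical(encodeVertical(c(3, 2, 1, 0))$code, 14L)

  expect_error(encodeHorizontal(c(0, 2)), "\\{0,1\\}")
  expect_error(encodeHorizontal(c(1, 0)), "\\{0,1\\}")
  expect_error(encodeVertical(c(0, 1)), "\\{0,-1\\}")
})

test_that("codec round-trips every reachable monotone run exhaustively", {
  for (q in 1:8) {
    for (code in as.integer(seq(0L, 2L^q - 1L, by = 2L))) {  # bit 0 clear
      cells <- decodeHorizontal(5, code, q)
      enc <- encodeHorizontal(cells)
      expect_identical(enc$initial, 5)
      expect_identical(enc$code, code)
      cellsV <- decodeVertical(5, code, q)
      encV <- encodeVertical(cellsV)
      expect_identical(encV$code, code)
      expect_identical(decodeVertical(encV$initial, encV$code, q), cellsV)
    }
  }
})

test_that("preprocessing table matches the oracle entry by entry", {
  t1 <- buildPrecompTable(1)
  expect_identical(precompLookup(t1, 0L, 0L), list(max = 0, argmax = 0L))

  t3 <- buildPrecompTable(3)
  # v = (0,1,1) -> code 6; vbar = (0,0,-1) -> code 4
  expect_identical(precompLookup(t3, 6L, 4L), list(max = 1, argmax = 1L))

  t4 <- buildPrecompTable(4)
  for (h in seq(0L, 15L, by = 2L)) for (v in seq(0L, 15L, by = 2L)) {
    orc <- groupCombinationOracle(decodeHorizontal(0, h, 4L),
                                  decodeVertical(0, v, 4L))
    expect_identical(precompLookup(t4, h, v), orc)
  }

  expect_error(buildPrecompTable(0), "1..12")
  expect_error(buildPrecompTable(13), "1..12")
  expect_error(precompLookup(t4, 16L, 0L), "out of range")
})

test_that("two-vector tables equal the plain engine cell by cell", {
  expect_identical(maxPairs(twoVectorFold(rnaSequence("GGGAAACCC"), q = 2)), 3)
  for (cfg in list(c(10L, 3L), c(33L, 2L), c(33L, 8L), c(64L, 4L),
                   c(20L, 1L), c(5L, 8L))) {
    n <- cfg[1L]; q <- cfg[2L]
    for (seed in 1:3) {
      sq <- randomRnaSequence(n, 40L + seed)
      expect_identical(scoreMatrix(twoVectorFold(sq, q)),
                       scoreMatrix(nussinovFold(sq)))
    }
  }
})

test_that("sequences shorter than the group width use the pure residual path", {
  sq <- randomRnaSequence(5, 11)
  fr <- twoVectorFold(sq, q = 8)
  expect_identical(opStats(fr)$tableLookups, 0)
  expect_identical(scoreMatrix(fr), scoreMatrix(nussinovFold(sq)))
})

test_that("grouped work satisfies the empirical speedup bound", {
  for (cfg in list(c(64L, 2L), c(100L, 4L), c(100L, 8L), c(257L, 8L))) {
    n <- cfg[1L]; q <- cfg[2L]
    sq <- randomRnaSequence(n, n + q)
    st <- opStats(twoVectorFold(sq, q))
    nussCand <- n * (n - 1) * (n + 1) / 6
    expect_lte(st$candidateEvaluations, nussCand / q + 2 * q * n^2)
    expect_lte(st$candidateEvaluations + q * st$tableLookups, nussCand)
  }
})

test_that("two-vector traceback goes through table-resolved splits correctly", {
  for (seed in 1:8) {
    sq <- randomRnaSequence(33, 70L + seed)
    expectValidWitness(twoVectorFold(sq, 4), sq)
    expectValidWitness(twoVectorFold(sq, 2), sq)
  }
})
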