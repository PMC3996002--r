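test_that("plain engine reproduces the canonical examples", {
  expect_identical(maxPairs(nussinovFold(rnaSequence("AAAA"))), 0)
  expect_identical(maxPairs(nussinovFold(rnaSequence("ACGU"))), 2)
  expect_identical(maxPairs(nussinovFold(rnaSequence("GGGAAACCC"))), 3)
})

test_that("every cell satisfies the recurrence locally", {
  sq <- randomRnaSequence(40, 7)
  fr <- nussinovFold(sq)
  D <- fr@score                       # D[i, j+1] layout
  s <- strsplit(seqBases(sq), "")[[1L]]
  rule <- pairingRule()
  n <- length(sq)
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    ks <- (i + 1L):j
    split <- max(D[i, ks] + D[ks, j + 1L])
    case1 <- pairScore(s[i], s[j], rule) + D[i + 1L, j]
    expect_identical(D[i, j + 1L], max(case1, split))
  }
})

test_that("tables are monotone with unit steps along rows and columns", {
  for (cfg in list(c(16L, 1L), c(64L, 2L), c(256L, 3L))) {
    D <- scoreMatrix(nussinovFold(randomRnaSequence(cfg[1L], cfg[2L])))
    expect_identical(monotoneViolations(D), 0L)
    expect_true(all(D >= 0))
    n <- cfg[1L]
    ij <- which(upper.tri(D, diag = TRUE), arr.ind = TRUE)
    expect_true(all(D[ij] <= (ij[, 2L] - ij[, 1L] + 1L) %/% 2L))
  }
})

test_that("split-term count matches the closed form n(n-1)(n+1)/6", {
  for (n in c(1L, 2L, 3L, 7L, 17L, 64L)) {
    st <- opStats(nussinovFold(randomRnaSequence(n, n)))
    expect_identical(st$candidateEvaluations, n * (n - 1) * (n + 1) / 6)
    expect_identical(st$tableLookups, 0)
  }
})

test_that("engine matches the enumeration oracle on small sequences", {
  for (s in enumerateSequences(4L)) {
    sq <- rnaSequence(s)
    expect_identical(maxPairs(nussinovFold(sq)),
                     bruteForceFold(sq)$maxPairs)
  }
  for (seed in 1:25) {
    sq <- randomRnaSequence(7L + seed %% 6L, 300L + seed)
    expect_identical(maxPairs(nussinovFold(sq)),
                     bruteForceFold(sq)$maxPairs)
  }
})

test_that("minimum loop length restricts case 1 correctly", {
  sq <- rnaSequence("ACGU")
  expect_identical(maxPairs(nussinovFold(sq, pairingRule(minLoop = 1L))), 1)
  expect_identical(maxPairs(nussinovFold(sq, pairingRule(minLoop = 3L))), 0)
  for (seed in 1:10) {
    sq <- randomRnaSequence(9, 800L + seed)
    rule <- pairingRule(minLoop = 3L)
    expect_identical(maxPairs(nussinovFold(sq, rule)),
                     bruteForceFold(sq, rule)$maxPairs)
  }
})

test_that("traceback recovers valid optimal structures", {
  fr <- nussinovFold(rnaSequence("ACGU"))
  expect_identical(nrow(tracebackFold(fr, 2, 2)@pairs), 0L)
  st <- tracebackFold(fr)
  expect_identical(nrow(st@pairs), 2L)
  expect_true(isTRUE(checkStructure(st, rnaSequence("ACGU"))))

  gcau <- tracebackFold(nussinovFold(rnaSequence("GCAU")))
  expect_identical(gcau@pairs[order(gcau@pairs[, 1L]), ],
                   matrix(c(1L, 2L, 3L, 4L), 2L, byrow = TRUE))

  expect_error(tracebackFold(fr, 0, 4), "out of bounds")
  expect_error(tracebackFold(fr, 1, 9), "out of bounds")

  for (seed in 1:10) {
    sq <- randomRnaSequence(30, 600L + seed)
    expectValidWitness(nussinovFold(sq), sq)
  }
})

test_that("dot-bracket rendering is definitional and rejects crossings", {
  empty <- new("SecondaryStructure", pairs = matrix(integer(0), 0, 2), n = 3L)
  expect_identical(dotBracket(empty), "...")
  nested <- new("SecondaryStructure",
                pairs = matrix(c(1L, 4L, 2L, 3L), 2L, byrow = TRUE), n = 4L)
  expect_identical(dotBracket(nested), "(())")
  adjacent <- new("SecondaryStructure",
                  pairs = matrix(c(1L, 2L, 3L, 4L), 2L, byrow = TRUE), n = 4L)
  expect_identical(dotBracket(adjacent), "()()")
  expect_error(
    new("SecondaryStructure",
        pairs = matrix(c(1L, 3L, 2L, 4L), 2L, byrow = TRUE), n = 4L),
    "crosses")
})

test_that("CT output follows the connect-table column layout", {
  seq <- rnaSequence("AU", name = "tiny")
  st <- new("SecondaryStructure", pairs = matrix(c(1L, 2L), 1L), n = 2L)
  f <- withr::local_tempfile(fileext = ".ct")
  writeCT(st, seq, f)
  lines <- readLines(f)
  expect_identical(lines[1L], "2 tiny")
  expect_identical(lines[2L], "1 A 0 2 2 1")
  expect_identical(lines[3L], "2 U 1 3 1 2")

  st0 <- new("SecondaryStructure", pairs = matrix(integer(0), 0, 2), n = 2L)
  writeCT(st0, seq, f)
  expect_identical(readLines(f)[2L], "1 A 0 2 0 1")
})
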