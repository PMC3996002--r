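# Shared fixtures for the folding test suite. Everything is generated in
# code under fixed seeds; the expensive six-engine agreement grid is
# computed once per session and shared by the agreement, monotonicity and
# accounting tests.

ENGINES <- c("nussinov", "two-vector", "fg", "partial-memo", "full-memo",
             "tiled")

foldAllEngines <- function(seq, q, shuffleSeed = 1L) {
  out <- lapply(ENGINES, function(a)
    foldSequence(seq, algorithm = a, q = q, shuffleSeed = shuffleSeed))
  names(out) <- ENGINES
  out
}

# all 4^n sequences of length n as character strings
enumerateSequences <- function(n) {
  g <- do.call(expand.grid,
               c(rep(list(c("A", "C", "G", "U")), n),
                 stringsAsFactors = FALSE))
  apply(as.matrix(g), 1L, paste, collapse = "")
}

# monotonicity of a standard-form score matrix: row steps in {0,1} going
# right, column steps in {0,-1} going down (checked on the upper triangle)
monotoneViolations <- function(D) {
  n <- nrow(D)
  bad <- 0L
  for (i in seq_len(n - 1L)) {
    if (i + 1L <= n) {
      dr <- diff(D[i, i:n])
      bad <- bad + sum(dr != 0 & dr != 1)
    }
    js <- (i + 1L):n
    dc <- D[cbind(i, js)] - D[cbind(pmin(i + 1L, js), js)]
    bad <- bad + sum(dc != 0 & dc != 1)
  }
  bad
}

# the six-engine agreement grid: 50 seeded sequences cycling through
# n in {16, 50, 100, 257} and q in {2, 3, 4, 8}
agreementGridSpec <- function() {
  ns <- c(16L, 50L, 100L, 257L)
  qs <- c(2L, 3L, 4L, 8L)
  lapply(seq_len(50L), function(i)
    list(n = ns[(i - 1L) %% 4L + 1L],
         q = qs[((i - 1L) %/% 4L) %% 4L + 1L],
         seed = 1000L + i))
}

.gridCache <- new.env(parent = emptyenv())

agreementGridRuns <- function() {
  if (!exists("runs", envir = .gridCache)) {
    runs <- lapply(agreementGridSpec(), function(cfg) {
      seq <- randomRnaSequence(cfg$n, cfg$seed)
      cfg$results <- foldAllEngines(seq, cfg$q, shuffleSeed = cfg$seed)
      cfg
    })
    assign("runs", runs, envir = .gridCache)
  }
  get("runs", envir = .gridCache)
}

expectValidWitness <- function(fr, seq, rule = pairingRule()) {
  st <- tracebackFold(fr)
  expect_identical(nrow(st@pairs), as.integer(maxPairs(fr)))
  expect_true(isTRUE(checkStructure(st, seq, rule)))
}
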