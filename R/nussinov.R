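# Reference cubic-time dynamic program, traceback, and structure writers.
#
# Score storage convention used by every engine: Dm is (n+1) x (n+1) with
# Dm[i, j+1] = D(i, j), so the base cases D(i, i-1) = 0 sit on the storage
# diagonal and the split max over k in i+1..j reads
#   Dm[i, (i+1):j] + Dm[(i+1):j, j+1].

TRACE_LEAF <- 0L
TRACE_PAIRED <- 1L
TRACE_SPLIT <- 2L

foldInputs <- function(seq, rule) {
  stopifnot(is(seq, "RnaSequence"), is(rule, "PairingRule"))
  list(s = seqCodes(seq), n = length(seq), pmat = rule@pairs,
       minLoop = rule@minLoop)
}

newFoldResult <- function(algorithm, seq, rule, q, Dm, traceOp, traceK,
                          stats, tables = list()) {
  new("FoldResult", algorithm = algorithm, seq = seq, rule = rule,
      q = as.integer(q), score = Dm, traceOp = traceOp, traceK = traceK,
      stats = stats, tables = tables)
}

#' Nussinov folding by the plain cubic recurrence
#'
#' Fills the upper-triangular table D column by column with
#' \deqn{D(i,j) = \max\{\, b(S_i, S_j) + D(i+1, j-1),\ \max_{i<k\le j} D(i,k-1) + D(k,j) \,\}}
#' where b is the pairing predicate. D(1, n) is the maximum number of
#' non-crossing complementary pairs. Decisions are recorded per cell so that
#' [tracebackFold()] can recover an optimal structure: pairing the two ends
#' is preferred when it ties the best split, and among tied splits the
#' smallest k is recorded.
#'
#' The counter \code{candidateEvaluations} is incremented for every split
#' term evaluated, hence equals \eqn{\sum_{i<j} (j-i) = n(n-1)(n+1)/6}
#' exactly for this engine.
#'
#' @param seq an [RnaSequence-class]
#' @param rule a [PairingRule-class]
#' @return a [FoldResult-class]
#' @examples
#' maxPairs(nussinovFold(rnaSequence("GGGAAACCC")))  # 3
#' @export
nussinovFold <- function(seq, rule = pairingRule()) {
  inp <- foldInputs(seq, rule)
  n <- inp$n; s <- inp$s; pmat <- inp$pmat; minLoop <- inp$minLoop
  Dm <- matrix(0, n + 1L, n + 1L)
  traceOp <- matrix(TRACE_LEAF, n, n)
  traceK <- matrix(0L, n, n)
  cand <- 0
  if (n >= 2L) {
    for (j in 2:n) {
      jj <- j + 1L
      for (i in (j - 1L):1L) {
        ks <- (i + 1L):j
        c2 <- Dm[i, ks] + Dm[ks, jj]
        cand <- cand + length(ks)
        w <- which.max(c2)
        best <- c2[w]; op <- TRACE_SPLIT; bk <- ks[w]
        if (pmat[s[i], s[j]] == 1L && (j - i - 1L) >= minLoop) {
          v1 <- 1 + Dm[i + 1L, j]
          if (v1 >= best) { best <- v1; op <- TRACE_PAIRED; bk <- 0L }
        }
        Dm[i, jj] <- best
        traceOp[i, j] <- op
        traceK[i, j] <- bk
      }
    }
  }
  newFoldResult("nussinov", seq, rule, 1L, Dm, traceOp, traceK,
                stats = list(candidateEvaluations = cand, tableLookups = 0))
}

#' @rdname maxPairs
#' @export
setMethod("maxPairs", "FoldResult", function(x) {
  n <- length(x@seq)
  x@score[1L, n + 1L]
})

#' @rdname scoreMatrix
#' @export
setMethod("scoreMatrix", "FoldResult", function(x) {
  n <- length(x@seq)
  x@score[seq_len(n), 1L + seq_len(n), drop = FALSE]
})

#' @rdname opStats
#' @export
setMethod("opStats", "FoldResult", function(x) x@stats)

#' @rdname tracebackFold
#' @export
setMethod("tracebackFold", "FoldResult", function(x, i = 1L, j = NULL) {
  n <- length(x@seq)
  if (is.null(j)) j <- n
  i <- as.integer(i); j <- as.integer(j)
  if (i < 1L || j > n || i > j + 1L)
    stop(sprintf("traceback range (%d,%d) out of bounds for n = %d", i, j, n))
  pairs <- matrix(integer(0L), 0L, 2L)
  stack <- list(c(i, j))
  while (length(stack) > 0L) {
    cell <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    ci <- cell[1L]; cj <- cell[2L]
    if (cj <= ci) next
    op <- x@traceOp[ci, cj]
    if (op == TRACE_PAIRED) {
      pairs <- rbind(pairs, c(ci, cj))
      stack[[length(stack) + 1L]] <- c(ci + 1L, cj - 1L)
    } else if (op == TRACE_SPLIT) {
      k <- x@traceK[ci, cj]
      stack[[length(stack) + 1L]] <- c(ci, k - 1L)
      stack[[length(stack) + 1L]] <- c(k, cj)
    }
  }
  storage.mode(pairs) <- "integer"
  new("SecondaryStructure", pairs = pairs, n = n)
})

#' @rdname dotBracket
#' @export
setMethod("dotBracket", "SecondaryStructure", function(x) {
  ch <- rep(".", x@n)
  if (nrow(x@pairs) > 0L) {
    ch[x@pairs[, 1L]] <- "("
    ch[x@pairs[, 2L]] <- ")"
  }
  paste(ch, collapse = "")
})

#' @rdname writeCT
#' @export
setMethod("writeCT", "SecondaryStructure", function(x, seq, path) {
  stopifnot(is(seq, "RnaSequence"))
  n <- length(seq)
  if (x@n != n) stop("structure length does not match sequence length")
  partner <- integer(n)
  if (nrow(x@pairs) > 0L) {
    partner[x@pairs[, 1L]] <- x@pairs[, 2L]
    partner[x@pairs[, 2L]] <- x@pairs[, 1L]
  }
  bases <- strsplit(seq@bases, "", fixed = TRUE)[[1L]]
  idx <- seq_len(n)
  lines <- c(sprintf("%d %s", n, seq@name),
             sprintf("%d %s %d %d %d %d", idx, bases, idx - 1L, idx + 1L,
                     partner, idx))
  writeLines(lines, path)
  invisible(path)
})

#' Check a structure against a sequence and rule
#'
#' Verifies (beyond the class validity, which already enforces index bounds,
#' disjointness and non-crossing) that every pair is complementary under the
#' rule and respects the minimum loop length.
#'
#' @param x a [SecondaryStructure-class]
#' @param seq the [RnaSequence-class]
#' @param rule a [PairingRule-class]
#' @return TRUE, or a character message describing the first violation
#' @export
checkStructure <- function(x, seq, rule = pairingRule()) {
  v <- validObject(x, test = TRUE)
  if (!isTRUE(v)) return(v)
  if (x@n != length(seq)) return("structure and sequence lengths differ")
  s <- seqCodes(seq)
  p <- x@pairs
  for (r in seq_len(nrow(p))) {
    i <- p[r, 1L]; j <- p[r, 2L]
    if (rule@pairs[s[i], s[j]] != 1L)
      return(sprintf("pair (%d,%d) is not complementary", i, j))
    if (j - i - 1L < rule@minLoop)
      return(sprintf("pair (%d,%d) violates minLoop = %d", i, j, rule@minLoop))
  }
  TRUE
}

setMethod("show", "FoldResult", function(object) {
  st <- object@stats
  cat(sprintf("FoldResult [%s] '%s': n = %d, q = %d, maxPairs = %d\n",
              object@algorithm, object@seq@name, length(object@seq),
              object@q, as.integer(maxPairs(object))))
  cat(sprintf("  candidateEvaluations = %.0f, tableLookups = %.0f\n",
              st$candidateEvaluations, st$tableLookups))
})

setMethod("show", "SecondaryStructure", function(object) {
  cat(sprintf("SecondaryStructure: %d pairs on n = %d\n",
              nrow(object@pairs), object@n))
  if (object@n <= 120L) cat(" ", dotBracket(object), "\n")
})
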