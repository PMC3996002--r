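# Independent brute-force references. Both operations here deliberately
# avoid the code paths of the DP engines: the fold oracle enumerates over
# the interval decomposition "position i is unpaired, or i pairs with some
# admissible k", and the group-combination oracle is a direct scan.

#' Exhaustive folding oracle for tiny sequences
#'
#' Computes the exact maximum number of non-crossing complementary pairs by
#' recursive enumeration (memoized on intervals), together with a witness
#' structure. The recursion considers "i unpaired" before "i paired with the
#' smallest admissible k", so the witness is deterministic. This is an
#' independent reference for the DP engines, not a reuse of them.
#'
#' @param seq an [RnaSequence-class] with length at most \code{cap}
#' @param rule a [PairingRule-class]
#' @param cap guard on the enumeration size (default 16)
#' @return list with \code{maxPairs} and \code{structure}
#'   (a [SecondaryStructure-class])
#' @examples
#' bruteForceFold(rnaSequence("ACGU"))$maxPairs   # 2
#' @export
bruteForceFold <- function(seq, rule = pairingRule(), cap = 16L) {
  n <- length(seq)
  if (n > cap)
    stop(sprintf("n = %d exceeds the enumeration cap (%d); use a DP engine",
                 n, cap))
  s <- seqCodes(seq)
  pmat <- rule@pairs
  minLoop <- rule@minLoop
  M <- matrix(NA_real_, n + 1L, n + 1L)  # M[i, j+1] memo; NA = not computed

  rec <- function(i, j) {
    if (j <= i) return(0)
    if (!is.na(M[i, j + 1L])) return(M[i, j + 1L])
    best <- rec(i + 1L, j)               # i unpaired, preferred on ties
    for (k in (i + 1L):j) {
      if (pmat[s[i], s[k]] == 1L && (k - i - 1L) >= minLoop) {
        v <- 1 + rec(i + 1L, k - 1L) + rec(k + 1L, j)
        if (v > best) best <- v
      }
    }
    M[i, j + 1L] <<- best
    best
  }

  witness <- function(i, j) {
    if (j <= i) return(NULL)
    target <- rec(i, j)
    if (rec(i + 1L, j) == target) return(witness(i + 1L, j))
    for (k in (i + 1L):j) {
      if (pmat[s[i], s[k]] == 1L && (k - i - 1L) >= minLoop &&
          1 + rec(i + 1L, k - 1L) + rec(k + 1L, j) == target) {
        return(rbind(c(i, k), witness(i + 1L, k - 1L), witness(k + 1L, j)))
      }
    }
    stop("internal error: witness reconstruction failed") # nocov
  }

  best <- rec(1L, n)
  w <- witness(1L, n)
  if (is.null(w)) w <- matrix(integer(0L), 0L, 2L)
  storage.mode(w) <- "integer"
  list(maxPairs = best,
       structure = new("SecondaryStructure", pairs = w, n = n))
}

#' Direct group-combination maximum
#'
#' Given two running-total vectors V and Vbar of equal length q, returns
#' \code{max_k V[k] + Vbar[k]} and the smallest 0-based k attaining it, by a
#' plain linear scan. This is the quantity every Four-Russians table entry
#' must reproduce; the function is the independent oracle used to verify
#' [buildPrecompTable()] and the memoized tables.
#'
#' @param V,Vbar numeric vectors of equal length q >= 1
#' @return list with \code{max} and \code{argmax} (0-based)
#' @examples
#' groupCombinationOracle(c(0, 1, 2), c(0, 0, -1))  # max 1 at k = 1
#' @export
groupCombinationOracle <- function(V, Vbar) {
  if (length(V) != length(Vbar) || length(V) < 1L)
    stop("'V' and 'Vbar' must be non-empty vectors of equal length")
  best <- -Inf; arg <- 0L
  for (k in seq_along(V)) {
    v <- V[k] + Vbar[k]
    if (v > best) { best <- v; arg <- k - 1L }
  }
  list(max = best, argmax = arg)
}
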