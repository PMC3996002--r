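#' @import methods
NULL

FOLD_ALPHABET <- c("A", "C", "G", "U", "N")

#' RNA sequence for base-pair maximization
#'
#' Holds a validated RNA sequence over the alphabet \code{A, C, G, U, N}.
#' \code{N} is a non-pairing sentinel used for tile padding; it never forms a
#' base pair under any [PairingRule]. All positions in the public API are
#' 1-based and inclusive.
#'
#' @slot bases single character string over \code{A,C,G,U,N}
#' @slot name free-text label (FASTA record name)
#'
#' @seealso [rnaSequence()], [readFoldFasta()], [randomRnaSequence()]
#' @export
setClass("RnaSequence",
  representation(bases = "character", name = "character"),
  prototype(bases = "", name = ""))

setValidity("RnaSequence", function(object) {
  if (length(object@bases) != 1L) return("'bases' must be a single string")
  if (length(object@name) != 1L) return("'name' must be a single string")
  if (nchar(object@bases) < 1L) return("sequence must be non-empty")
  ch <- strsplit(object@bases, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% FOLD_ALPHABET)
  if (length(bad) > 0L)
    return(sprintf("invalid character '%s' at position %d", ch[bad[1L]], bad[1L]))
  TRUE
})

#' Base-pairing rule
#'
#' A symmetric 0/1 predicate over ordered base pairs plus a minimum loop
#' length (number of unpaired bases that must separate the two ends of a
#' pair). The default rule is the strict Watson-Crick complement: A-U and
#' C-G score 1, everything else (including any pair involving the sentinel
#' \code{N}) scores 0, with \code{minLoop = 0} so adjacent bases may pair.
#'
#' @slot pairs 5x5 integer 0/1 matrix with dimnames \code{A,C,G,U,N}
#' @slot minLoop non-negative integer
#'
#' @seealso [pairingRule()], [pairScore()]
#' @export
setClass("PairingRule",
  representation(pairs = "matrix", minLoop = "integer"))

setValidity("PairingRule", function(object) {
  p <- object@pairs
  if (!identical(dim(p), c(5L, 5L))) return("'pairs' must be a 5x5 matrix")
  if (!identical(rownames(p), FOLD_ALPHABET) ||
      !identical(colnames(p), FOLD_ALPHABET))
    return("'pairs' dimnames must be A,C,G,U,N")
  if (!all(p %in% c(0L, 1L))) return("'pairs' entries must be 0 or 1")
  if (!identical(p, t(p))) return("pairing predicate must be symmetric")
  if (any(p[5L, ] != 0L)) return("sentinel N must never pair")
  if (length(object@minLoop) != 1L || is.na(object@minLoop) ||
      object@minLoop < 0L)
    return("'minLoop' must be a single non-negative integer")
  TRUE
})

#' Non-crossing secondary structure
#'
#' A set of disjoint, non-crossing base pairs on positions \code{1..n}. Two
#' pairs (i,j) and (k,l) with i < k must be either nested (i < k < l < j) or
#' disjoint (i < j < k < l); this is exactly the balanced-parenthesis
#' condition that makes [dotBracket()] well defined.
#'
#' @slot pairs m x 2 integer matrix, one row per pair, first column < second
#' @slot n sequence length the structure refers to
#'
#' @seealso [tracebackFold()], [dotBracket()], [writeCT()]
#' @export
setClass("SecondaryStructure",
  representation(pairs = "matrix", n = "integer"))

setValidity("SecondaryStructure", function(object) {
  p <- object@pairs
  n <- object@n
  if (length(n) != 1L || n < 0L) return("'n' must be a single non-negative integer")
  if (ncol(p) != 2L) return("'pairs' must have two columns")
  if (nrow(p) == 0L) return(TRUE)
  if (any(p < 1L) || any(p > n)) return("pair indices must lie in 1..n")
  if (any(p[, 1L] >= p[, 2L])) return("each pair must have i < j")
  idx <- as.vector(p)
  if (anyDuplicated(idx)) return("each position may occur in at most one pair")
  # non-crossing: sort by opening position, check with a stack of closers
  o <- order(p[, 1L])
  op <- p[o, 1L]; cl <- p[o, 2L]
  stack <- integer(0L)
  for (r in seq_along(op)) {
    while (length(stack) > 0L && stack[length(stack)] < op[r])
      stack <- stack[-length(stack)]
    if (length(stack) > 0L && cl[r] > stack[length(stack)])
      return(sprintf("pairs (%d,%d) crosses an enclosing pair",
                     op[r], cl[r]))
    stack <- c(stack, cl[r])
  }
  TRUE
})

#' Result of a folding engine
#'
#' Container returned by every engine ([nussinovFold()], [twoVectorFold()],
#' [fgFold()], [partialMemoFold()], [fullMemoFold()], [tiledFold()]). It
#' bundles the score table D, the traceback decision table D*, instrumented
#' operation counts, and any engine-specific preprocessing tables.
#'
#' The score table is stored internally in an (n+1) x (n+1) layout where
#' column j+1 holds D(., j), so the base cases D(i, i-1) = 0 live on the
#' main diagonal of the storage matrix. Use [scoreMatrix()] for the standard
#' n x n view and [maxPairs()] for D(1, n).
#'
#' Traceback decisions per cell: 0 = leaf (j <= i), 1 = paired ends
#' (case 1 of the recurrence), 2 = split at the stored k (case 2).
#'
#' @slot algorithm engine label
#' @slot seq the folded [RnaSequence-class]
#' @slot rule the [PairingRule-class] used
#' @slot q group/tile width (1 for the plain Nussinov engine)
#' @slot score internal (n+1) x (n+1) score storage
#' @slot traceOp n x n integer decision codes
#' @slot traceK n x n integer split indices (absolute k)
#' @slot stats named list of operation counters
#' @slot tables engine-specific tables (memo tables, FG tables, layout)
#'
#' @export
setClass("FoldResult",
  representation(algorithm = "character", seq = "RnaSequence",
                 rule = "PairingRule", q = "integer", score = "matrix",
                 traceOp = "matrix", traceK = "matrix",
                 stats = "list", tables = "list"))

setValidity("FoldResult", function(object) {
  n <- nchar(object@seq@bases)
  if (!identical(dim(object@score), c(n + 1L, n + 1L)))
    return("score storage must be (n+1) x (n+1)")
  if (!identical(dim(object@traceOp), c(n, n)))
    return("traceOp must be n x n")
  if (any(object@score < 0)) return("scores must be non-negative")
  TRUE
})

#' Exhaustive Four-Russians preprocessing table
#'
#' The table R of the two-vector method: for every pair of a horizontal
#' difference-vector code h and a vertical difference-vector code v (both in
#' \code{[0, 2^q)}), the maximum over k of \code{V_k + Vbar_k} of the decoded
#' running-total vectors, and the smallest k attaining it (0-based).
#' Entries are stored flat at index \code{h * 2^q + v + 1}. All 2^q x 2^q
#' code pairs are present for branch-free indexing even though codes with
#' bit 0 set never arise from encoding (V_0 = 0 by definition).
#'
#' @slot q group width
#' @slot max numeric vector of length 4^q, group-combination maxima
#' @slot argmax integer vector of length 4^q, 0-based argmax k
#'
#' @seealso [buildPrecompTable()], [groupCombinationOracle()]
#' @export
setClass("PrecompTable",
  representation(q = "integer", max = "numeric", argmax = "integer"))

setValidity("PrecompTable", function(object) {
  q <- object@q
  if (length(q) != 1L || q < 1L || q > 12L) return("q must be in 1..12")
  if (length(object@max) != 4L^q || length(object@argmax) != 4L^q)
    return("entry vectors must have length 4^q")
  TRUE
})

#' Tiled table layout
#'
#' Decomposition of the (padded) DP table into q x q tiles. Tile (tr, tc)
#' (0-based, tc >= tr) holds cells with row index in tr*q+1 .. (tr+1)*q and
#' column index in tc*q .. (tc+1)*q - 1: the offset between row and column
#' grouping matches the split D(i, k-1) + D(k, j), which combines column
#' k-1 with row k. The sequence is padded to n' = n + q - (n mod q) with the
#' non-pairing sentinel so every tile is full.
#'
#' @slot q tile width
#' @slot n original sequence length
#' @slot nPad padded length n'
#' @slot nTiles tiles per side (n'/q)
#' @seealso [tileLayout()], [buildSchedule()], [tiledFold()]
#' @export
setClass("TiledLayout",
  representation(q = "integer", n = "integer", nPad = "integer",
                 nTiles = "integer"))

setValidity("TiledLayout", function(object) {
  q <- object@q; n <- object@n; np <- object@nPad
  if (q < 1L) return("q must be >= 1")
  if (np != n + q - n %% q) return("nPad must equal n + q - (n mod q)")
  if (np %% q != 0L || np <= n) return("nPad must be a multiple of q exceeding n")
  if (object@nTiles != np %/% q) return("nTiles must be nPad/q")
  TRUE
})

#' Diagonal wavefront schedule
#'
#' Ordered tile-diagonal sets for a [TiledLayout-class]. Diagonal d contains
#' every tile with tc - tr = d. All data a tile consumes (horizontal
#' difference vectors of tiles to its left, vertical difference vectors of
#' tiles below) come from strictly earlier diagonals, so tiles within one
#' diagonal may be computed in any order or concurrently.
#'
#' @slot layout the [TiledLayout-class]
#' @slot diagonals list of integer matrices (columns tr, tc), one per diagonal
#' @export
setClass("WavefrontSchedule",
  representation(layout = "TiledLayout", diagonals = "list"))

setValidity("WavefrontSchedule", function(object) {
  nt <- object@layout@nTiles
  if (length(object@diagonals) != nt)
    return("number of diagonals must equal the number of tile-columns")
  seen <- 0L
  for (d in seq_along(object@diagonals)) {
    m <- object@diagonals[[d]]
    if (ncol(m) != 2L) return("each diagonal must be a 2-column matrix")
    if (any(m[, 2L] - m[, 1L] != d - 1L))
      return("tiles on a diagonal must share tc - tr")
    seen <- seen + nrow(m)
  }
  if (seen != (nt * (nt + 1L)) %/% 2L)
    return("every upper-triangular tile must appear exactly once")
  TRUE
})
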