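# The FG interleaved algorithm and the two memoized hybrids. All three are
# result-identical to the two-vector engine; they differ only in when and
# for which difference-vector pairs the group-combination maxima are
# computed. The shared grouped DP lives in four-russians.R (groupedFold).

#' Frid-Gusfield interleaved folding
#'
#' Instead of exhaustively preprocessing all 2^(2q) code pairs up front,
#' the FG schedule interleaves preprocessing with the DP: whenever a row
#' group completes, its horizontal vector is expanded against all 2^q
#' possible vertical vectors and the results -- with the group's initial
#' cell value D(i, gq) already added -- are tabled, indexed by (row, group,
#' vertical code). This expansion is repeated for every group of every row
#' even when the same horizontal vector recurs, reproducing the duplicated
#' work that makes FG slower than the two-vector method in practice. A cell
#' query retrieves the tabled value and adds the matched column group's
#' initial value D(gq+1, j).
#'
#' @inheritParams twoVectorFold
#' @return a [FoldResult-class]; \code{opStats(x)$fgEntries} equals
#'   (completed row groups) x 2^q
#' @export
fgFold <- function(seq, q = 4L, rule = pairingRule()) {
  groupedFold(seq, q, rule, mode = "fg")
}

#' Partially memoized Four-Russians folding
#'
#' Hybrid schedule: like FG, preprocessing happens at row-group completion;
#' like the two-vector method, the table is indexed by the vector pair, so
#' nothing is ever computed twice. When a group completes with a horizontal
#' code not seen before, that code is expanded against all 2^q vertical
#' codes and tabled; all later queries are pure reads. The memo therefore
#' holds exactly (distinct horizontal codes seen) x 2^q entries.
#'
#' @inheritParams twoVectorFold
#' @return a [FoldResult-class]; see \code{opStats(x)$memoEntries} and
#'   \code{opStats(x)$distinctHCodes}
#' @export
partialMemoFold <- function(seq, q = 4L, rule = pairingRule()) {
  groupedFold(seq, q, rule, mode = "partial-memo")
}

#' Completely memoized Four-Russians folding
#'
#' Each (horizontal, vertical) code pair is computed the first time it is
#' queried and read from the memo thereafter. The memo holds exactly one
#' entry per distinct pair actually queried, so its size is bounded both by
#' 2^(2q) and by the number of table lookups.
#'
#' @inheritParams twoVectorFold
#' @return a [FoldResult-class]
#' @export
fullMemoFold <- function(seq, q = 4L, rule = pairingRule()) {
  groupedFold(seq, q, rule, mode = "full-memo")
}

#' Fold a sequence with a selectable engine
#'
#' Convenience dispatcher used by the command-line interface.
#'
#' @param seq an [RnaSequence-class]
#' @param algorithm one of \code{"nussinov"}, \code{"two-vector"},
#'   \code{"fg"}, \code{"partial-memo"}, \code{"full-memo"}, \code{"tiled"}
#' @param q group/tile width (ignored by \code{"nussinov"})
#' @param rule a [PairingRule-class]
#' @param shuffleSeed within-diagonal tile order seed (tiled engine only)
#' @return a [FoldResult-class]
#' @export
foldSequence <- function(seq, algorithm = c("nussinov", "two-vector", "fg",
                                            "partial-memo", "full-memo",
                                            "tiled"),
                         q = 4L, rule = pairingRule(), shuffleSeed = NULL) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    "nussinov" = nussinovFold(seq, rule),
    "two-vector" = twoVectorFold(seq, q, rule),
    "fg" = fgFold(seq, q, rule),
    "partial-memo" = partialMemoFold(seq, q, rule),
    "full-memo" = fullMemoFold(seq, q, rule),
    "tiled" = tiledFold(seq, q, rule, shuffleSeed = shuffleSeed))
}
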