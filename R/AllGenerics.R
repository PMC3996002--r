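#' Maximum number of pairs found by a fold
#'
#' Returns D(1, n), the maximum number of non-crossing complementary base
#' pairs for the full sequence.
#'
#' @param x a [FoldResult-class]
#' @return integer-valued numeric scalar
#' @export
setGeneric("maxPairs", function(x) standardGeneric("maxPairs"))

#' Score table in standard form
#'
#' The upper-triangular dynamic-programming table as an n x n matrix with
#' D(i, j) at \code{[i, j]} for j >= i; entries below the diagonal are 0.
#' Engine cross-checks compare these matrices cell by cell.
#'
#' @param x a [FoldResult-class]
#' @return numeric n x n matrix
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' Operation counters of a fold
#'
#' Named list with at least \code{candidateEvaluations} (number of evaluated
#' split terms D(i,k-1) + D(k,j)) and \code{tableLookups} (number of
#' Four-Russians table queries; 0 for the plain Nussinov engine). Variant
#' engines add their own accounting (memo entries, distinct codes, completed
#' row groups, guard violations).
#'
#' @param x a [FoldResult-class]
#' @return named list of counters
#' @export
setGeneric("opStats", function(x) standardGeneric("opStats"))

#' Recover an optimal structure from stored traceback decisions
#'
#' Replays the D* decision table from cell (i, j) and returns the optimal
#' non-crossing structure for that subsequence. The pair count of the result
#' equals D(i, j).
#'
#' @param x a [FoldResult-class]
#' @param i,j 1-based subsequence bounds; defaults recover the full fold
#' @return a [SecondaryStructure-class]
#' @export
setGeneric("tracebackFold",
  function(x, i = 1L, j = NULL) standardGeneric("tracebackFold"))

#' Dot-bracket notation of a structure
#'
#' @param x a [SecondaryStructure-class]
#' @return length-n character string of \code{(}, \code{)} and \code{.}
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))

#' Write a structure in connect-table (CT) format
#'
#' @param x a [SecondaryStructure-class]
#' @param seq the [RnaSequence-class] the structure belongs to
#' @param path output file path
#' @return invisibly, the path
#' @export
setGeneric("writeCT", function(x, seq, path) standardGeneric("writeCT"))

#' @describeIn RnaSequence sequence length n
#' @param x an \code{RnaSequence}
#' @export
setMethod("length", "RnaSequence", function(x) nchar(x@bases))

#' Sequence string of an RnaSequence
#' @param x an [RnaSequence-class]
#' @return single character string
#' @export
setGeneric("seqBases", function(x) standardGeneric("seqBases"))

#' Name label of an RnaSequence
#' @param x an [RnaSequence-class]
#' @return single character string
#' @export
setGeneric("seqName", function(x) standardGeneric("seqName"))

#' @rdname seqBases
#' @export
setMethod("seqBases", "RnaSequence", function(x) x@bases)

#' @rdname seqName
#' @export
setMethod("seqName", "RnaSequence", function(x) x@name)
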