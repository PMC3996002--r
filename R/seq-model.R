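# Sequence validation, FASTA I/O, the pairing rule and seeded fixtures.

#' Validate and construct an RNA sequence
#'
#' Uppercases the input, transliterates \code{T} to \code{U} (so DNA input
#' is accepted), strips all whitespace and validates the result against the
#' alphabet \code{A, C, G, U, N}. Rejects any other character with a message
#' naming the first offending position (position counted in the cleaned,
#' uppercased sequence).
#'
#' @param raw character string; bases, case-insensitive, possibly containing
#'   whitespace and \code{T}s
#' @param name record label, default \code{""}
#' @return an [RnaSequence-class]
#' @examples
#' rnaSequence("acgu")          # -> ACGU
#' rnaSequence("ACGT")          # T is transliterated to U
#' @export
rnaSequence <- function(raw, name = "") {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw))
    stop("'raw' must be a single character string")
  s <- gsub("[[:space:]]+", "", raw)
  if (nchar(s) == 0L)
    stop("sequence is empty after whitespace stripping")
  s <- chartr("T", "U", toupper(s))
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% FOLD_ALPHABET)
  if (length(bad) > 0L)
    stop(sprintf("invalid character '%s' at position %d (alphabet is A,C,G,U,T,N)",
                 ch[bad[1L]], bad[1L]))
  new("RnaSequence", bases = paste(ch, collapse = ""), name = as.character(name))
}

#' Read RNA sequences from a FASTA file
#'
#' Multi-record, multi-line FASTA. Each record is validated through
#' [rnaSequence()] (so DNA records are transliterated). Reading is delegated
#' to \code{Biostrings::readBStringSet}.
#'
#' @param path FASTA file path
#' @return list of [RnaSequence-class], in file order
#' @export
readFoldFasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("FASTA file is empty: ", path)
  if (!startsWith(first, ">"))
    stop("malformed FASTA (first line does not start with '>'): ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  out <- vector("list", length(set))
  nm <- names(set)
  for (k in seq_along(set)) {
    body <- as.character(set[[k]])
    if (nchar(body) == 0L)
      stop(sprintf("FASTA record '%s' has an empty sequence", nm[k]))
    out[[k]] <- rnaSequence(body, name = nm[k])
  }
  out
}

#' Write RNA sequences to a FASTA file
#'
#' Counterpart of [readFoldFasta()]; delegates to
#' \code{Biostrings::writeXStringSet}.
#'
#' @param seqs list of [RnaSequence-class] (or a single one)
#' @param path output path
#' @return invisibly, the path
#' @export
writeFoldFasta <- function(seqs, path) {
  if (is(seqs, "RnaSequence")) seqs <- list(seqs)
  set <- Biostrings::BStringSet(vapply(seqs, seqBases, character(1L)))
  names(set) <- vapply(seqs, seqName, character(1L))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Construct a pairing rule
#'
#' The default rule scores 1 exactly for the complementary pairs A-U and
#' C-G. \code{wobble = TRUE} additionally enables the G-U wobble pair (not
#' part of the default). \code{minLoop} is the minimum number of unpaired
#' bases between the ends of a pair; the default 0 reproduces the plain
#' recurrence where adjacent bases may pair, while \code{minLoop = 3} is the
#' common biological choice for hairpin loops.
#'
#' @param wobble also allow G-U?
#' @param minLoop non-negative integer
#' @param pairs optional custom 5x5 symmetric 0/1 matrix with dimnames
#'   \code{A,C,G,U,N} (overrides \code{wobble})
#' @return a [PairingRule-class]
#' @export
pairingRule <- function(wobble = FALSE, minLoop = 0L, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- matrix(0L, 5L, 5L, dimnames = list(FOLD_ALPHABET, FOLD_ALPHABET))
    pairs["A", "U"] <- pairs["U", "A"] <- 1L
    pairs["C", "G"] <- pairs["G", "C"] <- 1L
    if (isTRUE(wobble)) pairs["G", "U"] <- pairs["U", "G"] <- 1L
  } else {
    storage.mode(pairs) <- "integer"
  }
  new("PairingRule", pairs = pairs, minLoop = as.integer(minLoop))
}

#' Pairing predicate for two bases
#'
#' @param a,b single bases in \code{A,C,G,U,N}
#' @param rule a [PairingRule-class]
#' @return 0 or 1
#' @examples
#' pairScore("A", "U")  # 1
#' pairScore("A", "C")  # 0
#' @export
pairScore <- function(a, b, rule = pairingRule()) {
  if (!a %in% FOLD_ALPHABET || !b %in% FOLD_ALPHABET)
    stop("bases must be in {A,C,G,U,N}")
  rule@pairs[a, b]
}

#' Seeded random RNA sequence
#'
#' Uniform i.i.d. draws over \code{A, C, G, U}. The generator state of the
#' caller is left untouched; identical \code{(n, seed)} always give the
#' identical sequence.
#'
#' @param n length, >= 1
#' @param seed integer seed
#' @param name record label
#' @return an [RnaSequence-class]
#' @export
randomRnaSequence <- function(n, seed, name = sprintf("random_n%d_s%d", n, seed)) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  bases <- withLocalSeed(seed,
    sample(c("A", "C", "G", "U"), n, replace = TRUE))
  new("RnaSequence", bases = paste(bases, collapse = ""), name = name)
}

# run expr under a local RNG seed, restoring the caller's RNG state
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# integer codes 1..5 for A,C,G,U,N
seqCodes <- function(seq) {
  match(strsplit(seq@bases, "", fixed = TRUE)[[1L]], FOLD_ALPHABET)
}

setMethod("show", "RnaSequence", function(object) {
  n <- length(object)
  b <- object@bases
  if (n > 60L) b <- paste0(substr(b, 1L, 57L), "...")
  cat(sprintf("RnaSequence '%s' (n = %d)\n  %s\n", object@name, n, b))
})

setMethod("show", "PairingRule", function(object) {
  on <- which(object@pairs == 1L & upper.tri(object@pairs), arr.ind = TRUE)
  lab <- paste(FOLD_ALPHABET[on[, 1L]], FOLD_ALPHABET[on[, 2L]],
               sep = "-", collapse = ", ")
  cat(sprintf("PairingRule: %s; minLoop = %d\n", lab, object@minLoop))
})
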