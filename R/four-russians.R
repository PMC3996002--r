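# The two-vector method: difference-vector codec, exhaustive preprocessing
# table R, and the grouped column-major DP (shared, in parameterized form,
# with the FG and memoized variants in variants.R).
#
# Encoding convention: bit p (0-indexed, least significant = position 0) of
# a code carries the absolute difference at position p. Bit 0 is
# structurally 0 because V_0 = 0 by definition, so only 2^(q-1) codes are
# reachable from encoding; tables are nevertheless allocated over all
# 2^q x 2^q codes for branch-free flat indexing.

#' Encode q consecutive row cells as (initial value, horizontal code)
#'
#' Along a row the table is non-decreasing with steps in \{0, 1\}; the cells
#' are represented exactly by their first value plus the bit-coded step
#' vector v (v_0 = 0).
#'
#' @param cells numeric vector of q consecutive row values, left to right
#' @return list with \code{initial}, \code{code}, \code{q}
#' @examples
#' encodeHorizontal(c(2, 2, 3, 3))  # code 4 = bits 0010
#' @export
encodeHorizontal <- function(cells) {
  q <- length(cells)
  if (q < 1L) stop("'cells' must be non-empty")
  if (q == 1L) return(list(initial = cells[1L], code = 0L, q = 1L))
  d <- diff(cells)
  if (any(d != 0 & d != 1))
    stop("row differences outside {0,1}: upstream DP table is corrupt")
  list(initial = cells[1L], code = as.integer(sum(2^(1:(q - 1L)) * d)), q = q)
}

#' Encode q consecutive column cells as (initial value, vertical code)
#'
#' Down a column the table is non-increasing with steps in \{0, -1\}; bit p
#' of the code carries the absolute step.
#'
#' @param cells numeric vector of q consecutive column values, top to bottom
#' @return list with \code{initial}, \code{code}, \code{q}
#' @examples
#' encodeVertical(c(3, 3, 2, 2))    # code 4
#' @export
encodeVertical <- function(cells) {
  q <- length(cells)
  if (q < 1L) stop("'cells' must be non-empty")
  if (q == 1L) return(list(initial = cells[1L], code = 0L, q = 1L))
  d <- diff(cells)
  if (any(d != 0 & d != -1))
    stop("column differences outside {0,-1}: upstream DP table is corrupt")
  list(initial = cells[1L], code = as.integer(sum(2^(1:(q - 1L)) * -d)), q = q)
}

#' Decode a horizontal (initial, code) pair back to cell values
#' @param initial first cell value
#' @param code bit-encoded difference vector
#' @param q group width
#' @return numeric vector of q cell values
#' @export
decodeHorizontal <- function(initial, code, q) {
  if (q == 1L) return(initial)
  initial + c(0, cumsum(bitwAnd(code %/% 2^(1:(q - 1L)), 1L)))
}

#' Decode a vertical (initial, code) pair back to cell values
#' @inheritParams decodeHorizontal
#' @return numeric vector of q cell values
#' @export
decodeVertical <- function(initial, code, q) {
  if (q == 1L) return(initial)
  initial - c(0, cumsum(bitwAnd(code %/% 2^(1:(q - 1L)), 1L)))
}

# running-total decode tables for all 2^q codes: row (code+1) holds
# V_0..V_{q-1} (horizontal) resp. |Vbar| (vertical is the negation)
decodeTables <- function(q) {
  nq <- 2L^q
  codes <- 0:(nq - 1L)
  bits <- vapply(0:(q - 1L), function(p) as.numeric(bitwAnd(codes, 2L^p) > 0L),
                 numeric(nq))
  if (q == 1L) bits <- matrix(bits, ncol = 1L)
  bits[, 1L] <- 0   # v_0 = 0 by definition; bit 0 of a code is ignored
  V <- bits %*% upper.tri(matrix(0, q, q), diag = TRUE)
  list(V = V, Vbar = -V, nq = nq)
}

#' Build the exhaustive Four-Russians preprocessing table
#'
#' For every pair of codes (h, v) in \code{[0, 2^q) x [0, 2^q)}, tabulates
#' the maximum over k of \code{V_k + Vbar_k} of the decoded running totals
#' and the smallest 0-based k attaining it. This runs once, before any DP
#' cell is filled. The guard \code{q <= 12} keeps the 2^(2q)-entry
#' enumeration from exploding.
#'
#' @param q group width, 1..12
#' @return a [PrecompTable-class]
#' @export
buildPrecompTable <- function(q) {
  q <- as.integer(q)
  if (is.na(q) || q < 1L || q > 12L) stop("'q' must be an integer in 1..12")
  dt <- decodeTables(q)
  nq <- dt$nq
  maxv <- numeric(nq * nq)
  argk <- integer(nq * nq)
  hseq <- seq_len(nq)
  for (v in hseq) {
    M <- dt$V + matrix(dt$Vbar[v, ], nq, q, byrow = TRUE)
    am <- max.col(M, ties.method = "first")
    idx <- (hseq - 1L) * nq + v          # flat index h * 2^q + v + 1
    maxv[idx] <- M[cbind(hseq, am)]
    argk[idx] <- am - 1L
  }
  new("PrecompTable", q = q, max = maxv, argmax = argk)
}

#' Look up one entry of a preprocessing table
#' @param table a [PrecompTable-class]
#' @param h,v codes in \code{[0, 2^q)}
#' @return list with \code{max} and \code{argmax} (0-based)
#' @export
precompLookup <- function(table, h, v) {
  nq <- 2L^table@q
  if (any(h < 0L) || any(h >= nq) || any(v < 0L) || any(v >= nq))
    stop("codes out of range for this table")
  idx <- h * nq + v + 1L
  list(max = table@max[idx], argmax = table@argmax[idx])
}

setMethod("show", "PrecompTable", function(object) {
  cat(sprintf("PrecompTable: q = %d, %d x %d code pairs (%d reachable)\n",
              object@q, 2L^object@q, 2L^object@q, 4L^(object@q - 1L)))
})

#' Two-vector Four-Russians folding
#'
#' The grouped Nussinov DP. Rows are grouped (kq+1, ..., (k+1)q) and columns
#' (kq, ..., (k+1)q-1) -- offset by one so that the split D(i,k-1) + D(k,j)
#' always combines the g-th column group of row i with the g-th row group of
#' column j. For each cell, every full group is resolved by a single lookup
#' in the exhaustively precomputed table R:
#' \deqn{D(i,l) + D(l+1, j) + \max_k (V_k + \bar V_k)}
#' and the at most 2q residual cells on either side of the full groups are
#' evaluated by the plain recurrence. Difference vectors are encoded once
#' per completed row/column group and cached, never recomputed per query.
#' The resulting table is cell-identical to [nussinovFold()]'s.
#'
#' @param seq an [RnaSequence-class]
#' @param q group width, 1..12; default 4
#' @param rule a [PairingRule-class]
#' @return a [FoldResult-class]; \code{opStats(x)$tableLookups} counts R
#'   queries and \code{candidateEvaluations} counts residual split terms
#' @examples
#' maxPairs(twoVectorFold(rnaSequence("GGGAAACCC"), q = 2))  # 3
#' @export
twoVectorFold <- function(seq, q = 4L, rule = pairingRule()) {
  groupedFold(seq, q, rule, mode = "two-vector")
}

# Shared grouped engine. mode selects how full-group candidates are
# resolved and which preprocessing schedule runs:
#   two-vector  : exhaustive table R built up front
#   fg          : per-(row, group) expansion at group completion, value
#                 includes the group's initial cell (variants.R docs)
#   partial-memo: expand all 2^q partners when a NEW horizontal code is
#                 first seen at a group completion
#   full-memo   : compute each (h, v) pair at first query
groupedFold <- function(seq, q, rule, mode) {
  q <- as.integer(q)
  if (is.na(q) || q < 1L || q > 12L) stop("'q' must be an integer in 1..12")
  inp <- foldInputs(seq, rule)
  n <- inp$n; s <- inp$s; pmat <- inp$pmat; minLoop <- inp$minLoop

  nq <- 2L^q
  p2 <- if (q > 1L) 2^(1:(q - 1L)) else numeric(0L)
  ngr <- n %/% q + 1L

  # mode-specific preprocessing state
  Rmax <- Rarg <- NULL          # flat tables (two-vector, memo modes)
  dt <- NULL                    # decode tables (fg / memo modes)
  seenH <- NULL                 # partial-memo: which h codes were expanded
  memoEntries <- 0
  fgVal <- fgArg <- NULL        # fg: (n x ngr x 2^q) arrays
  completedRowGroups <- 0
  if (mode == "two-vector") {
    tab <- buildPrecompTable(q)
    Rmax <- tab@max; Rarg <- tab@argmax
  } else {
    dt <- decodeTables(q)
    Rmax <- rep(NA_real_, nq * nq)
    Rarg <- rep(NA_integer_, nq * nq)
    if (mode == "partial-memo") seenH <- logical(nq)
    if (mode == "fg") {
      fgVal <- array(NA_real_, c(n, ngr, nq))
      fgArg <- array(NA_integer_, c(n, ngr, nq))
    }
  }

  Dm <- matrix(0, n + 1L, n + 1L)
  traceOp <- matrix(TRACE_LEAF, n, n)
  traceK <- matrix(0L, n, n)
  Hc <- matrix(NA_integer_, n, ngr); Hi <- matrix(NA_real_, n, ngr)
  Vc <- matrix(NA_integer_, ngr, n); Vi <- matrix(NA_real_, ngr, n)
  cand <- 0; lks <- 0

  # horizontal group g completes when its last column (g+1)q - 1 is filled;
  # also run per-mode preprocessing for the group's realized h codes
  completeColumnGroup <- function(j) {
    if ((j + 1L) %% q != 0L) return(invisible(NULL))
    g <- (j + 1L) %/% q - 1L
    if (g < 1L) return(invisible(NULL))
    rows <- seq_len(g * q)
    blk <- Dm[rows, (g * q + 1L):(g * q + q), drop = FALSE]
    d <- if (q > 1L)
      blk[, 2:q, drop = FALSE] - blk[, 1:(q - 1L), drop = FALSE]
    else matrix(0, length(rows), 0L)
    if (any(d < 0 | d > 1))
      stop("row differences outside {0,1}: DP table is corrupt")
    hc <- as.integer(d %*% p2)
    if (q == 1L) hc <- integer(length(rows))
    Hc[rows, g + 1L] <<- hc
    Hi[rows, g + 1L] <<- blk[, 1L]
    completedRowGroups <<- completedRowGroups + length(rows)
    if (mode == "partial-memo") {
      for (h in setdiff(unique(hc), which(seenH) - 1L)) {
        M <- matrix(dt$V[h + 1L, ], nq, q, byrow = TRUE) + dt$Vbar
        am <- max.col(M, ties.method = "first")
        idx <- h * nq + seq_len(nq)
        Rmax[idx] <<- M[cbind(seq_len(nq), am)]
        Rarg[idx] <<- am - 1L
        seenH[h + 1L] <<- TRUE
        memoEntries <<- memoEntries + nq
      }
    } else if (mode == "fg") {
      # expand every (row, group) against all 2^q column vectors, even for
      # repeated h codes: the tabled value includes D(i, gq), which differs
      # per row, reproducing the FG duplicated work
      Hrow <- dt$V[hc + 1L, , drop = FALSE]
      curMax <- matrix(-Inf, length(rows), nq)
      curArg <- matrix(0L, length(rows), nq)
      for (k in seq_len(q)) {
        Bk <- outer(Hrow[, k], dt$Vbar[, k], "+")
        upd <- Bk > curMax
        curMax[upd] <- Bk[upd]
        curArg[upd] <- k - 1L
      }
      fgVal[rows, g + 1L, ] <<- blk[, 1L] + curMax
      fgArg[rows, g + 1L, ] <<- curArg
    }
    invisible(NULL)
  }

  completeColumnGroup(1L)   # q = 1: the group covering column 1 is already done
  if (n >= 2L) for (j in 2:n) {
    jj <- j + 1L
    ghi <- j %/% q - 1L
    if (q == 1L && j <= n) {   # q = 1: row group {j} is the base cell D(j,j)
      Vc[j, j] <- 0L
      Vi[j, j] <- 0
    }
    for (i in (j - 1L):1L) {
      glo <- (i + q - 1L) %/% q
      best <- -Inf; op <- TRACE_SPLIT; bk <- 0L
      if (glo > ghi) {                        # no full group: pure residual
        ks <- (i + 1L):j
        c2 <- Dm[i, ks] + Dm[ks, jj]
        cand <- cand + length(ks)
        w <- which.max(c2); best <- c2[w]; bk <- ks[w]
      } else {
        if (i + 1L <= glo * q) {              # residual before first group
          ks <- (i + 1L):(glo * q)
          c2 <- Dm[i, ks] + Dm[ks, jj]
          cand <- cand + length(ks)
          w <- which.max(c2); best <- c2[w]; bk <- ks[w]
        }
        gs <- glo:ghi
        gi <- gs + 1L
        vc <- Vc[gi, j]
        lks <- lks + length(gs)
        if (mode == "fg") {
          fi <- cbind(i, gi, vc + 1L)
          cg <- fgVal[fi] + Vi[gi, j]
          ag <- fgArg[fi]
        } else {
          fl <- Hc[i, gi] * nq + vc + 1L
          if (mode == "full-memo") {
            miss <- unique(fl[is.na(Rmax[fl])])
            if (length(miss) > 0L) {
              hm <- (miss - 1L) %/% nq; vm <- (miss - 1L) %% nq
              M <- dt$V[hm + 1L, , drop = FALSE] +
                   dt$Vbar[vm + 1L, , drop = FALSE]
              am <- max.col(M, ties.method = "first")
              Rmax[miss] <- M[cbind(seq_along(miss), am)]
              Rarg[miss] <- am - 1L
              memoEntries <- memoEntries + length(miss)
            }
          }
          cg <- Hi[i, gi] + Vi[gi, j] + Rmax[fl]
          ag <- Rarg[fl]
        }
        w <- which.max(cg)
        if (cg[w] > best) {
          best <- cg[w]
          bk <- gs[w] * q + 1L + ag[w]
        }
        ka <- (ghi + 1L) * q + 1L
        if (ka <= j) {                        # residual after last group
          ks <- ka:j
          c2 <- Dm[i, ks] + Dm[ks, jj]
          cand <- cand + length(ks)
          w <- which.max(c2)
          if (c2[w] > best) { best <- c2[w]; bk <- ks[w] }
        }
      }
      if (pmat[s[i], s[j]] == 1L && (j - i - 1L) >= minLoop) {
        v1 <- 1 + Dm[i + 1L, j]
        if (v1 >= best) { best <- v1; op <- TRACE_PAIRED; bk <- 0L }
      }
      Dm[i, jj] <- best
      traceOp[i, j] <- op
      traceK[i, j] <- bk
      # vertical group completion: top cell of rows gq+1..(g+1)q in col j
      if ((i - 1L) %% q == 0L && i + q - 1L <= j) {
        g <- (i - 1L) %/% q
        vals <- Dm[i:(i + q - 1L), jj]
        d <- if (q > 1L) vals[1:(q - 1L)] - vals[2:q] else numeric(0L)
        if (any(d < 0 | d > 1))
          stop("column differences outside {0,-1}: DP table is corrupt")
        Vc[g + 1L, j] <- as.integer(sum(p2 * d))
        Vi[g + 1L, j] <- vals[1L]
      }
    }
    completeColumnGroup(j)
  }

  stats <- list(candidateEvaluations = cand, tableLookups = lks)
  tables <- list()
  if (mode == "two-vector") {
    tables$precomp <- new("PrecompTable", q = q, max = Rmax, argmax = Rarg)
  } else if (mode %in% c("partial-memo", "full-memo")) {
    stats$memoEntries <- memoEntries
    stats$distinctHCodes <- if (mode == "partial-memo") sum(seenH)
                            else length(unique((which(!is.na(Rmax)) - 1L) %/% nq))
    tables$memoMax <- Rmax
    tables$memoArg <- Rarg
  } else if (mode == "fg") {
    stats$completedRowGroups <- completedRowGroups
    stats$fgEntries <- completedRowGroups * nq
    tables$fgVal <- fgVal
    tables$fgArg <- fgArg
  }
  newFoldResult(mode, seq, rule, q, Dm, traceOp, traceK, stats, tables)
}
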