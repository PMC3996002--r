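# q x q tile decomposition and diagonal-wavefront schedule. The engine
# mirrors the structure of a GPU implementation without any GPU: tiles on
# one tile-diagonal are mutually independent and are processed in a
# (seed-)shuffled serial order; a dynamic access guard verifies that a tile
# only ever consumes difference vectors stored by tiles on strictly earlier
# diagonals. Values of diagonal tiles needed by an off-diagonal tile are
# recomputed locally from the sequence (they are self-contained), mirroring
# the init_diag duplication of the parallel design instead of stalling the
# wavefront.

#' Pad a sequence for tiling
#'
#' Appends the non-pairing sentinel \code{N} so the padded length is
#' n' = n + q - (n mod q), always a strict multiple of q (a full extra tile
#' is added when q already divides n). Because \code{N} never pairs, every
#' D(i, j) with j <= n is unchanged by padding.
#'
#' @param seq an [RnaSequence-class]
#' @param q tile width
#' @return padded [RnaSequence-class]
#' @examples
#' length(padSequence(randomRnaSequence(10, 1), 4))  # 12
#' @export
padSequence <- function(seq, q) {
  q <- as.integer(q)
  if (q < 1L) stop("'q' must be >= 1")
  n <- length(seq)
  np <- n + q - n %% q
  new("RnaSequence",
      bases = paste0(seq@bases, strrep("N", np - n)),
      name = seq@name)
}

#' Tile layout for a sequence length
#'
#' @param n sequence length
#' @param q tile width
#' @return a [TiledLayout-class]
#' @export
tileLayout <- function(n, q) {
  n <- as.integer(n); q <- as.integer(q)
  if (q < 1L || n < 1L) stop("'n' and 'q' must be >= 1")
  np <- n + q - n %% q
  new("TiledLayout", q = q, n = n, nPad = np, nTiles = np %/% q)
}

#' Diagonal wavefront schedule for a tile layout
#'
#' Diagonal d (0-based) lists every tile (tr, tc) of the upper tile
#' triangle with tc - tr = d, in tile-row order. The schedule has exactly
#' nTiles diagonals and every tile appears once.
#'
#' @param layout a [TiledLayout-class]
#' @return a [WavefrontSchedule-class]
#' @export
buildSchedule <- function(layout) {
  stopifnot(is(layout, "TiledLayout"))
  nt <- layout@nTiles
  diagonals <- lapply(0:(nt - 1L), function(d) {
    tr <- 0:(nt - 1L - d)
    cbind(tr = tr, tc = tr + d)
  })
  new("WavefrontSchedule", layout = layout, diagonals = diagonals)
}

setMethod("show", "TiledLayout", function(object) {
  cat(sprintf("TiledLayout: n = %d, q = %d, nPad = %d, %d x %d tile grid\n",
              object@n, object@q, object@nPad, object@nTiles, object@nTiles))
})

setMethod("show", "WavefrontSchedule", function(object) {
  sizes <- vapply(object@diagonals, nrow, integer(1L))
  cat(sprintf("WavefrontSchedule: %d diagonals, tile counts %s\n",
              length(sizes), paste(sizes, collapse = " ")))
})

# plain Nussinov on the self-contained block a (positions a*q+1..(a+1)*q of
# the padded sequence); returns the local table, local traceback (absolute
# k) and the number of split terms evaluated
localBlock <- function(sp, a, q, pmat, minLoop) {
  off <- a * q
  DL <- matrix(0, q, q + 1L)       # DL[r - off, c - off + 1] = D(r, c)
  opL <- matrix(TRACE_LEAF, q, q)
  kL <- matrix(0L, q, q)
  cand <- 0
  if (q >= 2L) for (lj in 2:q) {
    j <- off + lj
    for (li in (lj - 1L):1L) {
      i <- off + li
      ks <- (li + 1L):lj
      c2 <- DL[li, ks] + DL[ks, lj + 1L]
      cand <- cand + length(ks)
      w <- which.max(c2)
      best <- c2[w]; op <- TRACE_SPLIT; bk <- off + ks[w]
      if (pmat[sp[i], sp[j]] == 1L && (j - i - 1L) >= minLoop) {
        v1 <- 1 + DL[li + 1L, lj]
        if (v1 >= best) { best <- v1; op <- TRACE_PAIRED; bk <- 0L }
      }
      DL[li, lj + 1L] <- best
      opL[li, lj] <- op
      kL[li, lj] <- bk
    }
  }
  list(D = DL, op = opL, k = kL, cand = cand)
}

#' Tiled diagonal-wavefront folding
#'
#' Decomposes the padded DP table into q x q tiles (see
#' [TiledLayout-class]) and fills them one tile-diagonal at a time. Within
#' a diagonal the tiles are processed in a seed-shuffled order; because
#' every tile consumes only (a) difference vectors stored by tiles on
#' strictly earlier diagonals, (b) locally recomputed values of the
#' self-contained diagonal blocks, and (c) its own cells, the result is
#' bit-identical for every processing order -- the serial, testable core of
#' the parallel design. A dynamic access guard counts any read of a vector
#' stored by a tile on the same or a later diagonal
#' (\code{opStats(x)$guardViolations}; always 0 for a correct schedule).
#'
#' The table restricted to positions 1..n is cell-identical to
#' [nussinovFold()]'s.
#'
#' @inheritParams twoVectorFold
#' @param shuffleSeed integer seed for the within-diagonal tile order, or
#'   \code{NULL} for tile-row order
#' @return a [FoldResult-class]
#' @export
tiledFold <- function(seq, q = 4L, rule = pairingRule(), shuffleSeed = NULL) {
  q <- as.integer(q)
  if (is.na(q) || q < 1L || q > 12L) stop("'q' must be an integer in 1..12")
  n <- length(seq)
  layout <- tileLayout(n, q)
  np <- layout@nPad; nt <- layout@nTiles
  sched <- buildSchedule(layout)
  padded <- padSequence(seq, q)
  sp <- seqCodes(padded)
  pmat <- rule@pairs; minLoop <- rule@minLoop

  tab <- buildPrecompTable(q)
  Rmax <- tab@max; Rarg <- tab@argmax
  nq <- 2L^q
  p2 <- if (q > 1L) 2^(1:(q - 1L)) else numeric(0L)
  popcount <- vapply(0:(nq - 1L), function(cd)
    sum(bitwAnd(cd %/% 2L^(0:(q - 1L)), 1L)), numeric(1L))

  Dm <- matrix(0, np + 1L, np + 1L)
  traceOp <- matrix(TRACE_LEAF, np, np)
  traceK <- matrix(0L, np, np)
  Hc <- matrix(NA_integer_, np, nt); Hi <- matrix(NA_real_, np, nt)
  Vc <- matrix(NA_integer_, nt, np); Vi <- matrix(NA_real_, nt, np)
  cand <- 0; lks <- 0; guardViolations <- 0L

  # guard: a read of vectors produced by tile (ptr, ptc) from the tile
  # currently on diagonal d must see a strictly earlier, already-stored
  # diagonal
  checkRead <- function(ptr, ptc, d, stored) {
    bad <- sum((ptc - ptr) >= d | !stored)
    if (bad > 0L) guardViolations <<- guardViolations + bad
    invisible(NULL)
  }

  for (d in 0:(nt - 1L)) {
    tiles <- sched@diagonals[[d + 1L]]
    ord <- seq_len(nrow(tiles))
    if (!is.null(shuffleSeed) && length(ord) > 1L)
      ord <- withLocalSeed(as.integer(shuffleSeed) + d, sample(ord))
    for (t in ord) {
      tr <- tiles[t, 1L]; tc <- tiles[t, 2L]
      if (tr == tc) {
        # diagonal tile: self-contained plain Nussinov on its block
        L <- localBlock(sp, tr, q, pmat, minLoop)
        cand <- cand + L$cand
        off <- tr * q
        rows <- (off + 1L):(off + q)
        Dm[rows, (off + 1L):(off + q + 1L)] <- L$D
        traceOp[rows, rows] <- L$op
        traceK[rows, rows] <- L$k
        next
      }
      # off-diagonal tile: rows tr*q+1..(tr+1)q, columns tc*q..(tc+1)q-1
      loR <- tr * q + 1L; hiR <- (tr + 1L) * q
      loC <- tc * q; hiC <- (tc + 1L) * q - 1L
      Ltr <- localBlock(sp, tr, q, pmat, minLoop)
      Ltc <- localBlock(sp, tc, q, pmat, minLoop)
      cand <- cand + Ltr$cand + Ltc$cand
      Lmid <- NULL
      if (d == 2L) {
        Lmid <- localBlock(sp, tr + 1L, q, pmat, minLoop)
        cand <- cand + Lmid$cand
      }
      glo <- tr + 1L; ghi <- tc - 1L
      for (j in loC:hiC) {
        jj <- j + 1L
        for (i in hiR:loR) {
          if (j <= i) next                       # lone corner j == i: leaf
          best <- -Inf; op <- TRACE_SPLIT; bk <- 0L
          if (i + 1L <= hiR) {                   # residual in own row block
            ks <- (i + 1L):hiR
            c2 <- Ltr$D[i - tr * q, ks - tr * q] + Dm[ks, jj]
            cand <- cand + length(ks)
            w <- which.max(c2); best <- c2[w]; bk <- ks[w]
          }
          if (glo <= ghi) {                      # full groups between blocks
            gs <- glo:ghi
            gi <- gs + 1L
            hc <- Hc[i, gi]; vc <- Vc[gi, j]
            checkRead(tr, gs, d, !is.na(hc))     # h vectors from tiles (tr, g)
            checkRead(gs, tc, d, !is.na(vc))     # v vectors from tiles (g, tc)
            fl <- hc * nq + vc + 1L
            cg <- Hi[i, gi] + Vi[gi, j] + Rmax[fl]
            lks <- lks + length(gs)
            w <- which.max(cg)
            if (cg[w] > best) {
              best <- cg[w]
              bk <- gs[w] * q + 1L + Rarg[fl[w]]
            }
          }
          if (loC + 1L <= j) {                   # residual in own col block
            ks <- (loC + 1L):j
            c2 <- Dm[i, ks] + Ltc$D[ks - tc * q, j - tc * q + 1L]
            cand <- cand + length(ks)
            w <- which.max(c2)
            if (c2[w] > best) { best <- c2[w]; bk <- ks[w] }
          }
          if (pmat[sp[i], sp[j]] == 1L && (j - i - 1L) >= minLoop) {
            d1 <- if (i + 1L <= hiR && j - 1L >= loC) {
              Dm[i + 1L, j]                      # inner cell of this tile
            } else if (i + 1L > hiR) {           # i is the bottom tile row
              if (j - 1L >= loC) {
                if (tr + 1L == tc) Ltc$D[1L, j - tc * q]
                else {
                  checkRead(tr + 1L, tc, d, !is.na(Vc[tr + 2L, j - 1L]))
                  Vi[tr + 2L, j - 1L]            # D((tr+1)q+1, j-1)
                }
              } else if (d == 2L) {
                Lmid$D[1L, q]                    # corner via middle block
              } else {
                checkRead(tr + 1L, tc - 1L, d, !is.na(Vc[tr + 2L, j - 1L]))
                Vi[tr + 2L, j - 1L]
              }
            } else {                             # j is the first tile column
              if (tc - 1L == tr) Ltr$D[i + 1L - tr * q, j - tr * q]
              else {
                # last cell of column group tc-1 in row i+1, reconstructed
                # from that group's stored initial value and code
                checkRead(tr, tc - 1L, d, !is.na(Hc[i + 1L, tc]))
                Hi[i + 1L, tc] + popcount[Hc[i + 1L, tc] + 1L]
              }
            }
            v1 <- 1 + d1
            if (v1 >= best) { best <- v1; op <- TRACE_PAIRED; bk <- 0L }
          }
          Dm[i, jj] <- best
          traceOp[i, j] <- op
          traceK[i, j] <- bk
        }
      }
      # tile complete: store only its difference vectors (plus initial
      # values), the data later diagonals are allowed to consume
      rows <- loR:hiR
      blk <- Dm[rows, (loC + 1L):(hiC + 1L), drop = FALSE]
      dH <- if (q > 1L)
        blk[, 2:q, drop = FALSE] - blk[, 1:(q - 1L), drop = FALSE]
      else matrix(0, q, 0L)
      hcodes <- as.integer(dH %*% p2)
      if (q == 1L) hcodes <- integer(q)
      Hc[rows, tc + 1L] <- hcodes
      Hi[rows, tc + 1L] <- blk[, 1L]
      dV <- if (q > 1L)
        blk[1:(q - 1L), , drop = FALSE] - blk[2:q, , drop = FALSE]
      else matrix(0, 0L, q)
      vcodes <- as.integer(p2 %*% dV)
      if (q == 1L) vcodes <- integer(q)
      Vc[tr + 1L, loC:hiC] <- vcodes
      Vi[tr + 1L, loC:hiC] <- blk[1L, ]
    }
  }

  stats <- list(candidateEvaluations = cand, tableLookups = lks,
                guardViolations = guardViolations, nPad = np,
                shuffleSeed = if (is.null(shuffleSeed)) NA_integer_
                              else as.integer(shuffleSeed))
  newFoldResult("tiled", seq, rule, q,
                Dm[seq_len(n + 1L), seq_len(n + 1L), drop = FALSE],
                traceOp[seq_len(n), seq_len(n), drop = FALSE],
                traceK[seq_len(n), seq_len(n), drop = FALSE],
                stats, tables = list(layout = layout))
}
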