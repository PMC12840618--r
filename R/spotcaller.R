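# Focal hotspot calling and TMC coldfield matching on a 5x5 grid.
#
# A hotspot is a single bin pair whose count stands out focally from a low
# local background: within the 5x5 grid centered on it (corners excluded,
# 21 cells kept) the center must reach `min_center` contacts, exceed the
# second-highest retained cell by the `excess` factor, and the background
# median must stay below `median_frac` of the center. A coldfield is the
# position along the matrix diagonal (separation preserved) minimising
# TMC = max^1.3 x median over the full 5x5 grid.

# relative cell coordinates of the 5x5 grid, row = anchor-1 shift (a),
# col = anchor-2 shift (b)
grid_cells <- function() {
  cells <- as.matrix(expand.grid(a = -2:2, b = -2:2))
  storage.mode(cells) <- "integer"
  cells
}

#' Grid cells retained by the hotspot criteria
#'
#' The 5x5 evaluation grid drops its 4 corner cells, leaving 21 cells: the
#' center plus a 20-cell local background.
#'
#' @return Integer matrix of relative (row, col) offsets in `-2..2`, one row
#'   per retained cell.
#' @export
grid_retained_cells <- function() {
  cells <- grid_cells()
  corner <- abs(cells[, "a"]) == 2L & abs(cells[, "b"]) == 2L
  cells[!corner, , drop = FALSE]
}

#' Diagonal offsets searched for a coldfield
#'
#' Candidate coldfield centers sit at diagonal displacements
#' `0, +/-step_bins, ..., +/-(n_positions - 1) * step_bins` from the hotspot
#' (both anchors shifted equally, preserving genomic separation). With the
#' defaults (step 5 bins, 20 positions per direction at 600 bp bins) the
#' search spans +/-95 bins = +/-57 kb.
#'
#' @param step_bins diagonal step between candidates, in bins.
#' @param n_positions candidate positions per direction (offset 0 included).
#' @return Sorted integer vector of diagonal offsets in bins.
#' @export
coldfield_offsets <- function(step_bins = 5L, n_positions = 20L) {
  stopifnot(step_bins >= 1, n_positions >= 1)
  k <- seq_len(n_positions) - 1L
  sort(unique(c(-k, k) * as.integer(step_bins)))
}

#' Extract the 5x5 count grid centered on a bin pair
#'
#' Missing sparse keys read as 0. Centers within 2 bins of a chromosome
#' start/end cannot host a full grid and return `NULL` (the candidate is
#' skipped, not an error).
#'
#' @param map a [bin_contacts()] map.
#' @param chrom chromosome name.
#' @param bin_i,bin_j 0-based bin indices of the center (`bin_i <= bin_j`).
#' @return 5x5 integer matrix (rows: `bin_i - 2 .. bin_i + 2`, cols:
#'   `bin_j - 2 .. bin_j + 2`), or `NULL` near a chromosome edge.
#' @export
extract_grid <- function(map, chrom, bin_i, bin_j) {
  stopifnot(inherits(map, "binned_contact_map"))
  nb <- map$nbins[chrom]
  if (is.na(nb)) nb <- max(bin_j + 3L, map$nbins[chrom], na.rm = TRUE)
  if (bin_i < 2L || bin_j > nb - 3L) return(NULL)
  cells <- grid_cells()
  q <- data.table(chrom = chrom,
                  bin_i = bin_i + cells[, "a"],
                  bin_j = bin_j + cells[, "b"])
  v <- map$counts[q, on = .(chrom, bin_i, bin_j)]$count
  v[is.na(v)] <- 0L
  matrix(v, 5L, 5L,
         dimnames = list(bin_i + -2:2, bin_j + -2:2))
}

# slack absorbing binary floating error in excess * second_max
.excess_eps <- 1e-9

#' Hotspot predicate on a 5x5 grid
#'
#' With the 4 corners excluded, a center qualifies as a focal hotspot when
#' (i) it has at least `min_center` contacts, (ii) it reaches at least
#' `excess` times the second-highest retained cell (the maximum over the 20
#' non-center retained cells, inclusive comparison), and (iii) the median of
#' those 20 background cells is strictly below `median_frac` of the center.
#'
#' @param grid 5x5 matrix from [extract_grid()].
#' @param min_center minimum center count.
#' @param excess multiplicative excess over the second-highest value.
#' @param median_frac strict upper bound on background median / center.
#' @return `TRUE`/`FALSE`.
#' @export
is_hotspot <- function(grid, min_center = 5, excess = 1.2, median_frac = 0.4) {
  if (is.null(grid)) return(FALSE)
  stopifnot(is.matrix(grid), all(dim(grid) == 5L))
  center <- grid[3L, 3L]
  keep <- grid[grid_retained_cells() + 3L]
  bg <- keep[-which(grid_retained_cells()[, 1L] == 0L &
                      grid_retained_cells()[, 2L] == 0L)]
  second_max <- max(bg)
  center >= min_center &&
    center >= excess * second_max - .excess_eps &&
    stats::median(bg) < median_frac * center
}

#' TMC depletion score of a 5x5 grid
#'
#' `TMC = max(grid)^exponent * median(grid)` over all 25 cells (no corner
#' exclusion here -- the corner rule belongs to the hotspot criteria only).
#' Low TMC marks an extended contact-depleted region; an all-zero grid
#' scores 0.
#'
#' @param grid 5x5 matrix.
#' @param exponent power applied to the maximum (default 1.3).
#' @return Numeric scalar.
#' @export
tmc <- function(grid, exponent = 1.3) {
  stopifnot(is.matrix(grid), all(dim(grid) == 5L))
  max(grid)^exponent * stats::median(grid)
}

#' Find the matched coldfield of one hotspot
#'
#' Evaluates TMC at every diagonal offset from [coldfield_offsets()] (both
#' bin indices shifted equally, so genomic separation is preserved) and
#' returns the candidate with minimal TMC. Ties are broken by the smallest
#' absolute offset, then by the negative offset. Candidates whose grid falls
#' off a chromosome end are skipped; if all do, `NULL` is returned and the
#' hotspot is dropped from paired output.
#'
#' @param map a [bin_contacts()] map.
#' @param hotspot list/row with `chrom`, `bin_i`, `bin_j` (hotspot center).
#' @param step_bins,n_positions search geometry, see [coldfield_offsets()].
#' @param tmc_exponent exponent of the TMC score.
#' @return list with `chrom`, `bin_i`, `bin_j`, `tmc`, `offset_bins`, or
#'   `NULL` if no candidate grid fits on the chromosome.
#' @export
find_coldfield <- function(map, hotspot, step_bins = 5L, n_positions = 20L,
                           tmc_exponent = 1.3) {
  offs <- coldfield_offsets(step_bins, n_positions)
  best <- NULL
  for (o in offs) {
    g <- extract_grid(map, hotspot$chrom, hotspot$bin_i + o, hotspot$bin_j + o)
    if (is.null(g)) next
    v <- tmc(g, tmc_exponent)
    if (is.null(best) || v < best$tmc ||
        (v == best$tmc && (abs(o) < abs(best$offset_bins) ||
                           (abs(o) == abs(best$offset_bins) && o < best$offset_bins)))) {
      best <- list(chrom = hotspot$chrom,
                   bin_i = hotspot$bin_i + o, bin_j = hotspot$bin_j + o,
                   tmc = v, offset_bins = o)
    }
  }
  best
}

# Vectorised per-chromosome calling engine. `ct` is the nonzero-count table
# of one chromosome; returns the hot/cold pair table for that chromosome.
call_chrom <- function(ct, chrom, nbins, min_center, excess, median_frac,
                       tmc_exponent, step_bins, n_positions) {
  dvals <- ct$bin_j - ct$bin_i
  d_lo <- min(dvals) - 4L
  d_hi <- max(dvals) + 4L
  M <- matrix(0L, nrow = nbins, ncol = d_hi - d_lo + 1L)
  M[cbind(ct$bin_i + 1L, dvals - d_lo + 1L)] <- ct$count

  cells <- grid_cells()
  corner <- abs(cells[, "a"]) == 2L & abs(cells[, "b"]) == 2L
  is_center <- cells[, "a"] == 0L & cells[, "b"] == 0L
  bg_cols <- which(!corner & !is_center)   # the 20 background cells

  lookup <- function(i, d, keep) {
    # 25-column cell matrix for candidate centers (i, i + d)
    V <- matrix(0L, length(i), sum(keep))
    kk <- which(keep)
    for (c2 in seq_along(kk)) {
      a <- cells[kk[c2], "a"]; b <- cells[kk[c2], "b"]
      V[, c2] <- M[cbind(i + a + 1L, d + (b - a) - d_lo + 1L)]
    }
    V
  }
  row_median <- function(V) {
    n <- ncol(V)
    S <- apply(V, 1L, sort.int, method = "quick")  # n x nrow matrix
    if (n %% 2L == 1L) S[(n + 1L) %/% 2L, ] else
      (S[n %/% 2L, ] + S[n %/% 2L + 1L, ]) / 2
  }

  ## hotspot pass: every nonzero in-band bin pair is a candidate, minus edges
  cand <- ct[bin_i >= 2L & bin_j <= nbins - 3L]
  if (!nrow(cand)) return(NULL)
  ci <- cand$bin_i
  cd <- cand$bin_j - cand$bin_i
  V <- lookup(ci, cd, !corner)
  ctr_col <- which(!corner)          # positions within retained columns
  center <- V[, match(which(is_center), which(!corner))]
  BG <- V[, match(bg_cols, which(!corner)), drop = FALSE]
  smax <- Reduce(pmax, asplit(BG, 2L))
  bmed <- row_median(BG)
  hot <- which(center >= min_center &
                 center >= excess * smax - .excess_eps &
                 bmed < median_frac * center)
  if (!length(hot)) return(NULL)
  H <- data.table(chrom = chrom, hot_bin1 = ci[hot], hot_bin2 = cand$bin_j[hot],
                  center_count = center[hot], second_max = smax[hot],
                  background_median = bmed[hot])

  ## coldfield pass: all offsets for all hotspots at once
  offs <- coldfield_offsets(step_bins, n_positions)
  n_h <- nrow(H)
  n_o <- length(offs)
  hi <- rep(H$hot_bin1, each = n_o)
  hd <- rep(H$hot_bin2 - H$hot_bin1, each = n_o)
  oo <- rep(offs, times = n_h)
  valid <- (hi + oo) >= 2L & (hi + hd + oo) <= nbins - 3L
  tmc_v <- rep(NA_real_, n_h * n_o)
  if (any(valid)) {
    Vc <- lookup(hi[valid] + oo[valid], hd[valid], rep(TRUE, 25L))
    mx <- Reduce(pmax, asplit(Vc, 2L))
    md <- row_median(Vc)
    tmc_v[valid] <- mx^tmc_exponent * md
  }
  sel <- data.table(h = rep(seq_len(n_h), each = n_o), off = oo,
                    tmc_val = tmc_v)[!is.na(tmc_val)]
  if (!nrow(sel)) return(NULL)   # no hotspot has any on-chromosome candidate
  sel[, abs_off := abs(off)]
  setorder(sel, h, tmc_val, abs_off, off)
  best <- sel[, .SD[1L], by = h]
  dropped <- setdiff(seq_len(n_h), best$h)
  if (length(dropped)) {
    message(length(dropped), " hotspot(s) dropped on ", chrom,
            ": coldfield search fell off the chromosome")
  }
  out <- H[best$h]
  out[, `:=`(cold_bin1 = hot_bin1 + best$off,
             cold_bin2 = hot_bin2 + best$off,
             tmc = best$tmc_val,
             offset_bins = best$off)]
  out
}

#' Call all hotspots and their matched coldfields
#'
#' Every nonzero bin pair of the map is tested against the hotspot criteria
#' (candidates within 2 bins of a chromosome end are skipped); each hotspot
#' is then paired with exactly one coldfield by diagonal TMC minimisation.
#' Output is deterministic given the map.
#'
#' @param map a [bin_contacts()] map (600 bp bins in the reference analysis).
#' @param min_center,excess,median_frac hotspot criteria, see [is_hotspot()].
#' @param tmc_exponent TMC exponent, see [tmc()].
#' @param step_bins,n_positions coldfield search, see [coldfield_offsets()].
#' @return `data.table` of class `"hotcold_pairs"`: `chrom`, `hot_bin1`,
#'   `hot_bin2`, `center_count`, `second_max`, `background_median`,
#'   `cold_bin1`, `cold_bin2`, `tmc`, `offset_bins`; attribute `bin_size`.
#' @export
call_all <- function(map, min_center = 5, excess = 1.2, median_frac = 0.4,
                     tmc_exponent = 1.3, step_bins = 5L, n_positions = 20L) {
  stopifnot(inherits(map, "binned_contact_map"))
  empty <- data.table(chrom = character(), hot_bin1 = integer(),
                      hot_bin2 = integer(), center_count = integer(),
                      second_max = integer(), background_median = numeric(),
                      cold_bin1 = integer(), cold_bin2 = integer(),
                      tmc = numeric(), offset_bins = integer())
  res <- if (nrow(map$counts)) {
    parts <- lapply(split(map$counts, by = "chrom", sorted = TRUE), function(ct) {
      chrom <- ct$chrom[1L]
      call_chrom(ct, chrom, map$nbins[[chrom]], min_center, excess,
                 median_frac, tmc_exponent, step_bins, n_positions)
    })
    rbindlist(c(list(empty), parts), use.names = TRUE)
  } else {
    empty
  }
  setorder(res, chrom, hot_bin1, hot_bin2)
  setattr(res, "bin_size", map$bin_size)
  setattr(res, "class", c("hotcold_pairs", class(res)))
  res[]
}
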