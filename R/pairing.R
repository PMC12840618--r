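# Sliding-window homotypic/heterotypic TE pairing at contact anchors.
#
# Around each anchor, 21 windows of 2 kb at 50% overlap span -11..+11 kb;
# the center window covers -1..+1 kb around the contact point. A family
# "present" in window w at both anchors of a contact contributes one
# (presence-based) pairing count for that window: homotypic when the two
# families match, heterotypic otherwise.

#' Sliding-window specification around a contact anchor
#'
#' Windows of `width` bp advance by `step` bp (50% overlap with the
#' defaults); window centers run from `-(span - width/2)` to
#' `+(span - width/2)` so window edges span `-span .. +span`. The defaults
#' give 21 windows across +/-11 kb with the center window covering
#' `[-1000, +1000]`.
#'
#' @param width window width in bp.
#' @param step distance between window centers in bp.
#' @param span outermost window edge in bp.
#' @return `data.table` of class `"window_spec"`: `window` (1-based index),
#'   `offset` (window center), `lo`, `hi` (inclusive edges).
#' @export
make_windows <- function(width = 2000L, step = 1000L, span = 11000L) {
  stopifnot(width > 0, step > 0, span >= width / 2)
  half <- width %/% 2L
  offsets <- seq.int(-(span - half), span - half, by = step)
  w <- data.table(window = seq_along(offsets),
                  offset = as.integer(offsets),
                  lo = as.integer(offsets - half),
                  hi = as.integer(offsets + half))
  setattr(w, "width", as.integer(width))
  setattr(w, "step", as.integer(step))
  setattr(w, "span", as.integer(span))
  setattr(w, "class", c("window_spec", class(w)))
  w[]
}

#' Assign TEs near an anchor to sliding windows
#'
#' Membership is by element center, inclusive on both window edges; a TE
#' center interior to the span falls in two overlapping windows, and one
#' sitting exactly on the 1 kb offset lattice falls in three (both
#' edge-sharing neighbours included -- inclusive bounds are applied
#' consistently).
#'
#' @param tes TE records near the anchor (e.g. from [query_flank()]); needs
#'   `family`, `strand`, `center`.
#' @param anchor_pos anchor position in bp (same coordinate system as the
#'   TE centers).
#' @param windows a [make_windows()] spec.
#' @return `data.table`: `window`, `family`, `strand`, `rel` (center minus
#'   anchor), one row per (element, window) membership.
#' @export
assign_windows <- function(tes, anchor_pos, windows = make_windows()) {
  tes <- as.data.table(tes)
  if (!nrow(tes)) {
    return(data.table(window = integer(), family = character(),
                      strand = character(), rel = integer()))
  }
  rel <- as.integer(tes$center - anchor_pos)
  out <- lapply(seq_len(nrow(windows)), function(wi) {
    inw <- rel >= windows$lo[wi] & rel <= windows$hi[wi]
    if (!any(inw)) return(NULL)
    data.table(window = windows$window[wi], family = tes$family[inw],
               strand = tes$strand[inw], rel = rel[inw])
  })
  res <- rbindlist(out)
  if (!nrow(res)) {
    res <- data.table(window = integer(), family = character(),
                      strand = character(), rel = integer())
  }
  res[]
}

new_pairing_table <- function(windows = make_windows()) {
  structure(list(
    counts = data.table(context = character(), fam_a = character(),
                        fam_b = character(), window = integer(),
                        count = integer()),
    strand = data.table(context = character(), hh = integer(), ht = integer()),
    n_contacts = c(hot = 0L, cold = 0L),
    windows = windows
  ), class = "pairing_table")
}

compress_pairing_table <- function(tab) {
  tab$counts <- tab$counts[, .(count = sum(count)),
                           by = .(context, fam_a, fam_b, window)]
  setorder(tab$counts, context, fam_a, fam_b, window)
  tab$strand <- tab$strand[, .(hh = sum(hh), ht = sum(ht)), by = context]
  tab
}

#' Add one contact's window maps to a pairing table
#'
#' For each window index `w`, every unordered family pair `(A, B)` with `A`
#' present in anchor 1's window `w` and `B` in anchor 2's window `w` (or
#' vice versa) is incremented by 1 -- presence-based counting, one increment
#' per contact per window per family pair, regardless of copy number.
#' Homotypic pairings are the `A == B` cells. Strand orientation is tallied
#' at the element-pair level for homotypic pairs: opposite strands count as
#' head--head, equal strands as head--tail.
#'
#' @param anchor1_windows,anchor2_windows window maps from
#'   [assign_windows()], built with the same window spec.
#' @param context `"hot"` or `"cold"`.
#' @param table a `"pairing_table"` to update (default: new empty table).
#' @return The updated `"pairing_table"`.
#' @export
count_pairings <- function(anchor1_windows, anchor2_windows,
                           context = c("hot", "cold"),
                           table = new_pairing_table()) {
  context <- match.arg(context)
  stopifnot(inherits(table, "pairing_table"))
  u1 <- unique(as.data.table(anchor1_windows)[, .(window, family)])
  u2 <- unique(as.data.table(anchor2_windows)[, .(window, family)])
  if (nrow(u1) && nrow(u2)) {
    m <- u1[u2, on = "window", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(m)) {
      inc <- unique(m[, .(window,
                          fam_a = pmin(family, i.family),
                          fam_b = pmax(family, i.family))])
      inc[, `:=`(context = context, count = 1L)]
      table$counts <- rbind(table$counts, inc[, names(table$counts), with = FALSE])
    }
  }
  e1 <- as.data.table(anchor1_windows)
  e2 <- as.data.table(anchor2_windows)
  if (nrow(e1) && nrow(e2)) {
    ep <- e1[e2, on = .(window, family), nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(ep)) {
      table$strand <- rbind(table$strand,
                            data.table(context = context,
                                       hh = sum(ep$strand != ep$i.strand),
                                       ht = sum(ep$strand == ep$i.strand)))
    }
  }
  table$n_contacts[context] <- table$n_contacts[context] + 1L
  compress_pairing_table(table)
}

#' Pairing counts for all hot/cold pairs against a TE index
#'
#' Batch equivalent of [query_flank()] + [assign_windows()] +
#' [count_pairings()] over every hotspot and coldfield anchor of a call set.
#' Anchor positions are the bin midpoints (`bin * bin_size + bin_size/2`).
#'
#' @param calls a [call_all()] table.
#' @param index a [build_te_index()] (or TE records, indexed on the fly).
#' @param windows a [make_windows()] spec (window width must equal twice the
#'   step, as in the reference 50%-overlap design).
#' @param flank flank half-width in bp used for the TE query.
#' @param bin_size bin size in bp; defaults to the call set's.
#' @return A `"pairing_table"`: `counts` (long table context / fam_a /
#'   fam_b / window / count), `strand` (head--head and head--tail element
#'   pair tallies per context), `n_contacts`, `windows`.
#' @export
pairing_counts <- function(calls, index, windows = make_windows(),
                           flank = 11000L, bin_size = NULL) {
  stopifnot(nrow(windows) >= 1)
  if (!inherits(index, "te_index")) index <- build_te_index(index)
  bin_size <- bin_size %||% attr(calls, "bin_size") %||% 600L
  tab <- new_pairing_table(windows)
  if (!nrow(calls)) return(tab)
  half <- bin_size %/% 2L

  anchors <- rbind(
    data.table(context = "hot", pair_id = seq_len(nrow(calls)), side = 1L,
               chrom = calls$chrom, pos = calls$hot_bin1 * bin_size + half),
    data.table(context = "hot", pair_id = seq_len(nrow(calls)), side = 2L,
               chrom = calls$chrom, pos = calls$hot_bin2 * bin_size + half),
    data.table(context = "cold", pair_id = seq_len(nrow(calls)), side = 1L,
               chrom = calls$chrom, pos = calls$cold_bin1 * bin_size + half),
    data.table(context = "cold", pair_id = seq_len(nrow(calls)), side = 2L,
               chrom = calls$chrom, pos = calls$cold_bin2 * bin_size + half)
  )
  anchors[, aid := .I]

  hits <- query_flank_many(index, anchors, flank)
  if (!nrow(hits)) {
    tab$n_contacts <- c(hot = nrow(calls), cold = nrow(calls))
    return(tab)
  }
  hits <- anchors[, .(aid, context, pair_id, side)][hits, on = "aid"]

  ## window expansion by arithmetic (requires width == 2 * step)
  wd <- attr(windows, "width"); st <- attr(windows, "step")
  stopifnot(identical(wd, 2L * st))
  S <- max(windows$offset)
  hits[, `:=`(off_lo = pmax(-S, st * as.integer(ceiling((rel - st) / st))),
              n_off = NA_integer_)]
  hits[, n_off := pmin(S, st * (rel %/% st + 1L)) %/% st - off_lo %/% st + 1L]
  hits <- hits[n_off >= 1L]
  W <- hits[rep(seq_len(.N), n_off)]
  W[, off := off_lo + st * (rowid(aid, rec_id) - 1L)]
  W <- W[off >= -S & off <= S]
  W[, window := (off + S) %/% st + 1L]

  ## presence-based pairing counts
  P <- unique(W[, .(context, pair_id, side, window, family)])
  P1 <- P[side == 1L]; P2 <- P[side == 2L]
  M <- P1[P2, on = .(context, pair_id, window), nomatch = NULL,
          allow.cartesian = TRUE]
  if (nrow(M)) {
    M[, `:=`(fam_a = pmin(family, i.family), fam_b = pmax(family, i.family))]
    cnt <- unique(M[, .(context, pair_id, window, fam_a, fam_b)])[
      , .(count = .N), by = .(context, fam_a, fam_b, window)]
    tab$counts <- cnt[, .(context, fam_a, fam_b, window, count)]
  }

  ## element-level strand tally for homotypic pairs
  E1 <- W[side == 1L, .(context, pair_id, window, family, strand, rec_id)]
  E2 <- W[side == 2L, .(context, pair_id, window, family, strand, rec_id)]
  EP <- E1[E2, on = .(context, pair_id, window, family), nomatch = NULL,
           allow.cartesian = TRUE]
  if (nrow(EP)) {
    tab$strand <- EP[, .(hh = sum(strand != i.strand),
                         ht = sum(strand == i.strand)), by = context]
  }

  tab$n_contacts <- c(hot = nrow(calls), cold = nrow(calls))
  compress_pairing_table(tab)
}

#' @export
print.pairing_table <- function(x, ...) {
  cat("pairing table:", x$n_contacts["hot"], "hot /", x$n_contacts["cold"],
      "cold contacts;", nrow(x$counts), "count cells over",
      nrow(x$windows), "windows\n")
  invisible(x)
}

central_window <- function(windows) windows$window[windows$offset == 0L]

pair_count <- function(tab, ctx, fa, fb, win) {
  a <- pmin(fa, fb); b <- pmax(fa, fb)
  v <- tab$counts[context == ctx & fam_a == a & fam_b == b & window %in% win,
                  sum(count)]
  if (is.na(v)) 0L else v
}

#' Per-family pairing metrics: hot/cold ratio, heterotypic ratio, specificity
#'
#' For each family within the given windows (default: the central 2 kb
#' window only): the homotypic hot/cold ratio (homotypic counts at hotspots
#' over homotypic counts at coldfields), the heterotypic ratio (same, over
#' all pairs of the family with a *different* partner), and the specificity
#' index = homotypic ratio / heterotypic ratio. A zero denominator leaves
#' the metric `NA` and flags the family `defined = FALSE`; such families are
#' excluded from downstream correlation and clustering.
#'
#' @param table a `"pairing_table"`.
#' @param families families to report (default: all present); an unknown
#'   family is an error.
#' @param windows_idx window indices to sum over (default: central window).
#' @return `data.table`: family, homotypic/heterotypic counts per context,
#'   the three metrics, `defined`.
#' @export
family_metrics <- function(table, families = NULL, windows_idx = NULL) {
  stopifnot(inherits(table, "pairing_table"))
  known <- sort(unique(c(table$counts$fam_a, table$counts$fam_b)))
  if (is.null(families)) {
    families <- known
  } else if (!all(families %in% known)) {
    stop("unknown family: ",
         paste(setdiff(families, known), collapse = ", "))
  }
  win <- windows_idx %||% central_window(table$windows)
  res <- rbindlist(lapply(families, function(f) {
    cc <- table$counts[window %in% win]
    homo <- cc[fam_a == f & fam_b == f, .(n = sum(count)), by = context]
    het <- cc[xor(fam_a == f, fam_b == f), .(n = sum(count)), by = context]
    g <- function(d, ctx) { v <- d[context == ctx, n]; if (length(v)) v else 0L }
    hh <- g(homo, "hot"); hc <- g(homo, "cold")
    th <- g(het, "hot"); tc <- g(het, "cold")
    hot_cold_ratio <- if (hc > 0L) hh / hc else NA_real_
    heterotypic_ratio <- if (tc > 0L) th / tc else NA_real_
    spec <- if (!is.na(hot_cold_ratio) && !is.na(heterotypic_ratio) &&
                heterotypic_ratio > 0) hot_cold_ratio / heterotypic_ratio
            else NA_real_
    data.table(family = f, hot_homotypic = hh, cold_homotypic = hc,
               hot_heterotypic = th, cold_heterotypic = tc,
               hot_cold_ratio = hot_cold_ratio,
               heterotypic_ratio = heterotypic_ratio,
               specificity_index = spec,
               defined = !is.na(hot_cold_ratio))
  }))
  res[]
}

#' Pairwise hot/cold specificity matrix
#'
#' Entry `(A, B)` is the hot count over the cold count for the unordered
#' family pair `(A, B)` within the central window; the diagonal holds the
#' homotypic hot/cold ratios. Families are the `top_k` most abundant by
#' total pairing counts, and rows/columns are sorted by descending diagonal
#' value. Cells with zero cold counts are `NA`.
#'
#' @param table a `"pairing_table"`.
#' @param top_k number of families to include (6, 12, 26 and 30 are the
#'   sizes used in the reference figures).
#' @param families optional explicit family vector (overrides `top_k`).
#' @return Symmetric numeric matrix with `families` attribute.
#' @export
specificity_matrix <- function(table, top_k = 30L, families = NULL) {
  stopifnot(inherits(table, "pairing_table"))
  if (is.null(families)) {
    ab <- rbind(table$counts[, .(family = fam_a, count)],
                table$counts[, .(family = fam_b, count)])
    rank <- ab[, .(total = sum(count)), by = family][order(-total)]
    families <- head(rank$family, top_k)
  }
  k <- length(families)
  win <- central_window(table$windows)
  vals <- matrix(NA_real_, k, k, dimnames = list(families, families))
  for (i in seq_len(k)) {
    for (j in i:k) {
      h <- pair_count(table, "hot", families[i], families[j], win)
      c0 <- pair_count(table, "cold", families[i], families[j], win)
      vals[i, j] <- vals[j, i] <- if (c0 > 0L) h / c0 else NA_real_
    }
  }
  ord <- order(-diag(vals), is.na(diag(vals)))
  vals <- vals[ord, ord, drop = FALSE]
  structure(vals, families = rownames(vals), class = c("specificity_matrix",
                                                       class(vals)))
}

#' Head--head to head--tail orientation ratio of homotypic pairs
#'
#' Homotypic element pairs with opposite strands are classified head--head,
#' equal strands head--tail; the ratio of the two tallies is returned.
#' With zero head--tail pairs the ratio is undefined (`NA` with a warning).
#'
#' @param table a `"pairing_table"`.
#' @param context `"both"` (default), `"hot"`, or `"cold"`.
#' @return Numeric scalar (possibly `NA`).
#' @export
orientation_ratio <- function(table, context = c("both", "hot", "cold")) {
  context <- match.arg(context)
  stopifnot(inherits(table, "pairing_table"))
  s <- table$strand
  if (context != "both") s <- s[s$context == context]
  hh <- sum(s$hh); ht <- sum(s$ht)
  if (ht == 0L) {
    warning("no head-tail homotypic pairs; orientation ratio undefined")
    return(NA_real_)
  }
  hh / ht
}

#' Default TE family evolutionary ages
#'
#' Approximate family ages in Myr used for the age-vs-specificity
#' correlation. The MIR (~130 Myr) and Alu (~50 Myr) anchors are the
#' reference values; the remaining entries are literature-typical defaults
#' bundled for the synthetic families and editable by the caller.
#'
#' @return `data.table`: `family`, `age_myr`.
#' @export
default_age_table <- function() {
  data.table(
    family  = c("MIRb", "MIR3", "L2a", "L2b", "L1M5", "ERVL", "AluY",
                "AluSx", "SVA_D"),
    age_myr = c(130,    130,    150,   150,   100,    70,    50,
                55,     13)
  )
}

#' Map family names to superfamilies
#'
#' Aggregates verbatim annotation names (MIRb, MIR3, ...) into the
#' coarse superfamilies used for summary figures (ALU, L1, L2, MIR, ERVL,
#' SVA). Names with no configured prefix map to themselves.
#'
#' @param families character vector of family names.
#' @param map named character vector `prefix -> superfamily`.
#' @return Character vector of superfamily labels.
#' @export
superfamily_map <- function(families,
                            map = c(Alu = "ALU", L1 = "L1", L2 = "L2",
                                    MIR = "MIR", ERV = "ERVL", SVA = "SVA")) {
  out <- families
  for (p in names(map)) out[startsWith(families, p)] <- map[[p]]
  out
}

#' Pearson correlation between family age and homotypic specificity
#'
#' @param metrics a [family_metrics()] table.
#' @param ages an age table (`family`, `age_myr`); default
#'   [default_age_table()].
#' @param metric which metric to correlate with age
#'   (`"hot_cold_ratio"`, the default, or `"specificity_index"`).
#' @return list with `r` (Pearson correlation; `NA` with a warning when one
#'   side has zero variance) and `n` (families used). Fewer than 3 usable
#'   families is an error.
#' @export
age_correlation <- function(metrics, ages = default_age_table(),
                            metric = c("hot_cold_ratio", "specificity_index")) {
  metric <- match.arg(metric)
  m <- merge(as.data.table(metrics), as.data.table(ages), by = "family")
  m <- m[is.finite(m[[metric]]) & is.finite(m$age_myr)]
  if (nrow(m) < 3L) stop("need >= 3 families with defined metrics and ages")
  if (stats::sd(m$age_myr) == 0 || stats::sd(m[[metric]]) == 0) {
    warning("zero variance; age correlation undefined")
    return(list(r = NA_real_, n = nrow(m)))
  }
  list(r = stats::cor(m$age_myr, m[[metric]]), n = nrow(m))
}
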