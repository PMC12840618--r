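#' Extract a named homotypic-ratio vector from a metrics table
#'
#' @param metrics a [family_metrics()] table.
#' @param metric column to extract (default `"hot_cold_ratio"`).
#' @return Named numeric vector (family -> ratio), undefined families as
#'   `NA`.
#' @export
ratio_vector <- function(metrics, metric = "hot_cold_ratio") {
  m <- as.data.table(metrics)
  stats::setNames(m[[metric]], m$family)
}

#' Pearson correlation between two homotypic-ratio vectors
#'
#' Families undefined (non-finite) in either vector are removed pairwise
#' before correlating; at least 3 shared defined families are required.
#'
#' @param a,b named numeric vectors (family -> ratio), e.g. from
#'   [ratio_vector()] on two datasets.
#' @return list with `r` (Pearson correlation) and `n` (shared families).
#' @export
correlate_ratios <- function(a, b) {
  shared <- intersect(names(a)[is.finite(a)], names(b)[is.finite(b)])
  if (length(shared) < 3L) {
    stop("need >= 3 shared defined families; got ", length(shared))
  }
  list(r = stats::cor(a[shared], b[shared]), n = length(shared))
}

#' Hierarchically cluster family ratio profiles
#'
#' Average-linkage agglomeration on Euclidean distances between family
#' profiles. Input is a datasets x families matrix of homotypic hot/cold
#' ratios (one row per dataset, one column per family); families whose
#' profile contains a non-finite value are dropped with a warning. Leaf
#' order is deterministic given the input (stats::hclust breaks ties by
#' input order).
#'
#' @param mat numeric matrix, datasets in rows, families in columns.
#' @param method linkage (default `"average"`).
#' @return list of class `"family_clustering"`: `tree` (an `hclust`),
#'   `order` (family labels in leaf order), `dropped` (families removed).
#' @export
cluster_families <- function(mat, method = "average") {
  stopifnot(is.matrix(mat))
  bad <- colnames(mat)[!apply(is.finite(mat), 2L, all)]
  if (length(bad)) {
    warning("dropping ", length(bad), " family(ies) with undefined ratios: ",
            paste(bad, collapse = ", "))
    mat <- mat[, setdiff(colnames(mat), bad), drop = FALSE]
  }
  if (ncol(mat) < 2L) stop("need >= 2 families with defined profiles")
  tree <- stats::hclust(stats::dist(t(mat), method = "euclidean"),
                        method = method)
  structure(list(tree = tree, order = tree$labels[tree$order], dropped = bad),
            class = "family_clustering")
}

#' @export
print.family_clustering <- function(x, ...) {
  cat("family clustering (", x$tree$method, " linkage): ",
      length(x$order), " leaves\n", sep = "")
  cat("leaf order:", paste(x$order, collapse = ", "), "\n")
  invisible(x)
}

#' Misbinning negative control
#'
#' Runs binning and hotspot/coldfield calling on the standard lattice, then
#' repeats the TE-pairing phase with anchor coordinates reconstructed from
#' the *wrong* bin size: each anchor at bin index `i` is placed at
#' `i * bin_size + bin_size/2` with `bin_size = 580` instead of 600. The
#' 20 bp-per-bin error accumulates along the chromosome (tens of kb at Mb
#' positions), effectively reshuffling the anchor coordinates relative to
#' the TE annotation, so a genuine focal pairing signal at position zero
#' must vanish; a signal that survives this control would indicate a
#' pipeline artifact. With `bin_size = 600` the control arm reproduces the
#' standard pipeline exactly.
#'
#' @param pairs_path path to a `.pairs`(.gz) file.
#' @param te TE records, a `"te_catalog"`, a `"te_index"`, or a BED path.
#' @param bin_size wrong bin size used for coordinate reconstruction in the
#'   pairing phase (default 580).
#' @param plan a [sampling_plan()].
#' @param config a [pipeline_config()] (its `bin_size` stays in force for
#'   binning and spot calling).
#' @param verbose emit per-stage messages.
#' @return list: `profile` (`data.table` window / offset / hot / cold total
#'   homotypic counts under the misbinned coordinates), `metrics`
#'   (per-family [family_metrics()] under the misbinned coordinates),
#'   `table` (the misbinned `"pairing_table"`), `pipeline` (the
#'   standard-lattice [run_pipeline()] result), `bin_size`.
#' @export
misbin_control <- function(pairs_path, te, bin_size = 580L,
                           plan = sampling_plan(),
                           config = pipeline_config(), verbose = FALSE) {
  res <- run_pipeline(pairs_path, te, config = config, plan = plan,
                      verbose = verbose)
  index <- resolve_te_index(te, config$te_bucket)
  windows <- make_windows(config$window_width, config$window_step,
                          config$window_span)
  tab <- pairing_counts(res$calls, index, windows = windows,
                        flank = config$flank, bin_size = bin_size)
  list(profile = homotypic_profile(tab),
       metrics = family_metrics(tab),
       table = tab,
       pipeline = res,
       bin_size = as.integer(bin_size))
}

#' Homotypic count profile across sliding windows
#'
#' Total homotypic pairing counts (summed over families) per window, for
#' hotspots and coldfields -- the profile whose center-window peak carries
#' the focal signal.
#'
#' @param table a `"pairing_table"`.
#' @param families optional family subset.
#' @return `data.table`: `window`, `offset`, `hot`, `cold`.
#' @export
homotypic_profile <- function(table, families = NULL) {
  stopifnot(inherits(table, "pairing_table"))
  cc <- table$counts[fam_a == fam_b]
  if (!is.null(families)) cc <- cc[fam_a %in% families]
  prof <- dcast(cc[, .(n = sum(count)), by = .(context, window)],
                window ~ context, value.var = "n", fill = 0L)
  base <- data.table(window = table$windows$window,
                     offset = table$windows$offset)
  prof <- merge(base, prof, by = "window", all.x = TRUE)
  for (col in c("hot", "cold")) {
    if (!col %in% names(prof)) prof[, (col) := 0L]
  }
  prof[is.na(hot), hot := 0L]
  prof[is.na(cold), cold := 0L]
  prof[, .(window, offset, hot, cold)]
}
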