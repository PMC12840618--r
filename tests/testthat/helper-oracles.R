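# Independent brute-force oracles and fixture builders. These deliberately
# re-derive every quantity from first principles (explicit loops, sorting)
# so they share no code path with the package implementation.

library(data.table)

# hotspot predicate: literal evaluation of the three printed criteria on a
# 5x5 grid with the 4 corners removed by coordinate check
o_is_hotspot <- function(g, min_center = 5, excess = 1.2, median_frac = 0.4) {
  center <- g[3, 3]
  bg <- c()
  for (r in 1:5) for (cc in 1:5) {
    corner <- (r %in% c(1, 5)) && (cc %in% c(1, 5))
    if (!corner && !(r == 3 && cc == 3)) bg <- c(bg, g[r, cc])
  }
  stopifnot(length(bg) == 20)
  s <- sort(bg, decreasing = TRUE)
  med <- (s[10] + s[11]) / 2
  (center >= min_center) && (center + 1e-9 >= excess * s[1]) &&
    (med < median_frac * center)
}

# TMC: sort all 25 values, take the 13th as median and the 25th as max
o_tmc <- function(g, p = 1.3) {
  v <- sort(as.vector(g))
  stopifnot(length(v) == 25)
  v[25]^p * v[13]
}

# window membership: explicit loop over the 21 first-principles windows
o_windows <- function(rel, span = 11000, width = 2000, step = 1000) {
  offs <- seq(-(span - width / 2), span - width / 2, by = step)
  which(vapply(offs, function(o) rel >= o - width / 2 && rel <= o + width / 2,
               logical(1)))
}

# presence-based pairing: set of unordered family pairs from the cross
# product of two presence sets
o_pairs <- function(fams1, fams2) {
  out <- character(0)
  for (a in unique(fams1)) for (b in unique(fams2)) {
    out <- c(out, paste(min(a, b), max(a, b), sep = "|"))
  }
  sort(unique(out))
}

# flank query: linear scan over all records
o_query <- function(records, chrom, pos, flank = 11000) {
  hit <- records$chrom == chrom &
    records$center >= pos - flank & records$center <= pos + flank
  r <- records[hit]
  r[order(r$center)]
}

# Pearson r from the covariance formula, no stats::cor
o_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Build a contact map through the public API from a bin-pair count spec:
# each (chrom, bin_i, bin_j, count) becomes `count` records at bin midpoints.
map_from_counts <- function(spec, bin_size = 600L, chrom_sizes = NULL) {
  spec <- as.data.table(spec)
  n <- spec[, rep(seq_len(.N), count)]
  rec <- spec[n, .(read_id = sprintf("r%d", seq_along(n)),
                   chrom1 = chrom, pos1 = bin_i * bin_size + bin_size %/% 2L,
                   chrom2 = chrom, pos2 = bin_j * bin_size + bin_size %/% 2L,
                   strand1 = "+", strand2 = "-")]
  bin_contacts(rec, bin_size, chrom_sizes)
}

# Random sparse in-band count table on one chromosome
random_count_spec <- function(n_keys, nbins = 200L, d_range = 14:66,
                              max_count = 8L) {
  data.table(
    chrom = "chrT",
    bin_i = sample(0:(nbins - 1 - max(d_range)), n_keys, replace = TRUE),
    d = sample(d_range, n_keys, replace = TRUE),
    count = sample(1:max_count, n_keys, replace = TRUE)
  )[, .(count = sum(count)), by = .(chrom, bin_i, bin_j = bin_i + d)]
}

# Random TE record table
random_te_records <- function(n, chroms = c("chrT1", "chrT2"), glen = 2e5) {
  start <- sample(0:(glen - 6001L), n, replace = TRUE)
  len <- sample(150:6000, n, replace = TRUE)
  data.table(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             family = sample(c("AluY", "MIRb", "L2a", "SVA_D"), n, TRUE),
             strand = sample(c("+", "-"), n, TRUE))[
    , center := (start + end) %/% 2L][]
}

# Write a plain-text .pairs file with given data lines (plus header)
write_pairs_text <- function(lines, path, gz = FALSE) {
  con <- if (gz) gzfile(path, "wb") else file(path, "wb")
  writeLines(c("## pairs format v1.0",
               "#columns: readID chr1 pos1 chr2 pos2 strand1 strand2",
               lines), con)
  close(con)
  path
}

pair_line <- function(id, chrom = "chrS1", pos1 = 10000, pos2 = 20000,
                      s1 = "+", s2 = "-") {
  paste(id, chrom, pos1, chrom, pos2, s1, s2, sep = "\t")
}
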