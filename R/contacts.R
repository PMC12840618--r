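#' Systematic sampling plan for streaming a .pairs file
#'
#' Records are selected by raw data-line index (header and malformed lines do
#' not advance the schedule differently: every data line counts, whether or
#' not it later survives the distance filter): skip the first `initial_skip`
#' lines, keep `take`, skip `cycle_skip`, repeat until EOF. For multi-GB
#' deposited files the plan used throughout this package's reference analyses
#' is `sampling_plan(1e6, 8e5, 2.5e6)` -- skip 1 M read pairs, process 800 K,
#' skip 2.5 M, repeat. The default is a pass-through plan that keeps
#' everything.
#'
#' @param initial_skip,take,cycle_skip record counts (`take` may be `Inf`).
#' @return Object of class `"sampling_plan"`.
#' @export
sampling_plan <- function(initial_skip = 0, take = Inf, cycle_skip = 0) {
  stopifnot(initial_skip >= 0, cycle_skip >= 0, take > 0)
  structure(list(initial_skip = initial_skip, take = take,
                 cycle_skip = cycle_skip),
            class = "sampling_plan")
}

# TRUE for 0-based data-line indices selected by the plan.
plan_selects <- function(idx, plan) {
  m <- idx - plan$initial_skip
  if (is.infinite(plan$take)) return(m >= 0)
  m >= 0 & (m %% (plan$take + plan$cycle_skip)) < plan$take
}

#' Stream contact records from a .pairs file under a sampling plan
#'
#' Reads a (gzipped or plain) 4DN `.pairs` file: `#`-prefixed header lines
#' are ignored, data lines must carry at least the seven columns readID,
#' chrom1, pos1, chrom2, pos2, strand1, strand2 (extra trailing columns are
#' tolerated). Malformed data lines are counted, skipped, and reported in one
#' warning. Same-chromosome records with `pos1 > pos2` are normalised by
#' swapping positions together with their strands.
#'
#' @param path path to the `.pairs`/`.pairs.gz` file.
#' @param plan a [sampling_plan()].
#' @return `data.table` with columns `read_id`, `chrom1`, `pos1`, `chrom2`,
#'   `pos2`, `strand1`, `strand2`; attributes `n_data_lines` (raw data lines
#'   seen) and `n_malformed`.
#' @export
stream_pairs <- function(path, plan = sampling_plan()) {
  if (!file.exists(path)) stop("pairs file not found: ", path)
  stopifnot(inherits(plan, "sampling_plan"))
  con <- gzfile(path, "r")
  on.exit(close(con))
  sel <- character(0)
  n_data <- 0L
  repeat {
    lines <- readLines(con, n = 200000L)
    if (!length(lines)) break
    dat <- lines[!startsWith(lines, "#")]
    if (!length(dat)) next
    idx <- n_data + seq_along(dat) - 1L
    keep <- plan_selects(idx, plan)
    if (any(keep)) sel <- c(sel, dat[keep])
    n_data <- n_data + length(dat)
  }

  empty <- data.table(read_id = character(), chrom1 = character(),
                      pos1 = integer(), chrom2 = character(),
                      pos2 = integer(), strand1 = character(),
                      strand2 = character())
  n_bad <- 0L
  if (length(sel)) {
    f <- tstrsplit(sel, "\t", fixed = TRUE)
    if (length(f) < 7L) {
      rec <- empty
      n_bad <- length(sel)
    } else {
      rec <- data.table(read_id = f[[1]], chrom1 = f[[2]],
                        pos1 = suppressWarnings(as.integer(f[[3]])),
                        chrom2 = f[[4]],
                        pos2 = suppressWarnings(as.integer(f[[5]])),
                        strand1 = f[[6]], strand2 = f[[7]])
      bad <- is.na(rec$pos1) | is.na(rec$pos2) | rec$pos1 < 1L | rec$pos2 < 1L |
        is.na(rec$chrom1) | is.na(rec$chrom2) |
        !(rec$strand1 %chin% c("+", "-")) | !(rec$strand2 %chin% c("+", "-"))
      n_bad <- sum(bad)
      rec <- rec[!bad]
    }
  } else {
    rec <- empty
  }
  if (n_bad > 0L) warning(n_bad, " malformed data line(s) skipped in ", path)
  if (n_data > 0L && length(sel) > 0L && nrow(rec) == 0L) {
    stop("no parseable data line among ", length(sel),
         " selected lines of nonempty file ", path)
  }
  ## normalise: same-chromosome records get pos1 <= pos2, strands swap along
  swap <- rec$chrom1 == rec$chrom2 & rec$pos1 > rec$pos2
  if (any(swap)) {
    rec[swap, c("pos1", "pos2", "strand1", "strand2") :=
              .(pos2, pos1, strand2, strand1)]
  }
  setattr(rec, "n_data_lines", n_data)
  setattr(rec, "n_malformed", n_bad)
  rec[]
}

#' Distance-band filter for contact records
#'
#' Keeps intra-chromosomal contacts whose separation `pos2 - pos1` lies in
#' `[min_sep, max_sep]` (both bounds inclusive). This band captures local
#' loops while excluding immediate neighbours; trans contacts are always
#' dropped. Records must be normalised (`pos1 <= pos2`), as produced by
#' [stream_pairs()].
#'
#' @param records `data.table` of contact records.
#' @param min_sep,max_sep band bounds in bp, inclusive.
#' @return Logical vector, one element per record.
#' @export
filter_band <- function(records, min_sep = 8000L, max_sep = 40000L) {
  sep <- records$pos2 - records$pos1
  records$chrom1 == records$chrom2 & sep >= min_sep & sep <= max_sep
}

#' Accumulate a sparse binned contact map
#'
#' Bin index is `floor((pos - 1) / bin_size)` (0-based bins over 1-based
#' positions -- the misbinning control depends on this exact lattice phase).
#' Keys are stored with `bin_i <= bin_j`; counts are additive.
#'
#' @param records normalised, band-filtered contact records.
#' @param bin_size bin size in bp (default 600).
#' @param chrom_sizes optional named vector of chromosome lengths in bp,
#'   used to define chromosome ends for edge handling in [call_all()]; when
#'   absent, the end is taken just beyond the last observed contact.
#' @return Object of class `"binned_contact_map"`: list with `bin_size`,
#'   `counts` (`data.table` chrom/bin_i/bin_j/count), `total_records`,
#'   `nbins` (named vector).
#' @export
bin_contacts <- function(records, bin_size = 600L, chrom_sizes = NULL) {
  stopifnot(bin_size >= 1)
  bin_size <- as.integer(bin_size)
  if (nrow(records)) {
    counts <- records[, .(chrom = chrom1,
                          bin_i = (pos1 - 1L) %/% bin_size,
                          bin_j = (pos2 - 1L) %/% bin_size)]
    counts[bin_i > bin_j, c("bin_i", "bin_j") := .(bin_j, bin_i)]
    counts <- counts[, .(count = .N), by = .(chrom, bin_i, bin_j)]
  } else {
    counts <- data.table(chrom = character(), bin_i = integer(),
                         bin_j = integer(), count = integer())
  }
  setkey(counts, chrom, bin_i, bin_j)
  nbins <- if (!is.null(chrom_sizes)) {
    stats::setNames(as.integer(chrom_sizes %/% bin_size), names(chrom_sizes))
  } else if (nrow(counts)) {
    nb <- counts[, .(nb = max(bin_j) + 3L), by = chrom]
    stats::setNames(nb$nb, nb$chrom)
  } else {
    integer(0)
  }
  structure(list(bin_size = bin_size, counts = counts,
                 total_records = nrow(records), nbins = nbins),
            class = "binned_contact_map")
}

#' @export
print.binned_contact_map <- function(x, ...) {
  cat("binned contact map:", x$total_records, "records in",
      nrow(x$counts), "nonzero bin pairs at", x$bin_size, "bp;",
      length(x$nbins), "chromosome(s)\n")
  invisible(x)
}
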