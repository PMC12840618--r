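#' Read a BED-like TE annotation table
#'
#' Expects a TSV with at least five columns -- chrom, start (0-based), end
#' (half-open), family, strand -- emulating DFAM/RepeatMasker annotation
#' exports. `#` comment lines are skipped; malformed lines (non-numeric or
#' inverted intervals, empty family, bad strand) are counted, skipped and
#' reported in one warning. The element `center = floor((start + end) / 2)`
#' is precomputed since all downstream window membership is by center.
#'
#' @param path TSV path.
#' @return `data.table`: `chrom`, `start`, `end`, `family`, `strand`,
#'   `center`; attribute `n_malformed`.
#' @export
read_te_bed <- function(path) {
  if (!file.exists(path)) stop("TE annotation file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), family = character(),
                      strand = character(), center = integer())
  if (!length(lines)) {
    warning("no TE records in ", path)
    setattr(empty, "n_malformed", 0L)
    return(empty[])
  }
  f <- tstrsplit(lines, "\t", fixed = TRUE)
  if (length(f) < 5L) {
    warning(length(lines), " malformed TE line(s) skipped in ", path)
    setattr(empty, "n_malformed", length(lines))
    return(empty[])
  }
  rec <- data.table(chrom = f[[1]],
                    start = suppressWarnings(as.integer(f[[2]])),
                    end = suppressWarnings(as.integer(f[[3]])),
                    family = f[[4]], strand = f[[5]])
  bad <- is.na(rec$start) | is.na(rec$end) | rec$start >= rec$end |
    is.na(rec$family) | !nzchar(rec$family) |
    !(rec$strand %chin% c("+", "-"))
  n_bad <- sum(bad)
  if (n_bad) warning(n_bad, " malformed TE line(s) skipped in ", path)
  rec <- rec[!bad]
  rec[, center := (start + end) %/% 2L]
  setattr(rec, "n_malformed", n_bad)
  rec[]
}

#' Bucket TE records for fast flank queries
#'
#' The genome is divided into `bucket_size` bins (10 kb in the reference
#' analysis) and every record is registered in each bucket its interval
#' `[start, end)` overlaps, so a flank query only touches a handful of
#' buckets.
#'
#' @param records TE records (from [read_te_bed()] or a
#'   [plant_te_catalog()] `$records` table).
#' @param bucket_size bucket width in bp.
#' @return Object of class `"te_index"`: list with `bucket_size`, `records`
#'   (with a `rec_id` column) and `table` (bucket-expanded `data.table`
#'   keyed by chrom/bucket).
#' @export
build_te_index <- function(records, bucket_size = 10000L) {
  stopifnot(bucket_size >= 1)
  bucket_size <- as.integer(bucket_size)
  rec <- as.data.table(records)
  if (nrow(rec) && !"center" %in% names(rec)) {
    rec[, center := (start + end) %/% 2L]
  }
  rec <- copy(rec)[, rec_id := .I]
  if (nrow(rec)) {
    tab <- rec[, .(bucket = (start %/% bucket_size):((end - 1L) %/% bucket_size)),
               by = .(rec_id, chrom, start, end, family, strand, center)]
  } else {
    tab <- data.table(rec_id = integer(), chrom = character(),
                      start = integer(), end = integer(),
                      family = character(), strand = character(),
                      center = integer(), bucket = integer())
  }
  setkey(tab, chrom, bucket)
  structure(list(bucket_size = bucket_size, records = rec, table = tab),
            class = "te_index")
}

#' Query TEs whose centers fall within a flank of a position
#'
#' Returns the records whose *center* lies in `[pos - flank, pos + flank]`
#' (both bounds inclusive; the interval itself may extend further),
#' deduplicated and sorted by center. An unknown chromosome yields an empty
#' result with a warning.
#'
#' @param index a [build_te_index()].
#' @param chrom chromosome name.
#' @param pos query position in bp (>= 0).
#' @param flank half-width of the query window in bp (default 11000).
#' @return `data.table` of matching records.
#' @export
query_flank <- function(index, chrom, pos, flank = 11000L) {
  stopifnot(inherits(index, "te_index"), pos >= 0)
  bs <- index$bucket_size
  if (nrow(index$table) && !chrom %in% index$table$chrom) {
    warning("unknown chromosome: ", chrom)
  }
  q <- data.table(chrom = chrom,
                  bucket = max(0L, (pos - flank) %/% bs):((pos + flank) %/% bs))
  hits <- index$table[q, on = .(chrom, bucket), nomatch = NULL,
                      allow.cartesian = TRUE]
  hits <- unique(hits, by = "rec_id")
  hits <- hits[center >= pos - flank & center <= pos + flank]
  setorder(hits, center)
  hits[, .(rec_id, chrom, start, end, family, strand, center)]
}

# Batch flank query: `anchors` must carry aid/chrom/pos. Same center rule as
# query_flank(), vectorised over anchors via the bucket table.
query_flank_many <- function(index, anchors, flank = 11000L) {
  bs <- index$bucket_size
  A <- as.data.table(anchors)
  A[, `:=`(b0 = pmax(0L, as.integer((pos - flank) %/% bs)),
           b1 = as.integer((pos + flank) %/% bs))]
  AB <- A[, .(bucket = b0:b1), by = .(aid, chrom, pos)]
  J <- index$table[AB, on = .(chrom, bucket), nomatch = NULL,
                   allow.cartesian = TRUE]
  J <- unique(J, by = c("aid", "rec_id"))
  J[, rel := center - pos]
  J <- J[abs(rel) <= flank]
  J[, .(aid, rec_id, chrom, family, strand, center, pos, rel)]
}
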