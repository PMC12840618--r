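#' Build a toy genome specification
#'
#' Chromosome names are `"chrS1"`, `"chrS2"`, ... so synthetic coordinates can
#' never be mistaken for a real assembly. Each chromosome must be long enough
#' to host a hotspot plus its +/-57 kb coldfield-search corridor and +/-11 kb
#' TE flanks.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param length length of every chromosome in bp (>= 200000).
#' @return A `data.table` with columns `chrom`, `length` (class
#'   `"genome_spec"`).
#' @export
#' @examples
#' make_genome(1, 1e6)
make_genome <- function(n_chrom, length) {
  stopifnot(is.numeric(n_chrom), length(n_chrom) == 1L, n_chrom >= 1)
  stopifnot(is.numeric(length), base::length(length) == 1L)
  if (length < 200000) {
    stop("chromosome length ", length, " bp cannot host one hotspot plus its ",
         "+/-57 kb search corridor and +/-11 kb flanks (need >= 200000 bp)")
  }
  g <- data.table(
    chrom  = paste0("chrS", seq_len(n_chrom)),
    length = as.integer(rep(length, n_chrom))
  )
  setattr(g, "class", c("genome_spec", class(g)))
  g[]
}

#' Default per-Mb TE family abundances for the synthetic generator
#'
#' Copy numbers per megabase loosely scaled from hg38 RepeatMasker densities
#' (Alu-like SINEs most abundant, SVA rare). Used by [plant_te_catalog()] via
#' [simulate_dataset()].
#'
#' @return Named integer vector, copies per Mb.
#' @export
default_family_abundance <- function() {
  c(AluY = 350L, MIRb = 190L, L1M5 = 170L, L2a = 150L, ERVL = 50L, SVA_D = 20L)
}

#' Lay out planted hotspot specifications along the diagonal
#'
#' Plants are spaced evenly along each chromosome (well clear of chromosome
#' ends so the whole +/-57 kb coldfield corridor stays on-chromosome), with a
#' seeded random anchor separation drawn uniformly from the bin separations
#' compatible with the 8--40 kb analysis band.
#'
#' @param genome a [make_genome()] spec.
#' @param n_plants total number of planted hotspots (split across
#'   chromosomes proportionally to length).
#' @param focal_count reads added to each planted center bin pair.
#' @param coupling_prob probability in `[0, 1]` that a same-family TE pair is
#'   planted within the central 2 kb of both anchors (see
#'   [plant_te_catalog()]).
#' @param coupled_family TE family name used for planted coupling.
#' @param seed integer seed for the anchor-separation draws.
#' @param bin_size lattice size in bp (default 600).
#' @param min_sep,max_sep analysis distance band in bp.
#' @return `data.table` of plant specs: `chrom`, `anchor1_bin`, `anchor2_bin`,
#'   `focal_count`, `coupling_prob`, `coupled_family`.
#' @export
make_plants <- function(genome, n_plants, focal_count = 10L,
                        coupling_prob = 0, coupled_family = "MIRb",
                        seed = 1L, bin_size = 600L,
                        min_sep = 8000L, max_sep = 40000L) {
  stopifnot(inherits(genome, "genome_spec"), n_plants >= 1)
  stopifnot(coupling_prob >= 0, coupling_prob <= 1, focal_count >= 0)
  d_lo <- as.integer(ceiling(min_sep / bin_size))   # 14 at 600 bp
  d_hi <- as.integer(floor(max_sep / bin_size))     # 66 at 600 bp
  # margin: full coldfield corridor (95 bins) + grid margin + flank room
  margin <- as.integer(ceiling(57000 / bin_size)) + 5L + d_hi
  share <- genome$length / sum(genome$length)
  n_per <- diff(round(c(0, cumsum(share * n_plants))))
  with_seed(seed, {
    specs <- lapply(seq_len(nrow(genome)), function(ci) {
      n <- n_per[ci]
      if (n == 0) return(NULL)
      nbins <- genome$length[ci] %/% bin_size
      usable <- nbins - 2L * margin
      if (usable < n) {
        stop("chromosome ", genome$chrom[ci], " too short for ", n,
             " plants at this spacing")
      }
      a1 <- margin + as.integer(round(seq(1, usable, length.out = n)))
      data.table(
        chrom        = genome$chrom[ci],
        anchor1_bin  = a1,
        anchor2_bin  = a1 + runif_int(n, d_lo, d_hi),
        focal_count  = as.integer(focal_count),
        coupling_prob = coupling_prob,
        coupled_family = coupled_family
      )
    })
    rbindlist(specs)
  })
}

validate_plants <- function(plants, genome, bin_size = 600L,
                            min_sep = 8000L, max_sep = 40000L) {
  stopifnot(all(c("chrom", "anchor1_bin", "anchor2_bin") %in% names(plants)))
  sep <- (plants$anchor2_bin - plants$anchor1_bin) * bin_size
  if (any(sep < min_sep | sep > max_sep)) {
    stop("plant anchor separation outside the ", min_sep, "-", max_sep,
         " bp analysis band")
  }
  if (!all(plants$chrom %in% genome$chrom)) stop("plant on unknown chromosome")
  if (!is.null(plants$coupling_prob) &&
      any(plants$coupling_prob < 0 | plants$coupling_prob > 1)) {
    stop("coupling_prob must lie in [0, 1]")
  }
  invisible(TRUE)
}

#' Generate a synthetic TE catalog with optional planted homotypic coupling
#'
#' Background elements are placed uniformly at random (length uniform on
#' `[150, 6000]` bp, spanning Alu-like to L1-like sizes; strand
#' Bernoulli(0.5)). For each plant spec, with probability `coupling_prob` one
#' element of `coupled_family` is placed with its center inside +/-1000 bp of
#' *each* anchor midpoint (the central 2 kb window), giving one guaranteed
#' homotypic pair at that contact. Coupling decisions are drawn *before* any
#' placement coordinates, one uniform per plant, so catalogs generated with
#' the same seed at increasing `coupling_prob` have nested coupled sets.
#'
#' @param genome a [make_genome()] spec.
#' @param family_abundance named vector, TE copies per family across the
#'   whole genome (distributed across chromosomes proportionally to length).
#' @param plants plant specs from [make_plants()] (may be empty).
#' @param seed integer seed.
#' @param bin_size lattice size in bp.
#' @return Object of class `"te_catalog"`: list with `records` (a
#'   `data.table`: `chrom`, `start` (0-based), `end` (half-open), `family`,
#'   `strand`, `center`, `origin`) and `truth` (one row per plant:
#'   `plant`, `chrom`, `anchor1_bin`, `anchor2_bin`, `coupled`, `family`).
#' @export
plant_te_catalog <- function(genome, family_abundance, plants = NULL,
                             seed = 1L, bin_size = 600L) {
  stopifnot(inherits(genome, "genome_spec"))
  if (length(family_abundance)) {
    if (is.null(names(family_abundance)) || any(!nzchar(names(family_abundance)))) {
      stop("family names must be nonempty")
    }
    if (any(family_abundance < 0)) stop("family counts must be >= 0")
  }
  if (is.null(plants)) {
    plants <- data.table(chrom = character(), anchor1_bin = integer(),
                         anchor2_bin = integer(), coupling_prob = numeric(),
                         coupled_family = character())
  } else {
    validate_plants(plants, genome, bin_size)
  }

  clip_n <- 0L
  with_seed(seed, {
    ## background placements, family by family (deterministic order)
    bg <- lapply(sort(names(family_abundance)), function(fam) {
      n <- as.integer(family_abundance[[fam]])
      if (n == 0L) return(NULL)
      ci <- sample.int(nrow(genome), n, replace = TRUE,
                       prob = genome$length / sum(genome$length))
      len <- runif_int(n, 150L, 6000L)
      start <- runif_int(n, 0L, genome$length[ci] - 1L)
      end <- start + len
      over <- end > genome$length[ci]
      if (any(over)) {
        clip_n <<- clip_n + sum(over)
        end[over] <- genome$length[ci][over]
      }
      data.table(chrom = genome$chrom[ci], start = start, end = end,
                 family = fam,
                 strand = c("+", "-")[1L + stats::rbinom(n, 1L, 0.5)],
                 origin = "background")
    })

    ## coupling: one uniform per plant, drawn before placement coordinates
    n_p <- nrow(plants)
    coupled <- if (n_p) stats::runif(n_p) < plants$coupling_prob else logical(0)
    planted <- NULL
    if (any(coupled)) {
      idx <- which(coupled)
      mids <- plants[idx, .(
        chrom,
        m1 = anchor1_bin * bin_size + bin_size %/% 2L,
        m2 = anchor2_bin * bin_size + bin_size %/% 2L,
        family = coupled_family
      )]
      one_anchor <- function(mid) {
        n <- length(mid)
        ctr <- mid + runif_int(n, -1000L, 1000L)
        len <- runif_int(n, 150L, 6000L)
        start <- pmax(0L, ctr - len %/% 2L)
        data.table(start = start, end = start + len,
                   strand = c("+", "-")[1L + stats::rbinom(n, 1L, 0.5)])
      }
      p1 <- one_anchor(mids$m1)
      p2 <- one_anchor(mids$m2)
      planted <- rbindlist(list(
        data.table(chrom = mids$chrom, p1, family = mids$family, origin = "coupled"),
        data.table(chrom = mids$chrom, p2, family = mids$family, origin = "coupled")
      ), use.names = TRUE)
      glen <- genome$length[match(planted$chrom, genome$chrom)]
      over <- planted$end > glen
      if (any(over)) {
        clip_n <- clip_n + sum(over)
        planted[over, end := glen[over]]
      }
    }

    records <- rbindlist(c(bg, list(planted)), use.names = TRUE)
    if (nrow(records)) {
      records[, center := (start + end) %/% 2L]
      setcolorder(records, c("chrom", "start", "end", "family", "strand",
                             "center", "origin"))
      setorder(records, chrom, start, end, family)
    } else {
      records <- data.table(chrom = character(), start = integer(),
                            end = integer(), family = character(),
                            strand = character(), center = integer(),
                            origin = character())
    }
    if (clip_n > 0L) {
      warning(clip_n, " TE interval(s) clipped at chromosome ends")
    }
    truth <- if (n_p) {
      data.table(plant = seq_len(n_p), chrom = plants$chrom,
                 anchor1_bin = plants$anchor1_bin,
                 anchor2_bin = plants$anchor2_bin,
                 coupled = coupled,
                 family = plants$coupled_family)
    } else {
      data.table(plant = integer(), chrom = character(),
                 anchor1_bin = integer(), anchor2_bin = integer(),
                 coupled = logical(), family = character())
    }
    structure(list(records = records, truth = truth, seed = seed),
              class = "te_catalog")
  })
}

#' @export
print.te_catalog <- function(x, ...) {
  cat("TE catalog:", nrow(x$records), "elements,",
      length(unique(x$records$family)), "families;",
      sum(x$truth$coupled), "of", nrow(x$truth),
      "plants carry a coupled pair\n")
  invisible(x)
}

#' Write a TE catalog (or record table) as BED-like TSV
#'
#' Columns: chrom, start (0-based), end (half-open), family, strand.
#'
#' @param catalog a `"te_catalog"` or a record `data.table`/`data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_te_bed <- function(catalog, path) {
  rec <- if (inherits(catalog, "te_catalog")) catalog$records else as.data.table(catalog)
  fwrite(rec[, .(chrom, start, end, family, strand)], path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a synthetic gzipped .pairs file with planted focal hotspots
#'
#' Background contacts are drawn independently per 600 bp bin pair in the
#' 8--40 kb band as Poisson(`background_rate`); read positions are uniform
#' within the two bins, conditioned on the pair separation staying inside the
#' band so the generator only ever emits the analysis band. Each plant spec
#' adds `focal_count` reads confined to its center bin pair; within each
#' anchor bin the planted reads cluster in a 300 bp sub-interval, matching
#' the physical scale of a Micro-C focal contact. Positions are
#' written 1-based, `pos1 <= pos2`, in the 4DN `.pairs` text dialect
#' (`#`-prefixed header, then TAB-separated readID, chrom1, pos1, chrom2,
#' pos2, strand1, strand2). Identical seeds give byte-identical files.
#'
#' @param genome a [make_genome()] spec.
#' @param plants plant specs from [make_plants()] (or `NULL`).
#' @param background_rate Poisson mean, expected reads per in-band bin pair.
#' @param seed integer seed.
#' @param out output path (`.pairs.gz`).
#' @param bin_size lattice size in bp.
#' @param min_sep,max_sep distance band in bp (inclusive).
#' @return Object of class `"truth_table"`: `data.table` of the planted
#'   spots (`chrom`, `anchor1_bin`, `anchor2_bin`, `focal_count`,
#'   `coupling_prob`, `coupled_family`) with attributes `seed` and `path`.
#' @export
generate_pairs_file <- function(genome, plants = NULL, background_rate = 0,
                                seed = 1L, out,
                                bin_size = 600L, min_sep = 8000L,
                                max_sep = 40000L) {
  stopifnot(inherits(genome, "genome_spec"), background_rate >= 0)
  if (!is.null(plants) && nrow(plants)) validate_plants(plants, genome, bin_size)
  d_lo <- as.integer(ceiling(min_sep / bin_size))
  d_hi <- as.integer(floor(max_sep / bin_size))

  draw_positions <- function(chrom, bi, bj) {
    # pos1 uniform in bin i; pos2 uniform in bin j restricted to the band
    n <- length(bi)
    p1 <- bi * bin_size + runif_int(n, 1L, bin_size)
    lo <- pmax(bj * bin_size + 1L, p1 + min_sep)
    hi <- pmin(bj * bin_size + bin_size, p1 + max_sep)
    p2 <- lo + floor(stats::runif(n) * (hi - lo + 1))
    data.table(chrom1 = chrom, pos1 = p1, chrom2 = chrom, pos2 = p2)
  }

  recs <- with_seed(seed, {
    parts <- lapply(seq_len(nrow(genome)), function(ci) {
      if (background_rate == 0) return(NULL)
      nbins <- genome$length[ci] %/% bin_size
      per_d <- lapply(d_lo:d_hi, function(dd) {
        n_i <- nbins - dd
        if (n_i <= 0) return(NULL)
        cnt <- stats::rpois(n_i, background_rate)
        nz <- which(cnt > 0L)
        if (!length(nz)) return(NULL)
        bi <- rep(nz - 1L, cnt[nz])
        draw_positions(genome$chrom[ci], bi, bi + dd)
      })
      rbindlist(per_d)
    })
    planted <- NULL
    if (!is.null(plants) && nrow(plants)) {
      # a focal contact is a ~300 bp object (MNase-level resolution): reads
      # of one plant cluster in a 300 bp sub-interval of each anchor bin
      n_p <- nrow(plants)
      cl <- function(bins) {
        lo <- bins * bin_size + 150L
        lo + runif_int(n_p, 0L, bin_size - 300L)   # cluster centers
      }
      c1 <- rep(cl(plants$anchor1_bin), plants$focal_count)
      c2 <- rep(cl(plants$anchor2_bin), plants$focal_count)
      chr <- rep(plants$chrom, plants$focal_count)
      if (length(c1)) {
        p1 <- c1 - 150L + runif_int(length(c1), 1L, 300L)
        p2 <- c2 - 150L + runif_int(length(c2), 1L, 300L)
        p2 <- pmin(pmax(p2, p1 + min_sep), p1 + max_sep)
        planted <- data.table(chrom1 = chr, pos1 = p1, chrom2 = chr, pos2 = p2)
      }
    }
    all <- rbindlist(c(parts, list(planted)))
    if (is.null(all) || !nrow(all)) {
      all <- data.table(chrom1 = character(), pos1 = integer(),
                        chrom2 = character(), pos2 = integer())
    }
    n <- nrow(all)
    all[, `:=`(strand1 = c("+", "-")[1L + stats::rbinom(n, 1L, 0.5)],
               strand2 = c("+", "-")[1L + stats::rbinom(n, 1L, 0.5)])]
    setorder(all, chrom1, pos1, pos2)
    all
  })

  con <- gzfile(out, "wb")
  on.exit(close(con))
  header <- c(
    "## pairs format v1.0",
    "#sorted: chr1-chr2-pos1-pos2",
    "#shape: upper triangle",
    paste("#chromsize:", genome$chrom, genome$length),
    "#columns: readID chr1 pos1 chr2 pos2 strand1 strand2"
  )
  writeLines(header, con)
  if (nrow(recs)) {
    ids <- sprintf("r%07d", seq_len(nrow(recs)))
    writeLines(paste(ids, recs$chrom1, recs$pos1, recs$chrom2, recs$pos2,
                     recs$strand1, recs$strand2, sep = "\t"), con)
  }

  truth <- if (!is.null(plants) && nrow(plants)) {
    cols <- intersect(c("chrom", "anchor1_bin", "anchor2_bin", "focal_count",
                        "coupling_prob", "coupled_family"), names(plants))
    copy(plants[, cols, with = FALSE])
  } else {
    data.table(chrom = character(), anchor1_bin = integer(),
               anchor2_bin = integer(), focal_count = integer())
  }
  setattr(truth, "seed", seed)
  setattr(truth, "path", out)
  setattr(truth, "class", c("truth_table", class(truth)))
  truth[]
}

#' One-call synthetic dataset: genome + TE catalog + .pairs file + truth
#'
#' Convenience wrapper used by tests, the demo and the acceptance script.
#' Sub-seeds for plants, catalog and contacts are derived from `seed`.
#'
#' @param out_dir directory to write `te.bed`, `contacts.pairs.gz`,
#'   `truth.tsv` into (created if needed).
#' @param seed integer master seed.
#' @param genome_length,n_chrom genome geometry.
#' @param n_hotspots number of planted hotspots.
#' @param focal_count reads per planted center bin pair.
#' @param background_rate Poisson background per in-band bin pair.
#' @param coupling_prob,coupled_family planted homotypic coupling.
#' @param family_abundance named copies-per-Mb vector
#'   (default [default_family_abundance()]), scaled by total genome length.
#' @param bin_size lattice size in bp.
#' @return list with `genome`, `plants`, `catalog`, `truth` and file paths
#'   `pairs_path`, `te_path`, `truth_path`.
#' @export
simulate_dataset <- function(out_dir, seed = 1L,
                             genome_length = 1e6, n_chrom = 1L,
                             n_hotspots = 60L, focal_count = 10L,
                             background_rate = 1.25,
                             coupling_prob = 0, coupled_family = "MIRb",
                             family_abundance = NULL,
                             bin_size = 600L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  genome <- make_genome(n_chrom, genome_length)
  plants <- make_plants(genome, n_hotspots, focal_count = focal_count,
                        coupling_prob = coupling_prob,
                        coupled_family = coupled_family,
                        seed = seed, bin_size = bin_size)
  if (is.null(family_abundance)) {
    mb <- sum(genome$length) / 1e6
    family_abundance <- pmax(1L, as.integer(round(default_family_abundance() * mb)))
    names(family_abundance) <- names(default_family_abundance())
  }
  catalog <- plant_te_catalog(genome, family_abundance, plants,
                              seed = seed + 1L, bin_size = bin_size)
  te_path <- file.path(out_dir, "te.bed")
  write_te_bed(catalog, te_path)
  pairs_path <- file.path(out_dir, "contacts.pairs.gz")
  truth <- generate_pairs_file(genome, plants, background_rate,
                               seed = seed + 2L, out = pairs_path,
                               bin_size = bin_size)
  truth_path <- file.path(out_dir, "truth.tsv")
  fwrite(merge(truth, catalog$truth[, .(chrom, anchor1_bin, anchor2_bin, coupled)],
               by = c("chrom", "anchor1_bin", "anchor2_bin"), sort = FALSE),
         truth_path, sep = "\t")
  list(genome = genome, plants = plants, catalog = catalog, truth = truth,
       pairs_path = pairs_path, te_path = te_path, truth_path = truth_path)
}
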