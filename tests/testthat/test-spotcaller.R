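test_that("grid extraction reads sparse keys with zeros elsewhere", {
  empty <- bin_contacts(data.table::data.table(
    read_id = character(), chrom1 = character(), pos1 = integer(),
    chrom2 = character(), pos2 = integer(), strand1 = character(),
    strand2 = character()))
  g0 <- extract_grid(empty, "chrX", 50, 80)
  expect_true(all(g0 == 0))

  map <- map_from_counts(data.table::data.table(
    chrom = "chrT", bin_i = c(50, 48), bin_j = c(80, 78), count = c(7, 2)))
  g <- extract_grid(map, "chrT", 50, 80)
  expect_equal(g[3, 3], 7)
  expect_equal(g[1, 1], 2)        # corner value present in the grid
  expect_equal(sum(g), 9)
  # corner is masked for the hotspot criteria but not for extraction
  expect_true(is_hotspot(g))

  # 2-bin margin at chromosome start
  expect_null(extract_grid(map, "chrT", 1, 31))
})

test_that("hotspot criteria follow the printed thresholds and boundaries", {
  base <- matrix(0, 5, 5)
  g <- base; g[3, 3] <- 10
  expect_true(is_hotspot(g))
  g <- base; g[3, 3] <- 4
  expect_false(is_hotspot(g))            # fails center >= 5
  g <- base; g[3, 3] <- 5; g[3, 4] <- 4
  expect_true(is_hotspot(g))             # 5 >= 1.2 * 4
  g <- base; g[3, 3] <- 6; g[3, 4] <- 5
  expect_true(is_hotspot(g))             # 6 >= 1.2 * 5, inclusive bound
  g <- base; g[3, 3] <- 6; g[3, 4] <- 6
  expect_false(is_hotspot(g))            # 6 < 1.2 * 6
  # corners are excluded: a huge corner cannot veto
  g <- base; g[3, 3] <- 10; g[1, 1] <- 100
  expect_true(is_hotspot(g))
  # median criterion is strict
  g <- matrix(4, 5, 5); g[3, 3] <- 10
  expect_false(is_hotspot(g))            # median 4 = 0.4 * 10, not <
})

test_that("TMC uses all 25 cells", {
  expect_equal(tmc(matrix(0, 5, 5)), 0)
  expect_equal(tmc(matrix(1, 5, 5)), 1)
  g <- matrix(2, 5, 5); g[2, 2] <- 10
  expect_equal(tmc(g), 10^1.3 * 2)
  # corners count for TMC (unlike the hotspot criteria)
  g <- matrix(2, 5, 5); g[1, 1] <- 50
  expect_equal(tmc(g), 50^1.3 * 2)
})

test_that("hotspot predicate and TMC match brute-force on random grids", {
  set.seed(71)
  for (i in 1:400) {
    g <- matrix(sample(0:7, 25, replace = TRUE), 5, 5)
    expect_equal(is_hotspot(g), o_is_hotspot(g), info = paste("grid", i))
    expect_equal(tmc(g), o_tmc(g), info = paste("grid", i))
  }
})

test_that("coldfield search covers +/-57 kb and minimises TMC with tie-breaks", {
  offs <- coldfield_offsets(5, 20)
  expect_equal(max(abs(offs)) * 600, 57000)
  expect_equal(length(offs), 39L)
  expect_true(0 %in% offs)

  # tile every candidate grid with ones except offsets -5 and +10
  spec <- data.table::CJ(a = -2:2, b = -2:2)[, {
    cells <- lapply(setdiff(coldfield_offsets(5, 20), c(-5, 10)), function(o) {
      data.table::data.table(chrom = "chrT", bin_i = 500 + o + a,
                             bin_j = 540 + o + b, count = 1)
    })
    data.table::rbindlist(cells)
  }, by = .(a, b)][, .(chrom, bin_i, bin_j, count)]
  map <- map_from_counts(spec)
  hot <- list(chrom = "chrT", bin_i = 500, bin_j = 540)
  cf <- find_coldfield(map, hot)
  expect_equal(cf$tmc, 0)
  expect_equal(cf$offset_bins, -5)       # |−5| < |+10| among the tmc=0 ties

  # global-minimum contract: exhaustive re-scan
  for (o in coldfield_offsets(5, 20)) {
    g <- extract_grid(map, "chrT", 500 + o, 540 + o)
    if (!is.null(g)) expect_gte(tmc(g), cf$tmc)
  }
})

test_that("an isolated hotspot on an empty map gets a zero-TMC coldfield", {
  map <- map_from_counts(data.table::data.table(
    chrom = "chrT", bin_i = 500, bin_j = 540, count = 9))
  cf <- find_coldfield(map, list(chrom = "chrT", bin_i = 500, bin_j = 540))
  expect_equal(cf$tmc, 0)
})

test_that("call_all matches per-candidate predicate evaluation on random maps", {
  set.seed(17)
  for (rep in 1:8) {
    spec <- random_count_spec(150, nbins = 300)
    sizes <- c(chrT = 300 * 600)
    map <- map_from_counts(spec, chrom_sizes = sizes)
    calls <- suppressMessages(call_all(map))
    # oracle: test every nonzero key with the exported single-candidate ops
    oracle_hot <- spec[, {
      g <- extract_grid(map, chrom, bin_i, bin_j)
      .(hot = !is.null(g) && is_hotspot(g))
    }, by = .(chrom, bin_i, bin_j)][hot == TRUE]
    expect_equal(nrow(calls), nrow(oracle_hot))
    if (nrow(calls)) {
      expect_equal(as.data.frame(calls[, .(chrom, bin_i = hot_bin1,
                                           bin_j = hot_bin2)]),
                   as.data.frame(oracle_hot[order(chrom, bin_i, bin_j),
                                            .(chrom, bin_i, bin_j)]))
      # coldfields equal the single-hotspot search
      for (k in seq_len(nrow(calls))) {
        cf <- find_coldfield(map, list(chrom = calls$chrom[k],
                                       bin_i = calls$hot_bin1[k],
                                       bin_j = calls$hot_bin2[k]))
        expect_equal(calls$cold_bin1[k], cf$bin_i)
        expect_equal(calls$tmc[k], cf$tmc)
        expect_equal(calls$offset_bins[k], cf$offset_bins)
      }
    }
  }
})

test_that("uniform maps yield no hotspots; empty maps yield empty calls", {
  nb <- 180
  spec <- data.table::CJ(bin_i = 0:(nb - 1), d = 14:66)[
    , .(chrom = "chrT", bin_i, bin_j = bin_i + d, count = 5)][bin_j < nb]
  map <- map_from_counts(spec[, .(chrom, bin_i, bin_j, count)],
                         chrom_sizes = c(chrT = nb * 600))
  expect_equal(nrow(suppressMessages(call_all(map))), 0L)

  empty <- bin_contacts(data.table::data.table(
    read_id = character(), chrom1 = character(), pos1 = integer(),
    chrom2 = character(), pos2 = integer(), strand1 = character(),
    strand2 = character()))
  expect_equal(nrow(call_all(empty)), 0L)
})

test_that("raising min_center never increases the number of hotspots", {
  set.seed(23)
  spec <- random_count_spec(300, nbins = 300)
  map <- map_from_counts(spec, chrom_sizes = c(chrT = 300 * 600))
  n <- sapply(3:8, function(mc) nrow(suppressMessages(call_all(map, min_center = mc))))
  expect_true(all(diff(n) <= 0))
})

test_that("hotspot calls are invariant to contacts outside all 5x5 grids", {
  set.seed(29)
  spec <- random_count_spec(80, nbins = 400, d_range = 14:40)
  map1 <- map_from_counts(spec, chrom_sizes = c(chrT = 400 * 600))
  calls1 <- suppressMessages(call_all(map1))
  # add contacts far away in the separation direction (d = 60..66: more than
  # 2 bins from every existing key's grid)
  far <- data.table::data.table(chrom = "chrT", bin_i = spec$bin_i,
                                bin_j = spec$bin_i + 63, count = 3)
  map2 <- map_from_counts(rbind(spec[, .(chrom, bin_i, bin_j, count)], far),
                          chrom_sizes = c(chrT = 400 * 600))
  calls2 <- suppressMessages(call_all(map2))
  old <- calls2[paste(chrom, hot_bin1, hot_bin2) %in%
                  calls1[, paste(chrom, hot_bin1, hot_bin2)]]
  expect_equal(nrow(old), nrow(calls1))
})
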