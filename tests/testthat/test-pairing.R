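test_that("window geometry: 21 windows of 2 kb spanning -11..+11 kb", {
  w <- make_windows()
  expect_equal(nrow(w), 21L)
  center <- w[offset == 0]
  expect_equal(c(center$lo, center$hi), c(-1000L, 1000L))
  expect_equal(min(w$lo), -11000L)
  expect_equal(max(w$hi), 11000L)
  # 50% overlap: window centers advance by half a width
  expect_equal(unique(diff(w$offset)), 1000L)
})

test_that("window assignment matches interval-membership enumeration", {
  w <- make_windows()
  set.seed(53)
  for (i in 1:1000) {
    rel <- sample(-12000:12000, 1)
    tes <- data.table::data.table(chrom = "c", start = 0L, end = 1L,
                                  family = "F", strand = "+",
                                  center = 100000L + rel)
    got <- assign_windows(tes, 100000L, w)$window
    expect_equal(sort(got), o_windows(rel), info = paste("rel =", rel))
  }
  # beyond the span: no window
  far <- data.table::data.table(chrom = "c", start = 0L, end = 1L,
                                family = "F", strand = "+", center = 111500L)
  expect_equal(nrow(assign_windows(far, 100000L, w)), 0L)
  expect_equal(nrow(assign_windows(far[0], 100000L, w)), 0L)
})

test_that("pairing counts are presence-based over unordered family pairs", {
  w <- make_windows()
  mk <- function(window, family, strand = rep("+", length(family))) {
    data.table::data.table(window = as.integer(window), family = family,
                           strand = strand, rel = rep(0L, length(family)))
  }
  t1 <- count_pairings(mk(11, "MIRb"), mk(11, "MIRb"), "hot")
  expect_equal(t1$counts[, .(fam_a, fam_b, window, count)],
               data.table::data.table(fam_a = "MIRb", fam_b = "MIRb",
                                      window = 11L, count = 1L))
  t2 <- count_pairings(mk(11, "MIRb"), mk(11, "L2a"), "hot")
  expect_equal(t2$counts$fam_a, "L2a")
  expect_equal(t2$counts$fam_b, "MIRb")
  t3 <- count_pairings(mk(integer(0), character(0)), mk(11, "AluY"), "hot")
  expect_equal(nrow(t3$counts), 0L)
  expect_equal(unname(t3$n_contacts["hot"]), 1L)
  # copy number does not inflate presence counts
  t4 <- count_pairings(mk(c(11, 11, 11), c("MIRb", "MIRb", "MIRb")),
                       mk(11, "MIRb"), "hot")
  expect_equal(t4$counts$count, 1L)
})

test_that("pairing counts match set-product enumeration on random fixtures", {
  fams <- c("A", "B", "C", "D")
  set.seed(59)
  for (i in 1:1000) {
    w1 <- sample(1:3, 1); w2 <- sample(1:3, 1)
    f1 <- sample(fams, sample(0:3, 1), replace = TRUE)
    f2 <- sample(fams, sample(0:3, 1), replace = TRUE)
    a1 <- data.table::data.table(window = rep(w1, length(f1)), family = f1,
                                 strand = "+", rel = 0L)
    a2 <- data.table::data.table(window = rep(w2, length(f2)), family = f2,
                                 strand = "-", rel = 0L)
    tab <- count_pairings(a1, a2, "hot")
    got <- tab$counts[, sort(paste(fam_a, fam_b, sep = "|"))]
    want <- if (w1 == w2) o_pairs(f1, f2) else character(0)
    expect_equal(got, want, info = paste("fixture", i))
    expect_true(all(tab$counts$count == 1L))
  }
})

test_that("bulk pairing equals the per-contact exported operations", {
  sim <- suppressWarnings(simulate_dataset(
    file.path(tempdir(), "bulkcmp"), seed = 19, genome_length = 4e5,
    n_hotspots = 8, coupling_prob = 1, background_rate = 1.0))
  res <- run_pipeline(sim$pairs_path, sim$catalog, verbose = FALSE)
  calls <- res$calls
  idx <- build_te_index(sim$catalog$records)
  w <- make_windows()
  tab <- new_tab <- NULL
  for (k in seq_len(nrow(calls))) {
    for (ctx in c("hot", "cold")) {
      b1 <- if (ctx == "hot") calls$hot_bin1[k] else calls$cold_bin1[k]
      b2 <- if (ctx == "hot") calls$hot_bin2[k] else calls$cold_bin2[k]
      p1 <- b1 * 600 + 300; p2 <- b2 * 600 + 300
      a1 <- assign_windows(query_flank(idx, calls$chrom[k], p1), p1, w)
      a2 <- assign_windows(query_flank(idx, calls$chrom[k], p2), p2, w)
      tab <- if (is.null(tab)) count_pairings(a1, a2, ctx)
             else count_pairings(a1, a2, ctx, tab)
    }
  }
  bulk <- res$table
  setkey(tab$counts, context, fam_a, fam_b, window)
  setkey(bulk$counts, context, fam_a, fam_b, window)
  expect_equal(bulk$counts, tab$counts)
  expect_equal(bulk$n_contacts, tab$n_contacts)
  s1 <- tab$strand[order(context)]
  s2 <- bulk$strand[order(context)]
  expect_equal(s1, s2)
})

test_that("anchor swap leaves the pairing table unchanged", {
  w <- make_windows()
  mk <- function(family, strand) {
    data.table::data.table(window = 11L, family = family, strand = strand,
                           rel = 0L)
  }
  a <- mk(c("MIRb", "AluY"), c("+", "-"))
  b <- mk(c("L2a", "MIRb"), c("+", "+"))
  t_ab <- count_pairings(a, b, "hot")
  t_ba <- count_pairings(b, a, "hot")
  setkey(t_ab$counts, fam_a, fam_b, window)
  setkey(t_ba$counts, fam_a, fam_b, window)
  expect_equal(t_ab$counts, t_ba$counts)
  expect_equal(t_ab$strand[, .(hh, ht)], t_ba$strand[, .(hh, ht)])
})

test_that("family metrics implement the three ratio definitions", {
  mk <- function(window, family, strand = "+") {
    data.table::data.table(window = window, family = family, strand = strand,
                           rel = 0L)
  }
  tab <- new_pairing_table()
  add <- function(tab, n, f1, f2, ctx) {
    for (i in seq_len(n)) tab <- count_pairings(mk(11, f1), mk(11, f2), ctx, tab)
    tab
  }
  # hot homotypic 20, cold homotypic 10, het 5/5 -> ratio 2, het ratio 1,
  # specificity 2
  tab <- add(tab, 20, "MIRb", "MIRb", "hot")
  tab <- add(tab, 10, "MIRb", "MIRb", "cold")
  tab <- add(tab, 5, "MIRb", "L2a", "hot")
  tab <- add(tab, 5, "MIRb", "L2a", "cold")
  m <- family_metrics(tab)
  mm <- m[family == "MIRb"]
  expect_equal(mm$hot_cold_ratio, 2)
  expect_equal(mm$heterotypic_ratio, 1)
  expect_equal(mm$specificity_index, 2)
  expect_true(mm$defined)
  # L2a has no homotypic cold (or hot) counts: undefined, flagged
  expect_false(m[family == "L2a", defined])
  expect_error(family_metrics(tab, "NoSuchFam"), "unknown family")

  # identical hot and cold counts: all three metrics 1
  tab2 <- new_pairing_table()
  tab2 <- add(tab2, 4, "MIRb", "MIRb", "hot")
  tab2 <- add(tab2, 4, "MIRb", "MIRb", "cold")
  tab2 <- add(tab2, 3, "MIRb", "AluY", "hot")
  tab2 <- add(tab2, 3, "MIRb", "AluY", "cold")
  m2 <- family_metrics(tab2, "MIRb")
  expect_equal(m2$hot_cold_ratio, 1)
  expect_equal(m2$heterotypic_ratio, 1)
  expect_equal(m2$specificity_index, 1)
})

test_that("specificity matrix is symmetric, sorted by diagonal", {
  mk <- function(window, family) {
    data.table::data.table(window = window, family = family, strand = "+",
                           rel = 0L)
  }
  tab <- new_pairing_table()
  add <- function(tab, n, f1, f2, ctx) {
    for (i in seq_len(n)) tab <- count_pairings(mk(11, f1), mk(11, f2), ctx, tab)
    tab
  }
  tab <- add(tab, 8, "MIRb", "MIRb", "hot"); tab <- add(tab, 2, "MIRb", "MIRb", "cold")
  tab <- add(tab, 2, "AluY", "AluY", "hot"); tab <- add(tab, 4, "AluY", "AluY", "cold")
  tab <- add(tab, 3, "MIRb", "AluY", "hot"); tab <- add(tab, 3, "MIRb", "AluY", "cold")
  sm <- specificity_matrix(tab, top_k = 2)
  expect_equal(rownames(sm)[1], "MIRb")          # highest diagonal first
  expect_equal(sm["MIRb", "MIRb"], 4)
  expect_equal(sm["AluY", "AluY"], 0.5)
  expect_equal(sm["MIRb", "AluY"], sm["AluY", "MIRb"])
  expect_equal(sm["MIRb", "AluY"], 1)
})

test_that("orientation ratio classifies strands and flags degenerate input", {
  mk <- function(strand) {
    data.table::data.table(window = 11L, family = "MIRb", strand = strand,
                           rel = 0L)
  }
  tab <- new_pairing_table()
  for (i in 1:47) tab <- count_pairings(mk("+"), mk("-"), "hot", tab)  # head-head
  for (i in 1:50) tab <- count_pairings(mk("+"), mk("+"), "hot", tab)  # head-tail
  expect_equal(orientation_ratio(tab), 47 / 50)
  tab_hh <- count_pairings(mk("+"), mk("-"), "hot")
  expect_warning(r <- orientation_ratio(tab_hh), "undefined")
  expect_true(is.na(r))
})

test_that("age correlation reproduces the covariance formula", {
  m <- data.table::data.table(
    family = c("MIRb", "L2a", "AluY", "SVA_D"),
    hot_cold_ratio = c(1.8, 1.5, 0.7, 0.9),
    defined = TRUE)
  ages <- data.table::data.table(family = c("MIRb", "L2a", "AluY", "SVA_D"),
                                 age_myr = c(130, 150, 50, 13))
  got <- age_correlation(m, ages)
  expect_equal(got$n, 4L)
  expect_equal(got$r, o_pearson(ages$age_myr, m$hot_cold_ratio))

  # exact linear function of age -> r = 1
  m2 <- data.table::copy(m)[, hot_cold_ratio := 0.01 * ages$age_myr + 0.2]
  expect_equal(age_correlation(m2, ages)$r, 1)

  # identical ages -> zero variance, flagged
  ages0 <- data.table::copy(ages)[, age_myr := 100]
  expect_warning(r0 <- age_correlation(m, ages0), "zero variance")
  expect_true(is.na(r0$r))
  expect_error(age_correlation(m[1:2], ages), ">= 3")
})
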