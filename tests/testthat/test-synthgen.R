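# Synthetic miRNA/UTR/array generation: determinism, quota assignment,
# round-trip classification, and fidelity to the stated generative model.

test_that("make_mirna is deterministic, seed-sensitive, RNA alphabet", {
  a <- make_mirna(1, 22)
  b <- make_mirna(1, 22)
  expect_identical(a, b)
  expect_equal(nchar(a), 22L)
  expect_false(grepl("[^ACGU]", a))
  expect_false(identical(make_mirna(1), make_mirna(2)))
  expect_error(make_mirna(1, 17), "invalid-argument")
  expect_error(make_mirna(1, 26), "invalid-argument")
})

test_that("site classes are assigned by exact quota", {
  cfg <- sim_config(n_genes = 100,
                    site_class_fractions = c("8mer" = 0.1),
                    rng_seed = 5)
  ps <- plant_sites(make_mirna(3), cfg)
  expect_equal(sum(ps$truth$site_class == "8mer"), 10L)
  expect_equal(sum(ps$truth$site_class == "none"), 90L)
})

test_that("planted UTRs round-trip through classification, any seed", {
  mirna <- make_mirna(11)
  for (seed in c(1, 2, 3)) {
    cfg <- sim_config(n_genes = 60, utr_length_mean = 400,
                      utr_length_sd = 200, rng_seed = seed)
    ps <- plant_sites(mirna, cfg)
    ann <- classify_utrs(ps$utrs, mirna)
    expect_identical(ann$best_type, ps$truth$site_class)
    # planted coordinates point at a genuine site of the planted class
    planted <- ps$truth[ps$truth$site_class != "none", ]
    for (k in seq_len(nrow(planted))) {
      a <- classify_utr(ps$utrs[[planted$gene_id[k]]], mirna)
      expect_true(any(a$sites$start == planted$site_start[k] &
                      a$sites$type == planted$site_class[k]))
    }
    # genes with class none have true enrichment 0
    expect_true(all(ps$truth$true_log2_enrichment[
      ps$truth$site_class == "none"] == 0))
  }
})

test_that("identical config gives byte-identical written output", {
  cfg <- sim_config(n_genes = 40, utr_length_mean = 300, rng_seed = 42)
  mirna <- make_mirna(7)
  run <- function(dir) {
    ps <- plant_sites(mirna, cfg)
    sim <- simulate_arrays(ps$truth, cfg)
    write_simulation(sim, dir, truth = ps$truth, config = cfg)
    write_fasta_sequences(ps$utrs, file.path(dir, "utrs.fa"))
    tools::md5sum(list.files(dir, full.names = TRUE))
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- run(d1); s2 <- run(d2)
  expect_identical(unname(s1), unname(s2))
})

test_that("degenerate noise: zero effects and zero noise equalize channels", {
  truth <- toy_truth(20, rep("none", 20), rep(0, 20))
  cfg <- sim_config(n_genes = 20, noise_sd = 0, frac_bad_correlation = 0,
                    frac_low_signal = 0, rng_seed = 9)
  sim <- simulate_arrays(truth, cfg)
  for (tab in sim$tables) {
    expect_equal(tab$ch1_fg, tab$ch2_fg)
  }
})

test_that("QC failure stamping follows exact quotas and modes", {
  truth <- toy_truth(1000, rep("none", 1000), rep(0, 1000))
  cfg <- sim_config(n_genes = 1000, frac_bad_correlation = 0.05,
                    frac_low_signal = 0.03, rng_seed = 12)
  sim <- simulate_arrays(truth, cfg)
  expect_equal(sum(sim$element_truth$failure_mode == "bad_correlation"), 50L)
  expect_equal(sum(sim$element_truth$failure_mode == "low_signal"), 30L)
  tab <- sim$tables[[1]]
  bad <- sim$element_truth$failure_mode == "bad_correlation"
  low <- sim$element_truth$failure_mode == "low_signal"
  ok <- !bad & !low
  expect_true(all(tab$pixel_corr[bad] < 0.6))
  expect_true(all(tab$pixel_corr[!bad] >= 0.6))
  expect_true(all(tab$ch1_fg[low] / tab$ch1_bg[low] < 2.5 &
                  tab$ch2_fg[low] / tab$ch2_bg[low] < 2.5))
  expect_true(all(tab$ch1_fg[ok] / tab$ch1_bg[ok] >= 2.5 |
                  tab$ch2_fg[ok] / tab$ch2_bg[ok] >= 2.5))
})

test_that("planted effect is recovered at the generative-model rate", {
  # 200 genes at effect 1.5, noise 0.3, 2 IP arrays: mean per-gene IP
  # ratio within 1.5 +/- 3 * 0.3 / sqrt(2 * 200)
  n <- 200
  truth <- toy_truth(n, rep("8mer", n), rep(1.5, n))
  cfg <- sim_config(n_genes = n, noise_sd = 0.3, frac_bad_correlation = 0,
                    frac_low_signal = 0, rng_seed = 21)
  sim <- simulate_arrays(truth, cfg)
  flt <- filter_elements(sim$tables)
  mat <- assemble_matrix(sim$tables, flt$retained, sim$conditions,
                         normalize = FALSE)
  ip_mean <- rowMeans(mat[, grep("^ip", colnames(mat)), drop = FALSE])
  se <- 0.3 / sqrt(2 * n)
  expect_lt(abs(mean(ip_mean) - 1.5), 3 * se)
})

test_that("null simulation is centred: mean IP-vs-mock delta near 0", {
  n <- 1000
  truth <- toy_truth(n, rep("none", n), rep(0, n))
  cfg <- sim_config(n_genes = n, frac_bad_correlation = 0,
                    frac_low_signal = 0, rng_seed = 31)
  mat <- sim_to_matrix(truth, cfg)
  delta <- enrichment_ratio(mat)
  se <- 0.3 / sqrt(n)  # noise_sd * sqrt(1/2 + 1/2) / sqrt(n)
  expect_lt(abs(mean(delta)), 4 * se)
})

test_that("planted class means are strictly ordered as designed", {
  mirna <- make_mirna(17)
  cfg <- sim_config(n_genes = 300, utr_length_mean = 300, rng_seed = 8)
  ps <- plant_sites(mirna, cfg)
  mat <- sim_to_matrix(ps$truth, cfg)
  delta <- enrichment_ratio(mat)
  names(delta) <- sub(":.*$", "", names(delta))
  cm <- tapply(delta, ps$truth$site_class[match(names(delta),
                                                ps$truth$gene_id)], mean)
  ord <- c("8mer", "7mer-m8", "7mer-1A", "6mer-n2-7", "6mer-n3-8", "none")
  expect_true(all(diff(cm[ord]) < 0))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(site_class_fractions = c("8mer" = 0.7,
                                                   "7mer-m8" = 0.6)),
               "invalid-argument")
  expect_error(sim_config(effect_log2 = c("8mer" = 1, "none" = 0.2)),
               "invalid-argument")
  expect_error(sim_config(frac_bad_correlation = 0.8, frac_low_signal = 0.5),
               "invalid-argument")
})
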