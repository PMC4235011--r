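# SAM-style enrichment statistic, permutation null, local FDR and target
# calling.

test_that("enrichment delta is the difference of condition means", {
  m <- toy_ratio_matrix(rbind(c(4, 4, 1, 1), c(2, 2, 2, 2)),
                        c("ip", "ip", "mock", "mock"))
  d <- enrichment_ratio(m)
  expect_equal(unname(d), c(3, 0))
  # missing cells excluded from the mean
  m2 <- toy_ratio_matrix(rbind(c(4, NA, 1, 1)), c("ip", "ip", "mock", "mock"))
  expect_equal(unname(enrichment_ratio(m2)), 3)
  # a gene empty in one condition is skipped with a warning
  m3 <- toy_ratio_matrix(rbind(c(NA, NA, 1, 1)), c("ip", "ip", "mock", "mock"))
  expect_warning(d3 <- enrichment_ratio(m3), "skipped")
  expect_true(is.na(d3[1]))
})

test_that("expression change mirrors enrichment with sign kept", {
  m <- toy_ratio_matrix(rbind(c(-1, -1, 0, 0), c(1, 1, 1, 1)),
                        c("expression", "expression", "mock", "mock"))
  ch <- expression_change(m)
  expect_equal(unname(ch), c(-1, 0))
})

test_that("moderated d equals the brute-force statistic when s0 = 0", {
  set.seed(101)
  vals <- matrix(rnorm(10 * 6), nrow = 10)
  m <- toy_ratio_matrix(vals, c("ip", "ip", "ip", "mock", "mock", "mock"))
  fit <- sam_statistic(m, params = sam_parameters(s0 = 0))
  want <- brute_sam_d(vals, 1:3, 4:6, s0 = 0)
  expect_equal(unname(fit$d), unname(want), tolerance = 1e-12)
  expect_equal(unname(fit$delta),
               unname(rowMeans(vals[, 1:3]) - rowMeans(vals[, 4:6])))
})

test_that("an all-zero matrix yields d = 0 everywhere", {
  m <- toy_ratio_matrix(matrix(0, nrow = 5, ncol = 4),
                        c("ip", "ip", "mock", "mock"))
  fit <- sam_statistic(m)
  expect_equal(unname(fit$d), rep(0, 5))
})

test_that("gene with delta 3.0, pooled sd 0.5, s0 0.1 gives d = 5", {
  # scale within-group deviations so the pooled SE is exactly 0.5
  a <- c(3.5, 2.5); b <- c(0.5, -0.5)
  s_raw <- sqrt((1 / 2 + 1 / 2) / 2 * (sum((a - 3)^2) + sum(b^2)))
  a2 <- 3 + (a - 3) * 0.5 / s_raw
  b2 <- b * 0.5 / s_raw
  m <- toy_ratio_matrix(rbind(c(a2, b2)), c("ip", "ip", "mock", "mock"))
  fit <- sam_statistic(m, params = sam_parameters(s0 = 0.1))
  expect_equal(unname(fit$pooled_sd), 0.5, tolerance = 1e-12)
  expect_equal(unname(fit$d), 5, tolerance = 1e-12)
})

test_that("swapping condition labels negates delta and d exactly", {
  set.seed(102)
  vals <- matrix(rnorm(20 * 4), nrow = 20)
  m <- toy_ratio_matrix(vals, c("ip", "ip", "mock", "mock"))
  p <- sam_parameters(s0 = 0.2)
  f1 <- sam_statistic(m, params = p)
  f2 <- sam_statistic(m, ip_labels = colnames(m)[3:4],
                      mock_labels = colnames(m)[1:2], params = p)
  expect_equal(unname(f1$delta), -unname(f2$delta))
  expect_equal(unname(f1$d), -unname(f2$d))
})

test_that("exhaustive permutation null matches independent enumeration", {
  set.seed(103)
  vals <- matrix(rnorm(15 * 6), nrow = 15)
  m <- toy_ratio_matrix(vals, c("ip", "ip", "ip", "mock", "mock", "mock"))
  p <- sam_parameters(s0 = 0.1)
  calls <- permutation_local_fdr(m, params = p)
  null_d <- attr(calls, "null_d")
  expect_equal(ncol(null_d), choose(6, 3) - 2)
  # enumerate independently: every 3-subset of columns except the observed
  # partition (the observed subset and its complement)
  subsets <- combn(6, 3, simplify = FALSE)
  subsets <- Filter(function(s) !identical(s, 1:3) && !identical(s, 4:6),
                    subsets)
  want <- sapply(subsets, function(s) {
    brute_sam_d(vals, s, setdiff(1:6, s), s0 = 0.1)
  })
  got_sorted <- t(apply(null_d, 1, sort))
  want_sorted <- t(apply(want, 1, sort))
  expect_equal(unname(got_sorted), unname(want_sorted), tolerance = 1e-12)
})

test_that("the most extreme statistic has the smallest local FDR", {
  set.seed(104)
  n <- 300
  vals <- matrix(rnorm(n * 4, sd = 0.3), nrow = n)
  vals[1, 1:2] <- vals[1, 1:2] + 5  # one planted extreme gene
  m <- toy_ratio_matrix(vals, c("ip", "ip", "mock", "mock"))
  calls <- permutation_local_fdr(m)
  top <- which.max(abs(calls$d_stat))
  expect_equal(top, 1L)
  expect_true(all(calls$local_fdr[top] <= calls$local_fdr[-top]))
})

test_that("target lists nest across FDR thresholds and require delta > 0", {
  set.seed(105)
  n <- 400
  vals <- matrix(rnorm(n * 4, sd = 0.3), nrow = n)
  vals[1:20, 1:2] <- vals[1:20, 1:2] + 2
  vals[21:30, 1:2] <- vals[21:30, 1:2] - 2  # depleted, must never be called
  m <- toy_ratio_matrix(vals, c("ip", "ip", "mock", "mock"))
  calls <- permutation_local_fdr(m)
  t1 <- call_targets(calls, sam_parameters(fdr_threshold = 0.01))
  t5 <- call_targets(calls, sam_parameters(fdr_threshold = 0.05))
  expect_true(all(t1$row_key %in% t5$row_key))
  expect_true(all(t5$delta > 0))
  expect_false(any(rownames(m)[21:30] %in% t5$row_key))
  # sorted by descending d
  expect_false(is.unsorted(rev(t1$d_stat)))
})

test_that("degenerate null sets all local FDR to 1 and calls nothing", {
  m <- toy_ratio_matrix(matrix(0, nrow = 6, ncol = 4),
                        c("ip", "ip", "mock", "mock"))
  expect_warning(calls <- permutation_local_fdr(m), "degenerate")
  expect_true(all(calls$local_fdr == 1))
  expect_equal(nrow(call_targets(calls)), 0L)
})

test_that("single-column conditions fall back to delta ranking", {
  m <- toy_ratio_matrix(rbind(c(3, 1), c(0, 0)), c("ip", "mock"))
  expect_warning(fit <- sam_statistic(m), "fall")
  expect_equal(unname(fit$d), c(2, 0))
  expect_true(all(is.na(fit$pooled_sd)))
})

test_that("per-column shifts are absorbed by normalization end to end", {
  truth <- toy_truth(300, rep(c("8mer", "none"), c(50, 250)),
                     rep(c(1.5, 0), c(50, 250)))
  cfg <- sim_config(n_genes = 300, frac_bad_correlation = 0,
                    frac_low_signal = 0, rng_seed = 44)
  sim <- simulate_arrays(truth, cfg)
  flt <- filter_elements(sim$tables)
  mat1 <- assemble_matrix(sim$tables, flt$retained, sim$conditions)
  # rescale one array's channel 1 by a constant factor (adds a constant in
  # log space), then re-normalize
  sim$tables$ip_2$ch1_fg <- sim$tables$ip_2$ch1_bg +
    8 * (sim$tables$ip_2$ch1_fg - sim$tables$ip_2$ch1_bg)
  mat2 <- assemble_matrix(sim$tables, flt$retained, sim$conditions)
  expect_equal(unname(enrichment_ratio(mat1)), unname(enrichment_ratio(mat2)),
               tolerance = 1e-9)
})

test_that("calls TSV and metadata are written with run parameters", {
  set.seed(106)
  vals <- matrix(rnorm(50 * 4), nrow = 50)
  m <- toy_ratio_matrix(vals, c("ip", "ip", "mock", "mock"))
  calls <- permutation_local_fdr(m, rng_seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calls(calls, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 50L)
  expect_true(all(c("delta", "pooled_sd", "d_stat", "local_fdr",
                    "is_target") %in% names(back)))
  meta <- yaml::read_yaml(paste0(path, ".meta.yml"))
  expect_equal(meta$rng_seed, 7L)
  expect_equal(meta$n_permutations, choose(4, 2) - 2)
})
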