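# SAM-style enrichment calling: per-gene IP-vs-mock delta, moderated d
# statistic with tuned fudge factor s0, permutation null, local FDR, and
# the 1% target call.
#
# The moderated statistic is d = delta / (s + s0), where s is the
# two-sample pooled standard error and s0 a small positive fudge factor
# chosen so that the spread of d is uninformative about s (the canonical
# SAM recipe). The null distribution of d is built by recomputing it under
# balanced relabelings of the IP/mock columns, and the local FDR of a gene
# is the ratio of null to observed kernel density at its d, scaled by an
# estimate of the null proportion pi0.

# Columns of a gene_ratio_matrix belonging to a condition.
condition_cols <- function(mat, condition) {
  conds <- attr(mat, "conditions")
  if (is.null(conds)) stop("invalid-input: matrix lacks condition labels")
  names(conds)[conds == condition]
}

resolve_labels <- function(mat, labels, condition) {
  if (is.null(labels)) labels <- condition_cols(mat, condition)
  if (!length(labels)) {
    stop("invalid-input: empty ", condition, " label set")
  }
  if (!all(labels %in% colnames(mat))) {
    stop("invalid-input: labels absent from matrix: ",
         paste(setdiff(labels, colnames(mat)), collapse = ", "))
  }
  labels
}

# Per-gene mean and within-group sum of squares with NA exclusion.
group_stats <- function(mat, labels) {
  sub <- mat[, labels, drop = FALSE]
  n <- rowSums(!is.na(sub))
  mean <- rowMeans(sub, na.rm = TRUE)
  mean[n == 0] <- NA_real_
  ss <- rowSums((sub - mean)^2, na.rm = TRUE)
  ss[n == 0] <- NA_real_
  list(n = n, mean = mean, ss = ss)
}

#' Per-gene enrichment: mean log2(IP) minus mean log2(mock)
#'
#' Missing cells are excluded from each condition mean. Genes with no
#' non-missing value in one of the conditions get `NA` with a warning.
#'
#' @param mat A `gene_ratio_matrix` from [assemble_matrix()].
#' @param ip_labels,mock_labels Column labels of the two conditions;
#'   default: taken from the matrix's `conditions` attribute.
#' @return Named numeric vector of deltas (log2 units), one per matrix row.
#' @export
enrichment_ratio <- function(mat, ip_labels = NULL, mock_labels = NULL) {
  ip_labels <- resolve_labels(mat, ip_labels, "ip")
  mock_labels <- resolve_labels(mat, mock_labels, "mock")
  gi <- group_stats(mat, ip_labels)
  gm <- group_stats(mat, mock_labels)
  delta <- gi$mean - gm$mean
  if (anyNA(delta)) {
    warning(sum(is.na(delta)), " gene(s) skipped: no non-missing value in ",
            "one condition")
  }
  setNames(delta, rownames(mat))
}

#' Per-gene abundance change between transfected and mock whole-cell arrays
#'
#' Identical contract to [enrichment_ratio()] on an expression-mode matrix;
#' negative values mean reduced abundance in the transfected cells.
#'
#' @param mat Expression-mode `gene_ratio_matrix`.
#' @param transfected_labels,mock_labels Column labels of the two
#'   conditions; default `"expression"`-tagged vs `"mock"`-tagged columns.
#' @return Named numeric vector of log2 abundance changes.
#' @export
expression_change <- function(mat, transfected_labels = NULL,
                              mock_labels = NULL) {
  transfected_labels <- resolve_labels(mat, transfected_labels, "expression")
  mock_labels <- resolve_labels(mat, mock_labels, "mock")
  gi <- group_stats(mat, transfected_labels)
  gm <- group_stats(mat, mock_labels)
  delta <- gi$mean - gm$mean
  if (anyNA(delta)) {
    warning(sum(is.na(delta)), " gene(s) skipped: no non-missing value in ",
            "one condition")
  }
  setNames(delta, rownames(mat))
}

#' SAM analysis parameters
#'
#' @param s0 Fudge factor added to the pooled standard error; `NULL`
#'   (default) tunes it from the data as the percentile of the pooled-SD
#'   distribution minimizing the coefficient of variation of the statistic's
#'   spread across pooled-SD windows.
#' @param n_permutations Permutation draws when the balanced-relabeling
#'   space exceeds 500 (exhaustive enumeration is used below that).
#' @param fdr_threshold Local FDR threshold for target calls (default 0.01).
#' @return A `sam_parameters` list.
#' @export
sam_parameters <- function(s0 = NULL, n_permutations = 1000L,
                           fdr_threshold = 0.01) {
  stopifnot(is.null(s0) || s0 >= 0, n_permutations >= 1,
            fdr_threshold > 0, fdr_threshold < 1)
  structure(list(s0 = s0, n_permutations = as.integer(n_permutations),
                 fdr_threshold = fdr_threshold), class = "sam_parameters")
}

# d = delta / (s + s0); degenerate 0/0 is defined as 0.
moderated_d <- function(delta, s, s0) {
  denom <- s + s0
  d <- delta / denom
  d[!is.na(delta) & delta == 0 & (is.na(denom) | denom == 0)] <- 0
  d
}

# Canonical s0 tuning: candidates are the 0,5,...,100 percentiles of s;
# quality is the coefficient of variation, across deciles of s, of the MAD
# of d within each decile. Deterministic; ties go to the smallest
# percentile.
tune_s0 <- function(delta, s) {
  ok <- !is.na(delta) & !is.na(s)
  if (sum(ok) < 20 || all(s[ok] == s[ok][1])) {
    return(unname(median(s[ok], na.rm = TRUE)))
  }
  sv <- s[ok]; dv <- delta[ok]
  alphas <- seq(0, 1, by = 0.05)
  cand <- unname(quantile(sv, alphas, names = FALSE))
  breaks <- unique(quantile(sv, seq(0, 1, by = 0.1), names = FALSE))
  if (length(breaks) < 3) return(unname(median(sv)))
  bins <- cut(sv, breaks, include.lowest = TRUE)
  cv <- vapply(cand, function(s0) {
    d <- dv / (sv + s0)
    v <- tapply(d, bins, mad)
    v <- v[!is.na(v)]
    if (!length(v) || mean(v) == 0) return(Inf)
    sd(v) / mean(v)
  }, numeric(1))
  if (all(!is.finite(cv))) return(0)
  cand[which.min(cv)]
}

#' SAM-style moderated enrichment statistic
#'
#' Computes, per gene, the difference in condition means (`delta`), the
#' two-sample pooled standard error, and the moderated statistic
#' `d = delta / (pooled_sd + s0)`. With fewer than two usable columns in a
#' condition no pooled SD exists; the function warns and falls back to
#' ranking by `delta` (`d = delta`, `pooled_sd = NA`).
#'
#' @inheritParams enrichment_ratio
#' @param params A [sam_parameters()].
#' @return A `sam_fit` list: `delta`, `pooled_sd`, `d`, `s0`, `fallback`,
#'   plus the resolved `ip_labels` / `mock_labels`.
#' @export
sam_statistic <- function(mat, ip_labels = NULL, mock_labels = NULL,
                          params = sam_parameters()) {
  ip_labels <- resolve_labels(mat, ip_labels, "ip")
  mock_labels <- resolve_labels(mat, mock_labels, "mock")
  st <- sam_fit(mat, ip_labels, mock_labels, params$s0)
  st$ip_labels <- ip_labels
  st$mock_labels <- mock_labels
  structure(st, class = "sam_fit")
}

sam_fit <- function(mat, ip_labels, mock_labels, s0 = NULL) {
  gi <- group_stats(mat, ip_labels)
  gm <- group_stats(mat, mock_labels)
  delta <- gi$mean - gm$mean
  fallback <- length(ip_labels) < 2 || length(mock_labels) < 2
  if (fallback) {
    warning("fewer than 2 columns in a condition; falling back to delta ",
            "ranking (no pooled SD)")
    s <- rep(NA_real_, length(delta))
    d <- delta
    s0 <- 0
  } else {
    df <- gi$n + gm$n - 2
    s <- sqrt(((1 / gi$n + 1 / gm$n) / df) * (gi$ss + gm$ss))
    s[df < 1] <- NA_real_
    if (is.null(s0)) s0 <- tune_s0(delta, s)
    d <- moderated_d(delta, s, s0)
  }
  list(delta = setNames(delta, rownames(mat)),
       pooled_sd = setNames(s, rownames(mat)),
       d = setNames(d, rownames(mat)),
       s0 = s0, fallback = fallback)
}

# All balanced relabelings of the pooled IP+mock columns that change the
# observed partition: the observed assignment is excluded, and so is its
# complement when the group sizes are equal (it is the same partition with
# the sign of the statistic flipped, so it would carry the full treatment
# effect into the null). Exhaustive when the space has <= 500 relabelings,
# otherwise `n_permutations` uniform draws under `rng_seed`.
permutation_assignments <- function(n_ip, n_mock, n_permutations, rng_seed) {
  n <- n_ip + n_mock
  observed <- seq_len(n_ip)
  complement <- if (n_ip == n_mock) sort(setdiff(seq_len(n), observed))
                else NULL
  is_trivial <- function(s) {
    identical(s, observed) || (!is.null(complement) && identical(s, complement))
  }
  total <- choose(n, n_ip) - 1 - as.integer(!is.null(complement))
  if (total < 1) stop("invalid-input: no non-trivial label permutation exists")
  if (total <= 500) {
    all_sets <- combn(n, n_ip, simplify = FALSE)
    return(Filter(Negate(is_trivial), all_sets))
  }
  with_rng_seed(rng_seed, {
    out <- vector("list", n_permutations)
    i <- 1L
    while (i <= n_permutations) {
      s <- sort(sample.int(n, n_ip))
      if (is_trivial(s)) next
      out[[i]] <- s
      i <- i + 1L
    }
    out
  })
}

#' Permutation null and local false discovery rate
#'
#' Recomputes the moderated statistic under balanced relabelings of the
#' IP/mock columns (exhaustive when at most 500 relabelings exist, else
#' `n_permutations` seeded uniform draws; the observed labeling is never
#' part of the null). The local FDR of a gene at statistic `d` is
#' `min(1, pi0 * f0(d) / f(d))`, with `f0` and `f` Gaussian kernel density
#' estimates of the null and observed statistics (Silverman's rule
#' bandwidth) and `pi0 = min(1, 2 * mean(|d| <= median |d_null|))`. The
#' estimate is then made monotone non-increasing toward each tail by a
#' running maximum from the most extreme `d` inward, separately for the
#' positive and negative side (the relabeling null is asymmetric when true
#' effects are present), so an extreme statistic can never have a larger
#' local FDR than a central one of the same sign.
#'
#' @inheritParams sam_statistic
#' @param rng_seed Seed for permutation draws (only used when sampling).
#' @return An `enrichment_calls` data frame: `row_key`, `gene_id`,
#'   `oligo_index`, `delta`, `pooled_sd`, `d_stat`, `local_fdr`; attributes
#'   `s0`, `pi0`, `n_permutations`, `rng_seed`, `null_d` (genes x
#'   relabelings matrix).
#' @export
permutation_local_fdr <- function(mat, ip_labels = NULL, mock_labels = NULL,
                                  params = sam_parameters(),
                                  rng_seed = 1L) {
  ip_labels <- resolve_labels(mat, ip_labels, "ip")
  mock_labels <- resolve_labels(mat, mock_labels, "mock")
  fit <- sam_fit(mat, ip_labels, mock_labels, params$s0)
  cols <- c(ip_labels, mock_labels)
  assigns <- permutation_assignments(length(ip_labels), length(mock_labels),
                                     params$n_permutations, rng_seed)
  null_d <- vapply(assigns, function(sel) {
    pfit <- sam_fit(mat, cols[sel], cols[-sel], s0 = fit$s0)
    pfit$d
  }, numeric(nrow(mat)))
  null_d <- matrix(null_d, nrow = nrow(mat),
                   dimnames = list(rownames(mat), NULL))

  d <- fit$d
  ok <- !is.na(d)
  null_vec <- null_d[ok, , drop = FALSE]
  null_vec <- null_vec[!is.na(null_vec)]
  lfdr <- rep(NA_real_, length(d))
  if (!length(null_vec) || max(null_vec) - min(null_vec) < 1e-12) {
    warning("degenerate permutation null; local FDR set to 1")
    lfdr[ok] <- 1
    pi0 <- 1
  } else {
    pi0 <- min(1, 2 * mean(abs(d[ok]) <= median(abs(null_vec))))
    # one common bandwidth for both densities: the ratio of two kernel
    # estimates is only stable in the tails when numerator and denominator
    # are smoothed identically
    bw <- min(bw.nrd0(d[ok]), bw.nrd0(null_vec))
    f <- kde_at(d[ok], d[ok], bw)
    f0 <- kde_at(d[ok], null_vec, bw)
    raw <- pmin(1, pi0 * f0 / f)
    # Isotonic smoothing toward each tail separately: the permutation null
    # is not symmetric (true effects appear, negated, in the swapped
    # relabelings), so the two tails carry different evidence. Within a
    # tail the local FDR is projected onto the cone of functions
    # non-increasing in |d| (pool-adjacent-violators), which smooths
    # isolated density-ratio spikes instead of letting them dominate.
    dv <- d[ok]
    mono <- raw
    for (side in list(dv >= 0, dv < 0)) {
      if (!any(side)) next
      mono[side] <- iso_decreasing(abs(dv[side]), raw[side])
    }
    lfdr[ok] <- pmin(1, mono)
  }
  keys <- rownames(mat)
  split_keys <- strsplit(keys, ":", fixed = TRUE)
  calls <- data.frame(
    row_key = keys,
    gene_id = vapply(split_keys, `[`, "", 1),
    oligo_index = suppressWarnings(
      as.integer(vapply(split_keys, function(x) x[2], ""))),
    delta = unname(fit$delta),
    pooled_sd = unname(fit$pooled_sd),
    d_stat = unname(d),
    local_fdr = lfdr,
    stringsAsFactors = FALSE)
  structure(calls, s0 = fit$s0, pi0 = pi0,
            n_permutations = length(assigns), rng_seed = rng_seed,
            null_d = null_d, class = c("enrichment_calls", "data.frame"))
}

# Least-squares isotonic fit of y as a non-increasing function of x
# (pool-adjacent-violators via stats::isoreg on the reversed order).
iso_decreasing <- function(x, y) {
  ord <- order(x)
  rev_fit <- isoreg(rev(y[ord]))$yf  # non-decreasing along descending x
  out <- y
  out[ord] <- rev(rev_fit)
  out
}

# Gaussian kernel density of `sample` evaluated at arbitrary points `x`.
kde_at <- function(x, sample, bw) {
  if (bw <= 0) bw <- 1e-6
  vapply(x, function(xi) mean(dnorm(xi - sample, sd = bw)), numeric(1))
}

#' Call putative targets at a local FDR threshold
#'
#' A gene is a target iff its local FDR is at or below the threshold and
#' its enrichment is positive (recruitment to the RISC is directional).
#' The list is sorted by descending `d_stat`, ties broken by `row_key`.
#'
#' @param calls An `enrichment_calls` data frame from
#'   [permutation_local_fdr()].
#' @param params A [sam_parameters()] (supplies `fdr_threshold`), or a bare
#'   numeric threshold.
#' @return The subset of `calls` that are targets, sorted, with an
#'   `is_target` column (all `TRUE`).
#' @export
call_targets <- function(calls, params = sam_parameters()) {
  thr <- if (is.numeric(params)) params else params$fdr_threshold
  sel <- !is.na(calls$local_fdr) & calls$local_fdr <= thr &
    !is.na(calls$delta) & calls$delta > 0
  out <- calls[sel, , drop = FALSE]
  out <- out[order(-out$d_stat, out$row_key), , drop = FALSE]
  out$is_target <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Write enrichment calls and run metadata
#'
#' Calls go to `<path>` as TSV (with an `is_target` column at the given
#' threshold); run metadata (s0, pi0, permutation count, seed, threshold)
#' to `<path>.meta.yml`.
#'
#' @param calls An `enrichment_calls` data frame.
#' @param path Output TSV path.
#' @param params A [sam_parameters()].
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, params = sam_parameters()) {
  thr <- params$fdr_threshold
  df <- as.data.frame(calls)
  df$is_target <- !is.na(df$local_fdr) & df$local_fdr <= thr &
    !is.na(df$delta) & df$delta > 0
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(s0 = as.numeric(attr(calls, "s0")),
               pi0 = as.numeric(attr(calls, "pi0")),
               n_permutations = as.integer(attr(calls, "n_permutations")),
               rng_seed = as.integer(attr(calls, "rng_seed")),
               fdr_threshold = thr)
  yaml::write_yaml(meta, paste0(path, ".meta.yml"))
  invisible(path)
}
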