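# Downstream analyses: stratified cumulative distributions of enrichment
# by seed-site class (with KS tests against the no-site class and the
# site-efficacy hierarchy check), and unsupervised hierarchical clustering
# of the ratio matrix.

#' Stratify per-gene enrichment by seed-site class
#'
#' Partitions genes by the best seed-match type of their 3' UTR and builds
#' the empirical cumulative distribution of enrichment per class, with a
#' two-sample KS test of each site class against the `"none"` class.
#' Classes smaller than `min_class_size` are flagged (`small = TRUE`) but
#' kept.
#'
#' @param values Named numeric vector of per-gene enrichment (log2 IP minus
#'   mock), names = gene IDs.
#' @param annotations Data frame with `gene_id` and `best_type` columns
#'   (e.g. from [classify_utrs()]); every gene in `values` must appear.
#' @param min_class_size Classes below this size are flagged (default 5).
#' @return A `stratified_cdf` list: `classes` (per class: `values` sorted,
#'   `n`, `median`, `ecdf`, `small`), `tests` (data frame of KS `D` and `p`
#'   per class vs `"none"`), `min_class_size`.
#' @export
stratify <- function(values, annotations, min_class_size = 5L) {
  if (!length(values)) stop("invalid-input: empty enrichment vector")
  stopifnot(!is.null(names(values)),
            all(c("gene_id", "best_type") %in% names(annotations)))
  idx <- match(names(values), annotations$gene_id)
  if (anyNA(idx)) {
    stop("invalid-input: genes lack annotations: ",
         paste(head(names(values)[is.na(idx)]), collapse = ", "))
  }
  values <- values[!is.na(values)]
  type <- annotations$best_type[match(names(values), annotations$gene_id)]
  present <- intersect(seed_site_types(), unique(type))
  classes <- lapply(present, function(cl) {
    v <- sort(unname(values[type == cl]))
    list(values = v, n = length(v), median = median(v),
         ecdf = ecdf(v), small = length(v) < min_class_size)
  })
  names(classes) <- present
  tests <- NULL
  if ("none" %in% present) {
    none_v <- classes[["none"]]$values
    site_classes <- setdiff(present, "none")
    if (length(site_classes)) {
      tests <- do.call(rbind, lapply(site_classes, function(cl) {
        ks <- ks_two_sample(classes[[cl]]$values, none_v)
        data.frame(class = cl, n = classes[[cl]]$n, D = ks$D, p = ks$p,
                   stringsAsFactors = FALSE)
      }))
      rownames(tests) <- NULL
    }
  }
  structure(list(classes = classes, tests = tests,
                 min_class_size = as.integer(min_class_size)),
            class = "stratified_cdf")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum of the absolute difference between the two empirical
#' CDFs. The p-value is exact when `n_a * n_b <= 100` and asymptotic
#' otherwise.
#'
#' @param a,b Numeric samples (each non-empty).
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) stop("invalid-input: empty sample")
  kt <- suppressWarnings(
    ks.test(a, b, exact = length(a) * length(b) <= 100))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Check the seed-site recruitment-efficiency hierarchy
#'
#' Verifies that class medians are strictly ordered
#' 8mer > 7mer-m8 > 7mer-1A > 6mer-n2-7 > 6mer-n3-8 > none over the classes
#' present and meeting the minimum size; small classes are excluded from the
#' verdict but listed in the report.
#'
#' @param cdf A `stratified_cdf` from [stratify()].
#' @return List: `ok` (logical verdict), `report` (data frame of adjacent
#'   comparisons: `stronger`, `weaker`, medians, `holds`), `excluded`
#'   (classes below the minimum size).
#' @export
check_hierarchy <- function(cdf) {
  stopifnot(inherits(cdf, "stratified_cdf"))
  present <- intersect(seed_site_types(), names(cdf$classes))
  usable <- present[!vapply(cdf$classes[present], `[[`, TRUE, "small")]
  if (length(usable) < 2) {
    stop("invalid-input: need at least two usable classes")
  }
  med <- vapply(cdf$classes[usable], `[[`, numeric(1), "median")
  report <- data.frame(stronger = usable[-length(usable)],
                       weaker = usable[-1],
                       median_stronger = unname(med[-length(med)]),
                       median_weaker = unname(med[-1]),
                       holds = unname(med[-length(med)] > med[-1]),
                       stringsAsFactors = FALSE)
  list(ok = all(report$holds), report = report,
       excluded = setdiff(present, usable))
}

#' Unsupervised hierarchical clustering of a ratio matrix
#'
#' Agglomerative average-linkage clustering with distance 1 minus the
#' Pearson correlation over shared non-missing entries. Items are ordered
#' lexicographically before clustering so exact ties break
#' deterministically. A pair with fewer than two shared observations gets
#' the maximum distance 2 (with a warning); an item with fewer than two
#' shared observations against every other item is an error.
#'
#' @param mat Numeric matrix; rows are clustered (transpose to cluster
#'   arrays/columns).
#' @param method Linkage (default `"average"`).
#' @return An `hclust` object (leaf labels = rownames).
#' @export
hierarchical_cluster <- function(mat, method = "average") {
  if (is.null(rownames(mat))) rownames(mat) <- seq_len(nrow(mat))
  if (nrow(mat) < 2) stop("invalid-input: need at least 2 items to cluster")
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  cmat <- suppressWarnings(cor(t(mat), use = "pairwise.complete.obs"))
  diag(cmat) <- 1
  bad <- rownames(cmat)[vapply(seq_len(nrow(cmat)), function(i) {
    all(is.na(cmat[i, -i]))
  }, TRUE)]
  if (length(bad)) {
    stop("invalid-input: item(s) with < 2 shared observations with every ",
         "other item: ", paste(bad, collapse = ", "))
  }
  if (anyNA(cmat)) {
    warning("pairs with < 2 shared observations assigned maximum distance 2")
    cmat[is.na(cmat)] <- -1
  }
  d <- as.dist(1 - cmat)
  hclust(d, method = method)
}

#' Write a dendrogram in Newick format
#'
#' Branch lengths carry the merge heights (via [ape::as.phylo()]).
#'
#' @param hc An `hclust` object.
#' @param path Output Newick path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(hc, path) {
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write per-class stratification summaries and ECDF tables
#'
#' `<path>` gets the per-class summary (class, n, small flag, median, KS D
#' and p vs the no-site class); `<ecdf_path>` gets a long-format table of
#' (class, x, ecdf) evaluated at each class's own values, suitable for
#' plotting cumulative distributions.
#'
#' @param cdf A `stratified_cdf`.
#' @param path Summary TSV path.
#' @param ecdf_path Optional ECDF table TSV path.
#' @return `path`, invisibly.
#' @export
write_stratified <- function(cdf, path, ecdf_path = NULL) {
  cls <- names(cdf$classes)
  summ <- data.frame(
    class = cls,
    n = vapply(cdf$classes, `[[`, integer(1), "n"),
    small = vapply(cdf$classes, `[[`, logical(1), "small"),
    median = vapply(cdf$classes, `[[`, numeric(1), "median"),
    stringsAsFactors = FALSE)
  if (!is.null(cdf$tests)) {
    summ$ks_D_vs_none <- cdf$tests$D[match(cls, cdf$tests$class)]
    summ$ks_p_vs_none <- cdf$tests$p[match(cls, cdf$tests$class)]
  }
  write.table(summ, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ecdf_path)) {
    long <- do.call(rbind, lapply(cls, function(cl) {
      v <- cdf$classes[[cl]]$values
      data.frame(class = cl, x = v, ecdf = cdf$classes[[cl]]$ecdf(v),
                 stringsAsFactors = FALSE)
    }))
    write.table(long, ecdf_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
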