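# Independent oracles and fixture builders used across the suite. These
# deliberately avoid the package's own code paths (and Biostrings): naive
# sliding-window scans, hand-rolled reverse complement, brute-force
# agglomeration.

naive_revcomp <- function(x) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

naive_site_patterns <- function(mirna) {
  mirna <- chartr("T", "U", toupper(mirna))
  rc27 <- naive_revcomp(substr(mirna, 2, 7))
  rc38 <- naive_revcomp(substr(mirna, 3, 8))
  rc28 <- naive_revcomp(substr(mirna, 2, 8))
  c("8mer" = paste0(rc28, "A"), "7mer-m8" = rc28,
    "7mer-1A" = paste0(rc27, "A"), "6mer-n2-7" = rc27, "6mer-n3-8" = rc38)
}

# Sliding-window classification with the same containment rule, written
# against character vectors position by position.
naive_classify <- function(utr, mirna) {
  utr <- chartr("T", "U", toupper(utr))
  pats <- naive_site_patterns(mirna)
  n <- nchar(utr)
  st <- integer(0); en <- integer(0); ty <- character(0)
  for (k in seq_along(pats)) {
    p <- pats[[k]]; w <- nchar(p)
    if (w > n) next
    for (i in seq_len(n - w + 1)) {
      if (substr(utr, i, i + w - 1) != p) next
      j <- i + w - 1L
      if (any(st <= i & en >= j)) next
      st <- c(st, i); en <- c(en, j); ty <- c(ty, names(pats)[k])
    }
  }
  best <- if (length(ty)) names(pats)[min(match(ty, names(pats)))] else "none"
  ord <- order(st, en)
  list(best = best,
       sites = data.frame(start = st[ord], end = en[ord], type = ty[ord],
                          stringsAsFactors = FALSE))
}

# Position-by-position scan for WWCAAWG / CWTTGWW (W = A or T).
naive_tcf <- function(sequence) {
  s <- strsplit(toupper(sequence), "")[[1]]
  W <- function(ch) ch %in% c("A", "T")
  pos <- integer(0); ori <- character(0)
  for (i in seq_len(max(0, length(s) - 6))) {
    w <- s[i:(i + 6)]
    if (W(w[1]) && W(w[2]) && w[3] == "C" && w[4] == "A" && w[5] == "A" &&
        W(w[6]) && w[7] == "G") {
      pos <- c(pos, i); ori <- c(ori, "forward")
    }
    if (w[1] == "C" && W(w[2]) && w[3] == "T" && w[4] == "T" && w[5] == "G" &&
        W(w[6]) && W(w[7])) {
      pos <- c(pos, i); ori <- c(ori, "reverse")
    }
  }
  ord <- order(pos, ori)
  data.frame(position = pos[ord], orientation = ori[ord],
             stringsAsFactors = FALSE)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force average-linkage agglomeration on 1 - Pearson distance,
# tracking merge heights only (labels sorted lexicographically like the
# implementation's tie-break).
brute_average_linkage_heights <- function(mat) {
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  n <- nrow(mat)
  d <- 1 - stats::cor(t(mat))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < bestd - 1e-12) { bestd <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# A gene_ratio_matrix built directly from values (bypassing arrayqc), for
# statistics tests.
toy_ratio_matrix <- function(values, conditions) {
  stopifnot(ncol(values) == length(conditions))
  if (is.null(colnames(values))) {
    colnames(values) <- paste0(conditions, "_", seq_along(conditions))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("G%03d:1", seq_len(nrow(values)))
  }
  structure(values,
            conditions = stats::setNames(conditions, colnames(values)),
            class = c("gene_ratio_matrix", class(values)))
}

# Ground-truth table without sequences, for array-simulation tests.
toy_truth <- function(n_genes, classes, effects) {
  data.frame(gene_id = sprintf("G%05d", seq_len(n_genes)),
             site_class = classes,
             true_log2_enrichment = effects,
             stringsAsFactors = FALSE)
}

# Full synthetic path from a truth table to a normalized ratio matrix.
sim_to_matrix <- function(truth, cfg) {
  sim <- simulate_arrays(truth, cfg)
  flt <- filter_elements(sim$tables)
  assemble_matrix(sim$tables, flt$retained, sim$conditions)
}

# Independent SAM-style statistic for a complete (no-NA) matrix with fixed
# s0: plain two-sample pooled-SE t-like statistic computed longhand.
brute_sam_d <- function(values, ip_idx, mock_idx, s0 = 0) {
  apply(values, 1, function(x) {
    a <- x[ip_idx]; b <- x[mock_idx]
    n1 <- length(a); n2 <- length(b)
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    s <- sqrt((1 / n1 + 1 / n2) / (n1 + n2 - 2) * ss)
    (mean(a) - mean(b)) / (s + s0)
  })
}
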