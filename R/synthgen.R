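# Synthetic RIP-chip data with planted ground truth: miRNA and UTR
# generation with planted seed sites, and two-channel array-element tables
# for IP and mock-IP hybridizations.
#
# The generator emulates a HEEBO-like two-channel design: channel 2 carries
# a universal reference, channel 1 the IP (or mock-IP) sample, so the log2
# ratio of an element measures recruitment. Site classes and QC failures
# are assigned by exact quota so tests can assert counts.

#' Simulation configuration for synthetic RIP-chip data
#'
#' Defaults describe the study conditions the pipeline is validated under:
#' five seed-site classes of 200 genes each plus 200 no-site genes, planted
#' recruitment effects ordered 8mer (1.5) > 7mer-m8 (1.0) > 7mer-1A (0.7) >
#' 6mer-n2-7 (0.4) > 6mer-n3-8 (0.2) log2 units, per-cell noise 0.3 log2
#' units, and two IP plus two mock hybridizations (two independent
#' transfections per condition).
#'
#' @param n_genes Number of simulated genes.
#' @param oligos_per_gene Array elements (oligos) per gene, each treated as
#'   a separate measurement downstream.
#' @param n_arrays_ip,n_arrays_mock Hybridizations per condition.
#' @param utr_length_mean,utr_length_sd Mean and SD of 3' UTR length in
#'   nucleotides; lengths are log-normal, clamped to `[50, 10 * mean]`.
#' @param site_class_fractions Named proportions of genes per site class
#'   (the remainder gets class `"none"`); must sum to at most 1.
#' @param effect_log2 Named mean log2 recruitment effect per site class;
#'   `"none"` must map to 0.
#' @param noise_sd Per-element, per-array log2 noise SD on the ratio.
#' @param baseline_log_intensity_mean,baseline_log_intensity_sd Normal
#'   parameters of the reference-channel log2 signal.
#' @param background_intensity Constant per-spot background, intensity units.
#' @param frac_bad_correlation Proportion of elements stamped with a pixel
#'   regression correlation below 0.6 on every array.
#' @param frac_low_signal Proportion of elements stamped with
#'   signal/background below 2.5 in both channels on every array.
#' @param rng_seed Integer seed; the same config is byte-reproducible.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 1200L,
                       oligos_per_gene = 1L,
                       n_arrays_ip = 2L,
                       n_arrays_mock = 2L,
                       utr_length_mean = 800,
                       utr_length_sd = 600,
                       site_class_fractions = c("8mer" = 1 / 6,
                                                "7mer-m8" = 1 / 6,
                                                "7mer-1A" = 1 / 6,
                                                "6mer-n2-7" = 1 / 6,
                                                "6mer-n3-8" = 1 / 6),
                       effect_log2 = c("8mer" = 1.5, "7mer-m8" = 1.0,
                                       "7mer-1A" = 0.7, "6mer-n2-7" = 0.4,
                                       "6mer-n3-8" = 0.2, "none" = 0),
                       noise_sd = 0.3,
                       baseline_log_intensity_mean = 10,
                       baseline_log_intensity_sd = 1,
                       background_intensity = 100,
                       frac_bad_correlation = 0.05,
                       frac_low_signal = 0.05,
                       rng_seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              oligos_per_gene = as.integer(oligos_per_gene),
              n_arrays_ip = as.integer(n_arrays_ip),
              n_arrays_mock = as.integer(n_arrays_mock),
              utr_length_mean = utr_length_mean,
              utr_length_sd = utr_length_sd,
              site_class_fractions = site_class_fractions,
              effect_log2 = effect_log2,
              noise_sd = noise_sd,
              baseline_log_intensity_mean = baseline_log_intensity_mean,
              baseline_log_intensity_sd = baseline_log_intensity_sd,
              background_intensity = background_intensity,
              frac_bad_correlation = frac_bad_correlation,
              frac_low_signal = frac_low_signal,
              rng_seed = as.integer(rng_seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1, cfg$oligos_per_gene >= 1,
            cfg$n_arrays_ip >= 1, cfg$n_arrays_mock >= 1,
            cfg$noise_sd >= 0, cfg$utr_length_mean > 0,
            cfg$background_intensity > 0)
  fr <- cfg$site_class_fractions
  if (is.null(names(fr)) ||
      !all(names(fr) %in% setdiff(seed_site_types(), "none"))) {
    stop("invalid-argument: site_class_fractions must be named by site class")
  }
  if (any(fr < 0 | fr > 1) || sum(fr) > 1 + 1e-12) {
    stop("invalid-argument: site_class_fractions must be proportions summing to <= 1")
  }
  if (cfg$frac_bad_correlation < 0 || cfg$frac_bad_correlation > 1 ||
      cfg$frac_low_signal < 0 || cfg$frac_low_signal > 1 ||
      cfg$frac_bad_correlation + cfg$frac_low_signal > 1) {
    stop("invalid-argument: QC-failure fractions must be proportions summing to <= 1")
  }
  if (!"none" %in% names(cfg$effect_log2) || cfg$effect_log2[["none"]] != 0) {
    stop("invalid-argument: effect_log2 must map \"none\" to 0")
  }
  if (!all(names(fr) %in% names(cfg$effect_log2))) {
    stop("invalid-argument: effect_log2 missing a class in site_class_fractions")
  }
  invisible(cfg)
}

#' Generate a random mature miRNA sequence
#'
#' @param rng_seed Integer seed; the same seed reproduces the sequence.
#' @param length Mature length in nucleotides, 18-25.
#' @return RNA string (5' to 3').
#' @examples
#' make_mirna(1)
#' @export
make_mirna <- function(rng_seed, length = 22L) {
  if (length < 18 || length > 25) {
    stop("invalid-argument: mature miRNA length must be in [18, 25]")
  }
  with_rng_seed(rng_seed, random_rna(as.integer(length)))
}

# Exact-quota class assignment: round(frac * n) genes per class in
# precedence order, assigned to a seeded random shuffle of genes.
assign_site_classes <- function(n_genes, fractions) {
  classes <- intersect(setdiff(seed_site_types(), "none"), names(fractions))
  counts <- vapply(classes, function(cl) as.integer(round(fractions[[cl]] * n_genes)),
                   integer(1))
  if (sum(counts) > n_genes) {
    stop("invalid-argument: class quotas exceed n_genes")
  }
  assignment <- rep("none", n_genes)
  shuffled <- sample.int(n_genes)
  at <- 1L
  for (i in seq_along(classes)) {
    if (counts[i] > 0) {
      assignment[shuffled[at:(at + counts[i] - 1L)]] <- classes[i]
      at <- at + counts[i]
    }
  }
  assignment
}

# Draw one clamped log-normal UTR length.
draw_utr_length <- function(mean_nt, sd_nt) {
  sdlog <- sqrt(log(1 + (sd_nt / mean_nt)^2))
  meanlog <- log(mean_nt) - sdlog^2 / 2
  len <- round(rlnorm(1, meanlog, sdlog))
  as.integer(min(max(len, 50), 10 * mean_nt))
}

# Precedence rank (1 = strongest). "none" ranks last.
site_rank <- function(type) match(type, seed_site_types())

#' Plant seed-match sites into synthetic 3' UTRs
#'
#' Assigns each gene a site class by exact quota from
#' `config$site_class_fractions`, then builds a random UTR carrying exactly
#' one planted site of that class at a uniform-random internal position.
#' Background sequence is resampled (up to 1000 attempts per gene) until it
#' contains no site of equal or higher precedence than the planted class,
#' so [classify_utr()] on every planted UTR returns exactly the planted
#' class.
#'
#' @param mirna Mature miRNA sequence (at least 8 nt).
#' @param config A [sim_config()].
#' @return List with `utrs` (named RNA character vector) and `truth`, a data
#'   frame of `gene_id`, `site_class`, `true_log2_enrichment`, `site_start`,
#'   `site_end` (1-based inclusive; NA for class `"none"`).
#' @export
plant_sites <- function(mirna, config) {
  validate_sim_config(config)
  mirna <- as_rna(mirna)
  if (nchar(mirna) < 8) stop("invalid-argument: miRNA must be at least 8 nt")
  pats <- site_patterns(mirna)
  with_rng_seed(config$rng_seed, {
    n <- config$n_genes
    gene_ids <- sprintf("G%05d", seq_len(n))
    classes <- assign_site_classes(n, config$site_class_fractions)
    utrs <- character(n)
    starts <- rep(NA_integer_, n)
    ends <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      cl <- classes[i]
      planted <- plant_one_utr(cl, pats, config, gene_ids[i], mirna)
      utrs[i] <- planted$utr
      starts[i] <- planted$start
      ends[i] <- planted$end
    }
    truth <- data.frame(gene_id = gene_ids,
                        site_class = classes,
                        true_log2_enrichment =
                          unname(config$effect_log2[classes]),
                        site_start = starts, site_end = ends,
                        stringsAsFactors = FALSE)
    list(utrs = setNames(utrs, gene_ids), truth = truth)
  })
}

# Build one UTR for a gene of class `cl`; rejection-sample background until
# classification returns exactly the planted class (no unintended site of
# equal or higher precedence).
plant_one_utr <- function(cl, pats, config, gene_id, mirna) {
  max_tries <- 1000L
  rank <- match(cl, names(pats))
  for (try in seq_len(max_tries)) {
    len <- draw_utr_length(config$utr_length_mean, config$utr_length_sd)
    if (cl == "none") {
      utr <- random_rna(len)
      hit <- FALSE
      for (p in pats) if (grepl(p, utr, fixed = TRUE)) { hit <- TRUE; break }
      if (hit) next
      return(list(utr = utr, start = NA_integer_, end = NA_integer_))
    }
    pat <- pats[[cl]]
    w <- nchar(pat)
    len <- max(len, w + 2L)
    utr <- random_rna(len)
    # background must be free of equal-or-higher-precedence sites
    hit <- FALSE
    for (p in pats[seq_len(rank)]) {
      if (grepl(p, utr, fixed = TRUE)) { hit <- TRUE; break }
    }
    if (hit) next
    # internal position with at least one background nt on each side
    start <- sample.int(len - w - 1L, 1L) + 1L
    substr(utr, start, start + w - 1L) <- pat
    scan <- scan_seed_sites(utr, pats)
    ok <- scan$best == cl && scan$counts[[cl]] == 1L &&
      any(scan$start == start & scan$type == cl)
    if (ok) {
      return(list(utr = utr, start = start, end = start + w - 1L))
    }
  }
  stop("generation-failure: could not plant a clean ", cl,
       " site for gene ", gene_id, " within ", max_tries, " attempts")
}

#' Simulate two-channel array-element tables from a ground truth
#'
#' For every element (gene x oligo) on every hybridization, the reference
#' channel (channel 2) log2 signal is Normal(baseline); the sample channel
#' (channel 1) log2 signal adds the gene's true recruitment effect (on IP
#' arrays only) plus Normal(0, noise_sd). Foregrounds are background plus
#' signal over a constant background. Exact quotas of elements are stamped
#' as QC failures, identically on every array: `frac_bad_correlation` get a
#' pixel correlation below 0.6, `frac_low_signal` get signal/background
#' below 2.5 in both channels; all remaining elements are guaranteed a
#' correlation of at least 0.6 and a ratio of at least 2.5 in the reference
#' channel.
#'
#' @param truth Data frame with columns `gene_id`, `site_class`,
#'   `true_log2_enrichment` (as returned in `plant_sites()$truth`).
#' @param config A [sim_config()].
#' @return List: `tables`, a named list of per-hybridization element data
#'   frames (`element_id`, `gene_id`, `oligo_index`, `ch1_fg`, `ch1_bg`,
#'   `ch2_fg`, `ch2_bg`, `pixel_corr`); `conditions`, a named character
#'   vector (`"ip"`/`"mock"`) over table labels; `element_truth`, per-element
#'   QC stamps (`element_id`, `qc_fail`, `failure_mode`).
#' @export
simulate_arrays <- function(truth, config) {
  validate_sim_config(config)
  stopifnot(all(c("gene_id", "true_log2_enrichment") %in% names(truth)),
            !anyDuplicated(truth$gene_id))
  with_rng_seed(config$rng_seed + 1L, {
    n_el <- nrow(truth) * config$oligos_per_gene
    el <- data.frame(
      element_id = sprintf("E%06d", seq_len(n_el)),
      gene_id = rep(truth$gene_id, each = config$oligos_per_gene),
      oligo_index = rep(seq_len(config$oligos_per_gene), nrow(truth)),
      effect = rep(truth$true_log2_enrichment, each = config$oligos_per_gene),
      stringsAsFactors = FALSE)

    n_bad <- as.integer(round(config$frac_bad_correlation * n_el))
    n_low <- as.integer(round(config$frac_low_signal * n_el))
    stamp_order <- sample.int(n_el)
    mode <- rep("ok", n_el)
    if (n_bad > 0) mode[stamp_order[seq_len(n_bad)]] <- "bad_correlation"
    if (n_low > 0) mode[stamp_order[n_bad + seq_len(n_low)]] <- "low_signal"

    labels <- c(sprintf("ip_%d", seq_len(config$n_arrays_ip)),
                sprintf("mock_%d", seq_len(config$n_arrays_mock)))
    conditions <- setNames(rep(c("ip", "mock"),
                               c(config$n_arrays_ip, config$n_arrays_mock)),
                           labels)
    bg <- config$background_intensity
    min_log2_sig <- log2(1.5 * bg)  # keeps reference fg/bg >= 2.5

    tables <- lapply(labels, function(lab) {
      is_ip <- conditions[[lab]] == "ip"
      x2 <- rnorm(n_el, config$baseline_log_intensity_mean,
                  config$baseline_log_intensity_sd)
      x2 <- pmax(x2, min_log2_sig)
      ratio_log2 <- (if (is_ip) el$effect else 0) +
        rnorm(n_el, 0, config$noise_sd)
      s2 <- 2^x2
      s1 <- s2 * 2^ratio_log2
      corr <- runif(n_el, 0.6, 1.0)
      ch1_fg <- bg + s1
      ch2_fg <- bg + s2
      bad <- mode == "bad_correlation"
      low <- mode == "low_signal"
      if (any(bad)) corr[bad] <- runif(sum(bad), 0.1, 0.59)
      if (any(low)) {
        ch1_fg[low] <- bg * runif(sum(low), 1.1, 2.4)
        ch2_fg[low] <- bg * runif(sum(low), 1.1, 2.4)
      }
      data.frame(element_id = el$element_id, gene_id = el$gene_id,
                 oligo_index = el$oligo_index,
                 ch1_fg = ch1_fg, ch1_bg = bg,
                 ch2_fg = ch2_fg, ch2_bg = bg,
                 pixel_corr = corr, stringsAsFactors = FALSE)
    })
    names(tables) <- labels
    list(tables = tables, conditions = conditions,
         element_truth = data.frame(element_id = el$element_id,
                                    gene_id = el$gene_id,
                                    oligo_index = el$oligo_index,
                                    qc_fail = mode != "ok",
                                    failure_mode = mode,
                                    stringsAsFactors = FALSE))
  })
}

#' Write simulated element tables, truth and config to a directory
#'
#' Element tables are written as tab-delimited text with a header, one file
#' per hybridization (`elements_<label>.tsv`); gene truth and element truth
#' as TSV; the configuration as YAML.
#'
#' @param sim Result of [simulate_arrays()].
#' @param dir Output directory (created if needed).
#' @param truth Optional gene-level truth data frame to write alongside.
#' @param config Optional [sim_config()] to write as `sim_config.yml`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, truth = NULL, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (lab in names(sim$tables)) {
    p <- file.path(dir, paste0("elements_", lab, ".tsv"))
    write.table(sim$tables[[lab]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths[lab] <- p
  }
  p <- file.path(dir, "element_truth.tsv")
  write.table(sim$element_truth, p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths["element_truth"] <- p
  if (!is.null(truth)) {
    p <- file.path(dir, "gene_truth.tsv")
    write.table(truth, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["gene_truth"] <- p
  }
  if (!is.null(config)) {
    p <- file.path(dir, "sim_config.yml")
    yaml::write_yaml(unclass(config), p)
    paths["config"] <- p
  }
  invisible(paths)
}
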