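# Pipeline orchestration: one reproducible run chaining QC -> target
# calling -> seed-site scanning -> stratified CDF / clustering, with a run
# manifest; plus the small formula utilities used alongside the array
# analysis (xenograft tumor volume, TOP/FOP reporter ratio).

#' Pipeline configuration
#'
#' @param element_tables Named character vector of element-table TSV paths;
#'   names are the hybridization labels.
#' @param conditions Named character vector over the same labels with
#'   values `"ip"`, `"mock"` or `"expression"`; at least one `ip` and one
#'   `mock` (or one `expression` and one `mock`) label required.
#' @param utr_fasta Path to the 3' UTR FASTA (record IDs = gene IDs).
#' @param mirna Mature miRNA sequence, or a FASTA path holding it.
#' @param qc A [qc_thresholds()].
#' @param sam A [sam_parameters()].
#' @param min_class_size Minimum class size for the hierarchy verdict.
#' @param cluster_method Linkage for [hierarchical_cluster()].
#' @param out_dir Output directory.
#' @param rng_seed Global seed for the run.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(element_tables, conditions, utr_fasta, mirna,
                            qc = qc_thresholds(), sam = sam_parameters(),
                            min_class_size = 5L,
                            cluster_method = "average",
                            out_dir = "ripchip_out", rng_seed = 1L) {
  cfg <- list(element_tables = element_tables, conditions = conditions,
              utr_fasta = utr_fasta, mirna = mirna, qc = qc, sam = sam,
              min_class_size = as.integer(min_class_size),
              cluster_method = cluster_method, out_dir = out_dir,
              rng_seed = as.integer(rng_seed))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (is.null(names(cfg$element_tables)) ||
      !all(names(cfg$element_tables) %in% names(cfg$conditions))) {
    stop("config-validation: conditions must cover all element tables")
  }
  conds <- cfg$conditions[names(cfg$element_tables)]
  if (!("mock" %in% conds) || !any(c("ip", "expression") %in% conds)) {
    stop("config-validation: need >= 1 mock and >= 1 ip (or expression) label")
  }
  missing <- cfg$element_tables[!file.exists(cfg$element_tables)]
  if (length(missing)) {
    stop("config-validation: element table(s) not found: ",
         paste(missing, collapse = ", "))
  }
  if (!file.exists(cfg$utr_fasta)) {
    stop("config-validation: UTR FASTA not found: ", cfg$utr_fasta)
  }
  if (file.exists(cfg$mirna)) {
    cfg$mirna_seq <- unname(read_fasta_sequences(cfg$mirna)[1])
  } else {
    cfg$mirna_seq <- as_rna(cfg$mirna)
  }
  invisible(cfg)
}

#' Run the full RIP-chip analysis pipeline
#'
#' Stages, in order: element QC and ratio-matrix assembly; SAM-style
#' enrichment calling with permutation local FDR and the target call;
#' seed-site classification of the UTRs; stratified CDF analysis with the
#' hierarchy check; hierarchical clustering of the called targets across
#' arrays. All stage outputs are written under `config$out_dir`, and a run
#' manifest (config echo, package version, seed, per-file MD5 checksums,
#' timestamps) is written on both success and failure. A rerun with the
#' same config and seed reproduces every stage output byte for byte (the
#' manifest differs only in its timestamps).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results (`matrix`,
#'   `qc_report`, `calls`, `targets`, `annotations`, `stratified`,
#'   `hierarchy`, `manifest`).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_pipeline_config(config)
  mirna <- cfg$mirna_seq
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = manifest_config(config),
                   package_version = as.character(utils::packageVersion("ripchip")),
                   rng_seed = config$rng_seed,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   status = "failed", failed_stage = NA, outputs = list())
  manifest_path <- file.path(config$out_dir, "manifest.yml")
  on.exit(yaml::write_yaml(manifest, manifest_path))

  out <- function(name) file.path(config$out_dir, name)
  stage <- "arrayqc"
  result <- tryCatch({
    tables <- lapply(config$element_tables, read_element_table)
    flt <- filter_elements(tables, config$qc)
    mat <- assemble_matrix(tables, flt$retained,
                           config$conditions, config$qc)
    write.table(flt$report, out("qc_report.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_ratio_matrix(mat, out("ratio_matrix.tsv"))

    stage <- "targetcall"
    calls <- permutation_local_fdr(mat, params = config$sam,
                                   rng_seed = config$rng_seed)
    targets <- call_targets(calls, config$sam)
    write_calls(calls, out("enrichment_calls.tsv"), config$sam)
    write.table(targets, out("targets.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)

    stage <- "seqscan"
    utrs <- read_fasta_sequences(config$utr_fasta, alphabet = "rna")
    ann <- classify_utrs(utrs, mirna)
    write_site_annotations(ann, out("site_annotations.tsv"))

    stage <- "downstream"
    delta <- calls$delta
    names(delta) <- calls$gene_id
    # per-gene value = best oligo (largest delta); oligos are called
    # separately upstream
    delta <- tapply(delta, names(delta), max, na.rm = TRUE)
    delta <- delta[is.finite(delta)]
    delta <- delta[names(delta) %in% ann$gene_id]
    cdf <- stratify(delta, ann, config$min_class_size)
    hier <- tryCatch(check_hierarchy(cdf), error = function(e) NULL)
    write_stratified(cdf, out("stratified_summary.tsv"),
                     out("ecdf_table.tsv"))
    hc_rows <- NULL
    if (nrow(targets) >= 2) {
      tmat <- unclass(mat)[targets$row_key, , drop = FALSE]
      hc_rows <- tryCatch(
        hierarchical_cluster(tmat, config$cluster_method),
        error = function(e) NULL)
      if (!is.null(hc_rows)) {
        write_dendrogram(hc_rows, out("targets_dendrogram.nwk"))
        ordered <- tmat[hc_rows$labels[hc_rows$order], , drop = FALSE]
        write.table(data.frame(row_key = rownames(ordered),
                               as.data.frame(ordered), check.names = FALSE),
                    out("clustered_targets.tsv"), sep = "\t", quote = FALSE,
                    row.names = FALSE)
      }
    }
    list(matrix = mat, qc_report = flt$report, calls = calls,
         targets = targets, annotations = ann, stratified = cdf,
         hierarchy = hier, dendrogram = hc_rows)
  }, error = function(e) {
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    stop(e)
  })

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.yml"]
  sums <- md5sum(files)
  manifest$outputs <- as.list(setNames(unname(sums), basename(files)))
  manifest$status <- "ok"
  manifest$failed_stage <- NULL
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  result$manifest <- manifest
  invisible(result)
}

manifest_config <- function(config) {
  list(element_tables = as.list(config$element_tables),
       conditions = as.list(config$conditions),
       utr_fasta = config$utr_fasta,
       mirna = config$mirna,
       qc = unclass(config$qc),
       sam = lapply(unclass(config$sam), function(x) {
         if (is.null(x)) "auto" else x
       }),
       min_class_size = config$min_class_size,
       cluster_method = config$cluster_method,
       out_dir = config$out_dir)
}

#' Xenograft tumor volume from caliper measurements
#'
#' `volume = a * b^2 / 2` with `a` the tumor length and `b` the width, both
#' in mm; the result is in cubic millimeters. Warns (without failing) if
#' the width exceeds the length.
#'
#' @param a Length in mm.
#' @param b Width in mm.
#' @return Volume in cubic millimeters.
#' @examples
#' tumor_volume(10, 6)
#' @export
tumor_volume <- function(a, b) {
  if (any(a < 0) || any(b < 0)) stop("invalid-argument: negative dimension")
  if (any(a < b)) warning("length a < width b; check measurement order")
  a * b^2 / 2
}

#' Normalized TOPFlash/FOPFlash reporter ratio
#'
#' WNT/beta-catenin pathway activity from dual-luciferase readings:
#' each firefly reading is first normalized to its Renilla co-transfection
#' control, then the normalized TOPFlash value is divided by the normalized
#' FOPFlash value.
#'
#' @param top_firefly,top_renilla Firefly and Renilla luminescence of the
#'   TOPFlash (intact TCF sites) transfection.
#' @param fop_firefly,fop_renilla Same for the FOPFlash (mutated sites)
#'   transfection.
#' @return Dimensionless pathway activity.
#' @examples
#' top_fop_ratio(4, 2, 2, 2)
#' @export
top_fop_ratio <- function(top_firefly, top_renilla, fop_firefly,
                          fop_renilla) {
  if (any(top_renilla <= 0) || any(fop_renilla <= 0) || any(fop_firefly <= 0)) {
    stop("invalid-argument: zero or negative denominator")
  }
  (top_firefly / top_renilla) / (fop_firefly / fop_renilla)
}

#' Rescale a batch of reporter activities to a control mean of 100%
#'
#' @param values Numeric activities (e.g. from [top_fop_ratio()]).
#' @param control Logical or index vector selecting the control condition.
#' @return `values` rescaled so `mean(values[control])` reads 100.
#' @examples
#' scale_to_control(c(1, 1, 3.64), control = 1:2)
#' @export
scale_to_control <- function(values, control) {
  ctrl_mean <- mean(values[control])
  if (!is.finite(ctrl_mean) || ctrl_mean == 0) {
    stop("invalid-argument: control mean must be finite and nonzero")
  }
  100 * values / ctrl_mean
}
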