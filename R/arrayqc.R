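# Element-level QC, log2 ratios, global median normalization, and assembly
# of the gene/oligo x array ratio matrix.
#
# An element (one oligo spot) passes QC on one array iff its pixel
# regression correlation between the two channels is >= 0.6 AND its
# foreground/background intensity ratio is >= 2.5 in at least one channel;
# an element is retained overall iff it passes on >= 60% of the arrays.
# Ratios are log2(channel-1 / channel-2) on background-subtracted
# intensities and each array is globally normalized to median log2 ratio 0.

#' Element-level QC thresholds
#'
#' @param min_pixel_corr Minimum pixel regression correlation between the
#'   two channel signals over the element's pixels (default 0.6).
#' @param min_signal_to_background Minimum foreground/background intensity
#'   ratio required in at least one channel (default 2.5).
#' @param min_array_fraction Minimum fraction of arrays on which an element
#'   must pass to be retained (default 0.60).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_pixel_corr = 0.6,
                          min_signal_to_background = 2.5,
                          min_array_fraction = 0.60) {
  stopifnot(min_pixel_corr > 0, min_signal_to_background > 0,
            min_array_fraction > 0, min_array_fraction <= 1)
  structure(list(min_pixel_corr = min_pixel_corr,
                 min_signal_to_background = min_signal_to_background,
                 min_array_fraction = min_array_fraction),
            class = "qc_thresholds")
}

# fg/bg ratio with the 0-background convention: +Inf if fg > 0, 0 otherwise.
signal_ratio <- function(fg, bg) {
  ifelse(bg == 0, ifelse(fg > 0, Inf, 0), fg / bg)
}

#' Does an array element pass the per-array QC filter?
#'
#' Vectorized over the rows of an element table. All comparisons are
#' inclusive (`>=`).
#'
#' @param rec Data frame with columns `ch1_fg`, `ch1_bg`, `ch2_fg`,
#'   `ch2_bg`, `pixel_corr` (one row per element).
#' @param thr A [qc_thresholds()].
#' @return Logical vector, one value per row.
#' @export
element_passes <- function(rec, thr = qc_thresholds()) {
  needed <- c("ch1_fg", "ch1_bg", "ch2_fg", "ch2_bg", "pixel_corr")
  stopifnot(all(needed %in% names(rec)))
  ints <- as.matrix(rec[, c("ch1_fg", "ch1_bg", "ch2_fg", "ch2_bg")])
  if (any(ints < 0)) stop("invalid-record: negative intensities")
  if (any(rec$pixel_corr < -1 | rec$pixel_corr > 1)) {
    stop("invalid-record: pixel_corr outside [-1, 1]")
  }
  r1 <- signal_ratio(rec$ch1_fg, rec$ch1_bg)
  r2 <- signal_ratio(rec$ch2_fg, rec$ch2_bg)
  rec$pixel_corr >= thr$min_pixel_corr &
    (r1 >= thr$min_signal_to_background |
     r2 >= thr$min_signal_to_background)
}

#' Filter elements across a set of hybridizations
#'
#' An element is retained iff it passes [element_passes()] on at least
#' `min_array_fraction` of the arrays (inclusive comparison). All tables
#' must share the same element universe.
#'
#' @param tables Named list of element data frames, one per hybridization.
#' @param thr A [qc_thresholds()].
#' @return List: `retained`, character vector of retained `element_id`s (in
#'   table order); `report`, data frame of `element_id`, `gene_id`,
#'   `oligo_index`, `n_pass`, `n_arrays`, `pass_fraction`, `retained`.
#' @export
filter_elements <- function(tables, thr = qc_thresholds()) {
  if (!length(tables)) stop("invalid-input: empty table set")
  ref <- tables[[1]]
  ids <- ref$element_id
  for (tab in tables) {
    if (!identical(sort(tab$element_id), sort(ids))) {
      stop("invalid-input: tables do not share the same element universe")
    }
    if (anyDuplicated(tab$element_id)) {
      stop("invalid-input: duplicate element_id within a table")
    }
  }
  pass <- vapply(tables, function(tab) {
    tab <- tab[match(ids, tab$element_id), , drop = FALSE]
    element_passes(tab, thr)
  }, logical(length(ids)))
  pass <- matrix(pass, nrow = length(ids))
  n_pass <- rowSums(pass)
  frac <- n_pass / ncol(pass)
  retained <- frac >= thr$min_array_fraction
  report <- data.frame(element_id = ids,
                       gene_id = ref$gene_id,
                       oligo_index = ref$oligo_index,
                       n_pass = as.integer(n_pass),
                       n_arrays = ncol(pass),
                       pass_fraction = frac,
                       retained = retained,
                       stringsAsFactors = FALSE)
  list(retained = ids[retained], report = report)
}

#' Background-subtracted log2 channel ratio
#'
#' `log2(max(ch1_fg - ch1_bg, floor) / max(ch2_fg - ch2_bg, floor))`;
#' the floor guards against non-positive background-subtracted signal.
#'
#' @param rec Element data frame (vectorized over rows).
#' @param floor Positive intensity floor (default 1).
#' @return Numeric vector of log2 ratios.
#' @export
log_ratio <- function(rec, floor = 1) {
  stopifnot(floor > 0)
  log2(pmax(rec$ch1_fg - rec$ch1_bg, floor) /
       pmax(rec$ch2_fg - rec$ch2_bg, floor))
}

#' Globally normalize one array's log2 ratios to median 0
#'
#' Subtracts the median of the non-missing values, so that the median log2
#' ratio of the array is 0 after normalization (for an even count, the mean
#' of the two central order statistics).
#'
#' @param x Numeric vector of log2 ratios, possibly with `NA`.
#' @return `x` minus its median (NAs preserved).
#' @export
normalize_array <- function(x) {
  if (all(is.na(x))) stop("invalid-input: all-missing array column")
  x - median(x, na.rm = TRUE)
}

#' Assemble the normalized gene/oligo x array ratio matrix
#'
#' Builds the matrix of normalized log2 ratios over retained elements.
#' Elements dropped by [filter_elements()] are absent; a retained element
#' that fails QC on an individual array gets a missing value in that
#' column. Oligos mapping to the same gene are kept as separate rows, keyed
#' `gene_id:oligo_index`.
#'
#' @param tables Named list of element data frames.
#' @param retained Character vector of retained element IDs (from
#'   [filter_elements()]).
#' @param conditions Named character vector mapping each table label to a
#'   condition (`"ip"`, `"mock"` or `"expression"`).
#' @param thr A [qc_thresholds()] (used for the per-array missing rule).
#' @param floor Intensity floor for [log_ratio()].
#' @param normalize Median-center each column (default TRUE).
#' @return A `gene_ratio_matrix`: numeric matrix with rownames
#'   `gene_id:oligo_index`, colnames the table labels, and attributes
#'   `conditions` (named condition vector) and `element_ids`.
#' @export
assemble_matrix <- function(tables, retained, conditions,
                            thr = qc_thresholds(), floor = 1,
                            normalize = TRUE) {
  if (!length(tables)) stop("invalid-input: empty table set")
  if (!all(names(tables) %in% names(conditions))) {
    stop("invalid-input: condition labels must cover all tables")
  }
  ref <- tables[[1]]
  keep <- ref[match(retained, ref$element_id), c("element_id", "gene_id",
                                                 "oligo_index")]
  if (any(is.na(keep$element_id))) {
    stop("invalid-input: retained IDs missing from tables")
  }
  rowkeys <- paste(keep$gene_id, keep$oligo_index, sep = ":")
  mat <- matrix(NA_real_, nrow = nrow(keep), ncol = length(tables),
                dimnames = list(rowkeys, names(tables)))
  for (lab in names(tables)) {
    tab <- tables[[lab]]
    if (anyDuplicated(tab$element_id)) {
      stop("invalid-input: duplicate (element, array) entries in ", lab)
    }
    tab <- tab[match(keep$element_id, tab$element_id), , drop = FALSE]
    vals <- log_ratio(tab, floor)
    vals[!element_passes(tab, thr)] <- NA_real_
    mat[, lab] <- vals
  }
  if (normalize) {
    for (j in seq_len(ncol(mat))) mat[, j] <- normalize_array(mat[, j])
  }
  structure(mat, conditions = conditions[colnames(mat)],
            element_ids = keep$element_id, class = c("gene_ratio_matrix",
                                                     class(mat)))
}

#' Read one element table from tab-delimited text
#'
#' Expects the synthgen dialect (columns `element_id`, `gene_id`,
#' `oligo_index`, `ch1_fg`, `ch1_bg`, `ch2_fg`, `ch2_bg`, `pixel_corr`);
#' `column_map` renames columns of GPR-like exports onto that dialect.
#'
#' @param path TSV path with header.
#' @param column_map Optional named character vector, `names` = canonical
#'   column, value = column name in the file.
#' @return Element data frame.
#' @export
read_element_table <- function(path, column_map = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      names(tab)[names(tab) == column_map[[canon]]] <- canon
    }
  }
  needed <- c("element_id", "gene_id", "oligo_index", "ch1_fg", "ch1_bg",
              "ch2_fg", "ch2_bg", "pixel_corr")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("invalid-input: element table lacks columns: ",
         paste(missing, collapse = ", "))
  }
  tab[, needed]
}

#' Write a gene ratio matrix as TSV
#'
#' Rows are `gene_id:oligo_index` keys, columns the hybridization labels; a
#' `condition` header row is not included (conditions travel in the
#' pipeline config / manifest).
#'
#' @param mat A `gene_ratio_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ratio_matrix <- function(mat, path) {
  df <- data.frame(row_key = rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
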