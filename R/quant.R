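# quantification tables (salmon quant.sf dialect), sample designs, and the
# two expression-based transcript filters

QUANT_COLS <- c("Name", "Length", "EffectiveLength", "TPM", "NumReads")

#' Construct a quantification table
#'
#' A `quant_table` holds a non-negative TPM matrix (transcripts x samples)
#' and, optionally, a matching `NumReads` matrix.
#'
#' @param tpm numeric matrix with transcript ids as rownames and sample ids
#'   as colnames.
#' @param num_reads optional matrix of the same shape.
#' @return an object of class `quant_table`.
#' @export
quant_table <- function(tpm, num_reads = NULL) {
  tpm <- as.matrix(tpm)
  if (is.null(rownames(tpm)) || is.null(colnames(tpm)))
    stop_input("`tpm` needs transcript rownames and sample colnames")
  validate_ids(rownames(tpm))
  validate_ids(colnames(tpm))
  if (anyNA(tpm) || any(tpm < 0)) stop_input("TPM values must be non-negative")
  if (is.null(num_reads)) {
    num_reads <- tpm * 0
  } else {
    num_reads <- as.matrix(num_reads)
    if (!identical(dim(num_reads), dim(tpm)))
      stop_input("`num_reads` shape differs from `tpm`")
    if (anyNA(num_reads) || any(num_reads < 0))
      stop_input("NumReads values must be non-negative")
  }
  structure(list(tpm = tpm, num_reads = num_reads,
                 transcript_ids = rownames(tpm), sample_ids = colnames(tpm)),
            class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table: %d transcripts x %d samples\n",
              length(x$transcript_ids), length(x$sample_ids)))
  invisible(x)
}

read_one_quant <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(QUANT_COLS, colnames(df))
  if (length(missing_cols))
    stop_input(path, ": missing column(s): ", paste(missing_cols, collapse = ", "))
  num <- suppressWarnings(as.numeric(df$TPM))
  bad <- which(is.na(num) & !is.na(df$TPM))
  if (length(bad))
    stop_input(path, ": non-numeric TPM at line ", bad[1] + 1L)
  reads <- suppressWarnings(as.numeric(df$NumReads))
  badr <- which(is.na(reads) & !is.na(df$NumReads))
  if (length(badr))
    stop_input(path, ": non-numeric NumReads at line ", badr[1] + 1L)
  validate_ids(df$Name)
  data.frame(Name = df$Name, TPM = num, NumReads = reads,
             stringsAsFactors = FALSE)
}

#' Read per-sample quantification files
#'
#' Each file must carry the `quant.sf` header
#' `Name, Length, EffectiveLength, TPM, NumReads`. Transcript rows are the
#' union of the `Name` columns, in order of first appearance; a transcript
#' absent from some file gets TPM 0 there, with a warning.
#'
#' @param paths one TSV per sample.
#' @param sample_ids unique sample names (default: file directory or stem).
#' @return a [quant_table()].
#' @export
read_quant <- function(paths, sample_ids = NULL) {
  if (length(paths) == 0) stop_input("no quantification files given")
  if (is.null(sample_ids)) {
    sample_ids <- basename(dirname(paths))
    if (anyDuplicated(sample_ids))
      sample_ids <- tools::file_path_sans_ext(basename(paths))
  }
  if (length(sample_ids) != length(paths))
    stop_input("`sample_ids` must match `paths` in length")
  validate_ids(sample_ids)
  tabs <- lapply(paths, read_one_quant)
  ids <- unique(unlist(lapply(tabs, `[[`, "Name")))
  tpm <- matrix(0, length(ids), length(paths), dimnames = list(ids, sample_ids))
  reads <- tpm
  for (k in seq_along(tabs)) {
    t_k <- tabs[[k]]
    absent <- setdiff(ids, t_k$Name)
    if (length(absent))
      warning(sprintf("%s: %d transcript(s) absent, set to TPM 0",
                      sample_ids[k], length(absent)), call. = FALSE)
    tpm[t_k$Name, k] <- t_k$TPM
    reads[t_k$Name, k] <- t_k$NumReads
  }
  quant_table(tpm, reads)
}

#' Construct a sample design
#'
#' Maps each sample to one level of each experimental factor (e.g. season,
#' geographical area, sex).
#'
#' @param df data.frame whose first column (named `sample`) holds unique
#'   sample ids; every other column is a factor with non-empty level labels.
#' @return an object of class `sample_design` with fields `sample_ids` and
#'   `factors` (factor name -> named vector sample -> level).
#' @export
sample_design <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"sample" %in% colnames(df)) stop_input("design needs a `sample` column")
  if (ncol(df) < 2) stop_input("design declares no factors")
  validate_ids(as.character(df$sample))
  factors <- lapply(df[setdiff(colnames(df), "sample")], function(col) {
    col <- as.character(col)
    if (any(!nzchar(col)) || anyNA(col)) stop_input("empty factor level label")
    setNames(col, df$sample)
  })
  structure(list(sample_ids = as.character(df$sample), factors = factors),
            class = "sample_design")
}

#' Read a sample design CSV
#'
#' Header: `sample,<factor1>,<factor2>,...`.
#'
#' @param path CSV file.
#' @return a [sample_design()].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  sample_design(utils::read.csv(path, stringsAsFactors = FALSE,
                                colClasses = "character"))
}

#' Expression filter thresholds
#'
#' `condition_tpm_min` (default 1 TPM) is the per-condition floor applied to
#' raw assemblies; `mean_tpm_min` (default 0.1 TPM) is the overall-mean floor
#' applied after consolidation.
#'
#' @param condition_tpm_min non-negative TPM threshold, boundary inclusive.
#' @param mean_tpm_min non-negative TPM threshold; a mean *below* it is
#'   discarded, so the boundary itself is kept.
#' @return an object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(condition_tpm_min = 1.0, mean_tpm_min = 0.1) {
  stopifnot(condition_tpm_min >= 0, mean_tpm_min >= 0)
  structure(list(condition_tpm_min = condition_tpm_min,
                 mean_tpm_min = mean_tpm_min),
            class = "filter_thresholds")
}

check_quant_design <- function(quant, design, factor = NULL) {
  if (!is.null(factor) && !factor %in% names(design$factors))
    stop_input("unknown factor: ", factor)
  orphan <- setdiff(quant$sample_ids, design$sample_ids)
  if (length(orphan))
    stop_input("sample(s) missing from design: ", paste(orphan, collapse = ", "))
  invisible(TRUE)
}

#' Per-level mean TPM for one factor
#'
#' @param quant a [quant_table()].
#' @param design a [sample_design()] covering all samples of `quant`.
#' @param factor name of a declared factor.
#' @return matrix transcripts x levels of arithmetic mean TPM.
#' @export
condition_level_means <- function(quant, design, factor) {
  check_quant_design(quant, design, factor)
  lv <- design$factors[[factor]][quant$sample_ids]
  levels <- unique(unname(lv))
  out <- vapply(levels, function(l) {
    cols <- which(lv == l)
    rowMeans(quant$tpm[, cols, drop = FALSE])
  }, numeric(length(quant$transcript_ids)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(quant$transcript_ids, levels))
  else colnames(out) <- levels
  out
}

#' Per-condition expression filter
#'
#' Keeps a transcript iff at least one level of at least one declared factor
#' has mean TPM >= `condition_tpm_min` ("at least", boundary inclusive).
#' This retains condition-specific transcripts while discarding artifacts
#' expressed nowhere.
#'
#' @inheritParams condition_level_means
#' @param thresholds a [filter_thresholds()].
#' @return character vector of kept transcript ids, in table order.
#' @export
expression_filter <- function(quant, design,
                              thresholds = filter_thresholds()) {
  check_quant_design(quant, design)
  if (length(design$factors) == 0) stop_input("design declares no factors")
  keep <- rep(FALSE, length(quant$transcript_ids))
  for (f in names(design$factors)) {
    lm <- condition_level_means(quant, design, f)
    keep <- keep | apply(lm >= thresholds$condition_tpm_min, 1, any)
  }
  quant$transcript_ids[keep]
}

#' Mean-abundance filter
#'
#' Keeps a transcript iff its mean TPM across all samples is not *below*
#' `mean_tpm_min`; a mean exactly on the threshold is kept.
#'
#' @inheritParams expression_filter
#' @return character vector of kept transcript ids, in table order.
#' @export
mean_abundance_filter <- function(quant, thresholds = filter_thresholds()) {
  m <- rowMeans(quant$tpm)
  quant$transcript_ids[m >= thresholds$mean_tpm_min]
}

# subset a quant table to ids (in table order)
quant_subset <- function(quant, ids) {
  keep <- quant$transcript_ids %in% ids
  quant_table(quant$tpm[keep, , drop = FALSE],
              quant$num_reads[keep, , drop = FALSE])
}
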