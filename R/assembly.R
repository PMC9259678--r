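# seqio: assembly sets are Biostrings::DNAStringSet objects whose names are
# the transcript ids, with per-record metadata columns `description` and
# `source` (originating assembler label)

#' Build an assembly set from character sequences
#'
#' An assembly set is a [Biostrings::DNAStringSet] with unique transcript ids
#' as names and metadata columns `description` and `source`. Bases are
#' uppercased on ingest; only `A`, `C`, `G`, `T`, `N` are accepted.
#'
#' @param bases character vector of nucleotide sequences.
#' @param ids character vector of unique, non-empty ids.
#' @param descriptions optional free-text descriptions (recycled).
#' @param source label of the originating assembler run (recycled).
#' @return a `DNAStringSet` with mcols `description` and `source`.
#' @examples
#' a <- assembly_set(c("ACGT", "GGCC"), c("t1", "t2"), source = "trinity")
#' @export
assembly_set <- function(bases, ids, descriptions = "", source = "") {
  if (length(bases) != length(ids))
    stop_input("`bases` and `ids` must have the same length")
  bases <- toupper(bases)
  validate_bases(bases, ids)
  validate_ids(ids)
  x <- Biostrings::DNAStringSet(bases)
  names(x) <- ids
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(
    description = rep_len(as.character(descriptions), length(x)),
    source = rep_len(as.character(source), length(x)))
  x
}

validate_ids <- function(ids) {
  if (any(!nzchar(ids)) || anyNA(ids)) stop_input("empty transcript id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_input("duplicate transcript id(s): ", paste(unique(dup), collapse = ", "))
  invisible(ids)
}

validate_bases <- function(bases, ids) {
  if (any(!nzchar(bases)))
    stop_input("empty sequence body for id(s): ",
               paste(ids[!nzchar(bases)], collapse = ", "))
  bad <- grepl("[^ACGTN]", bases)
  if (any(bad))
    stop_input("sequence(s) contain characters outside {A,C,G,T,N}: ",
               paste(ids[bad], collapse = ", "))
  invisible(bases)
}

#' Read an assembly FASTA file
#'
#' The header token before the first whitespace becomes the id, the remainder
#' the description. Lowercase bases are uppercased; characters outside
#' `{A,C,G,T,N}` (either case) are rejected, as are duplicate ids and empty
#' entries.
#'
#' @param path FASTA file (wrapped or single-line).
#' @param source label recorded for every record (defaults to the file stem).
#' @return an assembly set (see [assembly_set()]).
#' @export
read_assembly_fasta <- function(path, source = NULL) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  assembly_set(as.character(x), ids, desc,
               source = source %||% tools::file_path_sans_ext(basename(path)))
}

#' Write an assembly set as FASTA
#'
#' Descriptions, when present, are appended to the header after the id.
#' Round-trips losslessly through [read_assembly_fasta()].
#'
#' @param assembly an assembly set.
#' @param path destination file.
#' @param line_width bases per sequence line (>= 1).
#' @return `path`, invisibly.
#' @export
write_assembly_fasta <- function(assembly, path, line_width = 60L) {
  stopifnot(line_width >= 1)
  x <- as(assembly, "DNAStringSet")
  desc <- assembly_descriptions(assembly)
  names(x) <- ifelse(nzchar(desc), paste(names(assembly), desc), names(assembly))
  Biostrings::writeXStringSet(x, filepath = path, width = as.integer(line_width))
  invisible(path)
}

assembly_descriptions <- function(assembly) {
  mc <- S4Vectors::mcols(assembly)
  if (!is.null(mc) && "description" %in% colnames(mc))
    as.character(mc$description) else rep("", length(assembly))
}

assembly_sources <- function(assembly) {
  mc <- S4Vectors::mcols(assembly)
  if (!is.null(mc) && "source" %in% colnames(mc))
    as.character(mc$source) else rep("", length(assembly))
}

# subset an assembly to `ids`, preserving ingest order of the assembly
assembly_subset <- function(assembly, ids) {
  keep <- names(assembly) %in% ids
  assembly[keep]
}

#' N50 of a set of sequence lengths
#'
#' The length `L` such that sequences of length >= `L` together contain at
#' least half of the total bases (descending cumulative sums, "at least
#' half", first crossing).
#'
#' @param lengths positive integer lengths.
#' @return the N50, in bases.
#' @examples
#' assembly_n50(c(4, 3, 3, 2, 2, 2)) # 3
#' @export
assembly_n50 <- function(lengths) {
  if (length(lengths) == 0) stop_input("empty length set")
  if (any(lengths <= 0) || anyNA(lengths)) stop_input("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(as.numeric(s))
  s[which(cum >= sum(as.numeric(s)) / 2)[1]]
}

#' Assembly quality statistics
#'
#' The per-stage quality panel: transcript count, GC percentage (computed on
#' `A/C/G/T` only, `N` excluded from numerator and denominator), median
#' contig length (mean of the two central values for even counts), N50 and
#' total bases.
#'
#' @param assembly a non-empty assembly set.
#' @return an object of class `assembly_stats` (a named list with fields
#'   `n_transcripts`, `gc_percent`, `median_length`, `n50`, `total_bases`).
#' @export
assembly_stats <- function(assembly) {
  if (length(assembly) == 0) stop_input("empty assembly")
  x <- as(assembly, "DNAStringSet")
  af <- Biostrings::alphabetFrequency(x, baseOnly = TRUE)
  counts <- colSums(af)
  acgt <- sum(counts[c("A", "C", "G", "T")])
  if (acgt == 0) stop_input("assembly contains no A/C/G/T bases")
  lens <- Biostrings::width(x)
  structure(list(
    n_transcripts = length(x),
    gc_percent = 100 * sum(counts[c("G", "C")]) / acgt,
    median_length = median(lens),
    n50 = assembly_n50(lens),
    total_bases = sum(as.numeric(lens))
  ), class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("Assembly statistics\n")
  cat(sprintf("  # Transcripts:        %d\n", x$n_transcripts))
  cat(sprintf("  %%GC:                  %.2f\n", x$gc_percent))
  cat(sprintf("  Median contig length: %.1f\n", x$median_length))
  cat(sprintf("  N50:                  %d\n", x$n50))
  cat(sprintf("  # Bases:              %.0f\n", x$total_bases))
  invisible(x)
}

#' @export
as.data.frame.assembly_stats <- function(x, ...) {
  data.frame(n_transcripts = x$n_transcripts, gc_percent = x$gc_percent,
             median_length = x$median_length, n50 = x$n50,
             total_bases = x$total_bases)
}
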