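# microRNA precursor screening: combine an external hairpin classifier score
# (lower = more hairpin-like) with an internally computed mature-miRNA match

#' Read a mature-miRNA FASTA (RNA alphabet allowed)
#'
#' `U` is normalized to `T` and sequences are uppercased; characters outside
#' `{A,C,G,U,T,N}` are rejected.
#'
#' @param path FASTA of mature miRNA sequences (miRBase dialect).
#' @return a `DNAStringSet` named by mature id.
#' @export
read_mature_fasta <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  seqs <- toupper(as.character(x))
  bad <- grepl("[^ACGUTN]", seqs)
  if (any(bad))
    stop_input("mature sequence(s) outside the {A,C,G,U,T,N} alphabet: ",
               paste(ids[bad], collapse = ", "))
  seqs <- chartr("U", "T", seqs)
  validate_ids(ids)
  out <- Biostrings::DNAStringSet(setNames(seqs, ids))
  out
}

#' Read a hairpin score table
#'
#' TSV with columns `transcript_id` and `score` (classifier convention:
#' lower is more hairpin-like).
#'
#' @param path TSV file.
#' @return named numeric vector of scores.
#' @export
read_hairpin_scores <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "score") %in% colnames(df)))
    stop_input(path, ": needs columns transcript_id, score")
  score <- as.numeric(df$score)
  if (anyNA(score) || any(!is.finite(score)))
    stop_input("scores must be finite numbers")
  setNames(score, df$transcript_id)
}

#' Match mature miRNAs against transcripts
#'
#' Every full-length ungapped placement of each mature sequence on each
#' transcript (both strands) with Hamming distance <= `max_mismatch` is
#' reported. `start` is the 0-based offset of the window on the transcript's
#' forward strand; `N` positions count as mismatches. A mature longer than
#' the transcript is skipped silently.
#'
#' @param assembly an assembly set of candidate transcripts.
#' @param matures a `DNAStringSet` (see [read_mature_fasta()]) or named
#'   character vector of mature sequences.
#' @param max_mismatch maximum mismatches (default 2).
#' @return data.frame with columns `transcript_id`, `mature_id`, `start`,
#'   `strand`, `mismatches`, ordered by (transcript, mature, start).
#' @export
match_mature <- function(assembly, matures, max_mismatch = 2L) {
  stopifnot(max_mismatch >= 0)
  mat_names <- names(matures)
  if (is.null(mat_names) || any(!nzchar(mat_names)))
    stop_input("mature sequences must be named")
  mat <- setNames(toupper(as.character(matures)), mat_names)
  tx <- as.character(assembly)
  rows <- list()
  for (ti in seq_along(tx)) {
    for (mi in seq_along(mat)) {
      m <- mat[[mi]]
      if (nchar(m) > nchar(tx[[ti]])) next
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") m else revcomp(m)
        hit <- hamming_windows_cpp(tx[[ti]], pat, as.integer(max_mismatch))
        if (nrow(hit)) {
          rows[[length(rows) + 1L]] <- data.frame(
            transcript_id = names(assembly)[ti], mature_id = names(mat)[mi],
            start = hit$start, strand = strand, mismatches = hit$mismatches,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(transcript_id = character(), mature_id = character(),
                      start = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(match(out$transcript_id, names(assembly)),
                   match(out$mature_id, names(mat)), out$start), ]
  rownames(out) <- NULL
  out
}

#' Call microRNA precursor candidates
#'
#' A transcript is a candidate iff its hairpin score is <= `score_max`
#' (inclusive: a score of exactly 0.71 qualifies at the default) AND it has
#' at least one mature match. Transcripts absent from the score table are
#' never candidates.
#'
#' @param scores named numeric vector (see [read_hairpin_scores()]).
#' @param matches a [match_mature()] table.
#' @param score_max inclusive score ceiling (default 0.71).
#' @return an object of class `precursor_candidates`: data.frame with
#'   columns `transcript_id`, `score`, `n_matches`, `best_mature_id`,
#'   `best_mismatches`; the full match rows of the candidates are attached
#'   as `attr(x, "matches")`.
#' @export
call_candidates <- function(scores, matches, score_max = 0.71) {
  stopifnot(is.finite(score_max))
  scored <- names(scores)[scores <= score_max]
  with_match <- unique(matches$transcript_id)
  cand_ids <- scored[scored %in% with_match]
  rows <- lapply(cand_ids, function(id) {
    mm <- matches[matches$transcript_id == id, , drop = FALSE]
    best <- mm[order(mm$mismatches, match(mm$mature_id, mm$mature_id)), ][1, ]
    data.frame(transcript_id = id, score = unname(scores[id]),
               n_matches = nrow(mm), best_mature_id = best$mature_id,
               best_mismatches = best$mismatches, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(transcript_id = character(), score = numeric(),
                         n_matches = integer(), best_mature_id = character(),
                         best_mismatches = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("precursor_candidates", "data.frame"),
            matches = matches[matches$transcript_id %in% cand_ids, ,
                              drop = FALSE],
            score_max = score_max)
}

#' @export
print.precursor_candidates <- function(x, ...) {
  cat(sprintf("precursor_candidates: %d candidate(s) at score <= %.2f\n",
              nrow(x), attr(x, "score_max")))
  if (nrow(x)) print(as.data.frame(x))
  invisible(x)
}
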