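# simplified coding-sequence consolidation: per-transcript ORF calls, gene
# grouping by CDS identity, and member classification (main/noclass/althi/
# altmid/part/noncoding)

STOP_CODONS <- c("TAA", "TAG", "TGA")

translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X" # codons containing N
  paste(aa, collapse = "")
}

# best ORF within one reading frame of one oriented sequence; returns NULL
# or list(local_start0, cds_length, complete) with 0-based local coordinates
frame_best_orf <- function(codons, min_codons, prefer_late_start = FALSE) {
  atg <- which(codons == "ATG")
  if (length(atg) == 0) return(NULL)
  stops <- which(codons %in% STOP_CODONS)
  k <- length(codons)
  # stop at or after each ATG; NA when the frame runs off the contig end
  nxt <- if (length(stops)) stops[findInterval(atg, stops, left.open = TRUE) + 1L]
         else rep(NA_integer_, length(atg))
  len_codons <- ifelse(is.na(nxt), k - atg + 1L, nxt - atg + 1L)
  ok <- len_codons >= min_codons
  if (!any(ok)) return(NULL)
  atg <- atg[ok]; nxt <- nxt[ok]; len_codons <- len_codons[ok]
  best_len <- max(len_codons)
  cand <- which(len_codons == best_len)
  pick <- if (prefer_late_start) cand[length(cand)] else cand[1]
  list(atg_codon = atg[pick], len_codons = best_len,
       complete = !is.na(nxt[pick]))
}

#' Longest ATG-initiated open reading frame
#'
#' Scans all six frames for the longest ORF starting at `ATG`; the stop codon
#' is included when present, otherwise the ORF runs open-ended to the contig
#' edge and is flagged incomplete. Ties go to the forward strand, then the
#' smaller frame, then the smaller forward-strand start.
#'
#' @param record a nucleotide string (or a length-1 assembly set element).
#' @param min_cds minimum CDS length in bases (multiple of 3, >= 3).
#' @return `NULL` when no ORF reaches `min_cds`; otherwise a list with
#'   `frame` (1..3 forward, -1..-3 reverse), 0-based forward-strand
#'   `cds_start`/`cds_end`, `cds_length`, `protein` (stop excluded) and
#'   `complete`.
#' @examples
#' find_longest_orf("ATGAAATAG")$protein # "MK"
#' @export
find_longest_orf <- function(record, min_cds = 90L) {
  if (min_cds < 3 || min_cds %% 3 != 0)
    stop_input("`min_cds` must be a positive multiple of 3")
  seq <- toupper(as.character(record))
  L <- nchar(seq)
  min_codons <- min_cds %/% 3
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (off in 0:2) {
      n_codons <- (L - off) %/% 3
      if (n_codons < min_codons) next
      starts <- seq.int(off + 1L, by = 3L, length.out = n_codons)
      codons <- substring(s, starts, starts + 2L)
      # on the reverse strand, the latest local start is the smallest
      # forward-strand cds_start
      hit <- frame_best_orf(codons, min_codons,
                            prefer_late_start = (strand == "-"))
      if (is.null(hit)) next
      local0 <- off + (hit$atg_codon - 1L) * 3L # 0-based on oriented seq
      cds_len <- hit$len_codons * 3L
      if (strand == "+") {
        cds_start <- local0
      } else {
        cds_start <- L - (local0 + cds_len)
      }
      cand <- list(frame = if (strand == "+") off + 1L else -(off + 1L),
                   cds_start = cds_start, cds_end = cds_start + cds_len,
                   cds_length = cds_len,
                   protein = translate_codons(
                     codons[hit$atg_codon:(hit$atg_codon + hit$len_codons -
                                             1L - hit$complete)]),
                   complete = hit$complete,
                   cds_seq = substr(s, local0 + 1L, local0 + cds_len))
      if (is.null(best) || cand$cds_length > best$cds_length) best <- cand
    }
  }
  best
}

check_consolidate_params <- function(min_cds, althi_min, altmid_min,
                                     part_max_frac) {
  if (!(altmid_min > 0 && altmid_min < althi_min && althi_min <= 1))
    stop_input("need 0 < altmid_min < althi_min <= 1")
  if (!(part_max_frac > 0 && part_max_frac < 1))
    stop_input("need 0 < part_max_frac < 1")
  if (min_cds < 3 || min_cds %% 3 != 0)
    stop_input("`min_cds` must be a positive multiple of 3")
  invisible(TRUE)
}

# union-find over 1..n
uf_groups <- function(n, edges_i, edges_j) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(edges_i)) {
    ri <- find(edges_i[e]); rj <- find(edges_j[e])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  vapply(seq_len(n), find, integer(1))
}

#' Consolidate transcripts into gene groups
#'
#' A simplified stand-in for coding-sequence-driven gene consolidation:
#' the longest ORF is called per transcript; coding transcripts are grouped
#' by single linkage over CDS identity >= `altmid_min` (identity as in
#' [pairwise_identity()], computed on the CDS substrings in coding
#' orientation); within each group the primary is the transcript with the
#' longest CDS (ties: longer transcript, then smaller id). Non-primary
#' members are `part` when their CDS is shorter than
#' `part_max_frac` x primary CDS (overriding alternate labels), else `althi`
#' at CDS identity >= `althi_min`, else `altmid`. Transcripts without an ORF
#' become singleton non-coding groups. Gene ids are `ESG` + zero-padded
#' integers in primary ingest order.
#'
#' @param assembly an assembly set.
#' @param min_cds minimum CDS length (bases, multiple of 3).
#' @param althi_min,altmid_min CDS identity floors of the high/medium
#'   alternate categories.
#' @param part_max_frac CDS-length fraction below which a member is `part`.
#' @return an object of class `gene_groups`: a data.frame with columns
#'   `gene_id`, `transcript_id`, `category`, `coding`, `cds_start`,
#'   `cds_end`, `frame`, `cds_length`, `protein`.
#' @export
consolidate_genes <- function(assembly, min_cds = 90L, althi_min = 0.98,
                              altmid_min = 0.90, part_max_frac = 0.70) {
  check_consolidate_params(min_cds, althi_min, altmid_min, part_max_frac)
  ids <- names(assembly)
  n <- length(ids)
  seqs <- as.character(assembly)
  orfs <- lapply(seqs, find_longest_orf, min_cds = min_cds)
  coding <- !vapply(orfs, is.null, logical(1))
  cidx <- which(coding)
  group_of <- integer(n)
  if (length(cidx)) {
    cds <- vapply(orfs[cidx], `[[`, character(1), "cds_seq")
    # word size 9 keeps the shared-k-mer skip bound informative at the 0.90
    # linkage floor (k*(1-c) must stay below 1)
    pairs <- identity_pairs_cpp(unname(cds), altmid_min, 9L, TRUE)
    comp <- uf_groups(length(cidx), pairs$i, pairs$j)
    group_of[cidx] <- comp
  }
  # groups: coding components + noncoding singletons, keyed by the smallest
  # ingest index they contain
  groups <- split(seq_len(n)[coding], group_of[coding])
  groups <- c(groups, as.list(which(!coding)))
  rows <- vector("list", length(groups))
  primary_pos <- integer(length(groups))
  lens <- nchar(seqs)
  for (g in seq_along(groups)) {
    members <- groups[[g]]
    if (length(members) == 1 && !coding[members]) {
      primary_pos[g] <- members
      rows[[g]] <- data.frame(transcript_id = ids[members],
                              category = "noncoding", coding = FALSE,
                              cds_start = NA_integer_, cds_end = NA_integer_,
                              frame = NA_integer_, cds_length = 0L,
                              protein = "", stringsAsFactors = FALSE)
      next
    }
    cds_len <- vapply(orfs[members], `[[`, integer(1), "cds_length")
    ord <- order(-cds_len, -lens[members], ids[members], method = "radix")
    prim <- members[ord[1]]
    primary_pos[g] <- prim
    prim_cds <- orfs[[prim]]$cds_seq
    cat_of <- character(length(members))
    for (t in seq_along(members)) {
      m <- members[t]
      if (m == prim) {
        cat_of[t] <- if (length(members) > 1) "main" else "noclass"
      } else if (orfs[[m]]$cds_length < part_max_frac * orfs[[prim]]$cds_length) {
        cat_of[t] <- "part"
      } else {
        idf <- pairwise_identity(orfs[[m]]$cds_seq, prim_cds, "forward")
        idr <- pairwise_identity(orfs[[m]]$cds_seq, prim_cds, "reverse")
        cat_of[t] <- if (max(idf, idr) >= althi_min) "althi" else "altmid"
      }
    }
    rows[[g]] <- data.frame(
      transcript_id = ids[members], category = cat_of, coding = TRUE,
      cds_start = vapply(orfs[members], `[[`, integer(1), "cds_start"),
      cds_end = vapply(orfs[members], `[[`, integer(1), "cds_end"),
      frame = vapply(orfs[members], `[[`, integer(1), "frame"),
      cds_length = cds_len,
      protein = vapply(orfs[members], `[[`, character(1), "protein"),
      stringsAsFactors = FALSE)
  }
  # gene numbering follows the primary id so it is invariant under input
  # permutation
  ord_g <- order(ids[primary_pos], method = "radix")
  rows <- rows[ord_g]
  gene_ids <- sprintf("ESG%06d", seq_along(rows))
  out <- do.call(rbind, Map(function(df, gid) cbind(gene_id = gid, df,
                                                    stringsAsFactors = FALSE),
                            rows, gene_ids))
  rownames(out) <- NULL
  structure(out, class = c("gene_groups", "data.frame"),
            params = list(min_cds = min_cds, althi_min = althi_min,
                          altmid_min = altmid_min,
                          part_max_frac = part_max_frac))
}

#' @export
print.gene_groups <- function(x, ...) {
  cat(sprintf("gene_groups: %d transcripts in %d genes\n",
              nrow(x), length(unique(x$gene_id))))
  print(table(x$category))
  invisible(x)
}

#' Select the retained transcript set of a consolidation
#'
#' The default profile keeps everything (primaries and all alternates);
#' filtering is the business of the containment and abundance stages.
#' Stricter profiles may drop `part` and/or `noncoding` members.
#'
#' @param groups a [consolidate_genes()] result.
#' @param assembly the assembly the groups were computed on.
#' @param drop categories to drop: any of `"part"`, `"noncoding"`.
#' @return the retained sub-assembly, in ingest order.
#' @export
select_okay_set <- function(groups, assembly, drop = character()) {
  bad <- setdiff(drop, c("part", "noncoding"))
  if (length(bad)) stop_input("unknown drop categories: ",
                              paste(bad, collapse = ", "))
  keep_ids <- groups$transcript_id[!groups$category %in% drop]
  assembly_subset(assembly, keep_ids)
}

#' Write a gene map TSV
#'
#' Columns: `gene_id`, `transcript_id`, `category`, `coding`, `cds_start`,
#' `cds_end`, `frame`.
#'
#' @param groups a [consolidate_genes()] result.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(groups, path) {
  write.table(groups[c("gene_id", "transcript_id", "category", "coding",
                       "cds_start", "cds_end", "frame")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write primary-CDS protein translations as FASTA
#'
#' One entry per gene group whose primary transcript is coding.
#'
#' @param groups a [consolidate_genes()] result.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_primary_proteins <- function(groups, path) {
  prim <- groups[groups$category %in% c("main", "noclass") & groups$coding, ]
  aa <- Biostrings::AAStringSet(setNames(prim$protein,
                                         paste(prim$gene_id,
                                               prim$transcript_id)))
  Biostrings::writeXStringSet(aa, filepath = path)
  invisible(path)
}
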