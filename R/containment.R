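# containment-based redundancy removal: discard transcripts whose sequence
# is included in a longer transcript for more than `coverage_min` of their
# length

#' Containment parameters
#'
#' @param coverage_min covered fraction above which (strict `>`) a contained
#'   transcript is discarded; default 0.90.
#' @param block_identity_min minimum ungapped identity of a matched block.
#' @param kmer_size seed word size.
#' @param both_strands scan the reverse complement as well.
#' @param chain_gap maximum gap (bases) between seeds chained on one
#'   diagonal before a block is split.
#' @return an object of class `containment_params`.
#' @export
containment_params <- function(coverage_min = 0.90, block_identity_min = 0.95,
                               kmer_size = 15L, both_strands = TRUE,
                               chain_gap = 50L) {
  stopifnot(coverage_min > 0, coverage_min < 1,
            block_identity_min > 0, block_identity_min <= 1,
            kmer_size >= 8, kmer_size <= 15, chain_gap >= 0)
  structure(list(coverage_min = coverage_min,
                 block_identity_min = block_identity_min,
                 kmer_size = as.integer(kmer_size),
                 both_strands = both_strands,
                 chain_gap = as.integer(chain_gap)),
            class = "containment_params")
}

#' All-vs-all containment scan
#'
#' For every (shorter, longer-or-equal) pair sharing a seed k-mer, matched
#' blocks (seed, chain on diagonal, verify at `block_identity_min`, extend
#' ungapped) are projected onto the shorter sequence and merged; the covered
#' fraction is the union length over the shorter length. Both strands are
#' scanned when configured and the better strand is reported. One hit is
#' emitted per pair with covered fraction > 0.
#'
#' @param assembly an assembly set.
#' @param params a [containment_params()].
#' @return an object of class `containment_hits`: data.frame with columns
#'   `contained_id`, `container_id`, `covered_fraction`, `n_blocks`,
#'   `strand`.
#' @export
containment_scan <- function(assembly, params = containment_params()) {
  ids <- names(assembly)
  res <- containment_scan_cpp(unname(as.character(assembly)),
                              params$kmer_size, params$block_identity_min,
                              params$both_strands, params$chain_gap)
  out <- data.frame(contained_id = ids[res$contained],
                    container_id = ids[res$container],
                    covered_fraction = res$covered_fraction,
                    n_blocks = res$n_blocks,
                    strand = res$strand, stringsAsFactors = FALSE)
  out <- out[order(match(out$contained_id, ids), match(out$container_id, ids)), ]
  rownames(out) <- NULL
  structure(out, class = c("containment_hits", "data.frame"), params = params)
}

#' Prune contained transcripts
#'
#' Removes every record covered for strictly more than `coverage_min` of its
#' length by a strictly longer record, in a single pass against the original
#' set (a fragment contained only in another removed fragment is still
#' removed). Equal-length pairs above the threshold are mutual containment:
#' the lexicographically smaller id is kept. Exactly 90.0% coverage is kept
#' at the default threshold ("more than 90%" is strict).
#'
#' @inheritParams containment_scan
#' @return the pruned assembly, ingest order preserved; removed ids are
#'   available via `S4Vectors::metadata(x)$removed_ids` and the full hit
#'   table via `metadata(x)$hits`.
#' @export
containment_prune <- function(assembly, params = containment_params()) {
  hits <- containment_scan(assembly, params)
  lens <- setNames(Biostrings::width(assembly), names(assembly))
  over <- hits[hits$covered_fraction > params$coverage_min, , drop = FALSE]
  longer <- lens[over$container_id] > lens[over$contained_id]
  equal <- lens[over$container_id] == lens[over$contained_id] &
    over$container_id < over$contained_id
  removed <- unique(over$contained_id[longer | equal])
  out <- assembly[!names(assembly) %in% removed]
  S4Vectors::metadata(out)$removed_ids <- removed
  S4Vectors::metadata(out)$hits <- hits
  out
}

#' Write a containment hit table as TSV
#'
#' Columns: `contained_id`, `container_id`, `covered_fraction` (4 decimals),
#' `n_blocks`, `strand`.
#'
#' @param hits a [containment_scan()] result.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_containment_tsv <- function(hits, path) {
  df <- hits
  df$covered_fraction <- sprintf("%.4f", df$covered_fraction)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
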