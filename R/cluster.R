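# greedy incremental identity clustering of near-duplicate transfrags
# (the cd-hit-est-style collapse at 95% identity)

#' Clustering parameters
#'
#' @param identity_min minimum identity (matched bases / shorter length) for
#'   a sequence to join a cluster; default 0.95.
#' @param kmer_size word size of the lossless candidate prefilter.
#' @param both_strands compare the reverse complement as well.
#' @param assign_mode `"first_hit"` joins the first qualifying cluster in
#'   founding order (greedy default); `"best_hit"` the highest-identity one.
#' @param use_prefilter disable only to cross-check prefilter soundness.
#' @return an object of class `cluster_params`.
#' @export
cluster_params <- function(identity_min = 0.95, kmer_size = 11L,
                           both_strands = TRUE,
                           assign_mode = c("first_hit", "best_hit"),
                           use_prefilter = TRUE) {
  assign_mode <- match.arg(assign_mode)
  stopifnot(identity_min > 0, identity_min <= 1, kmer_size >= 4,
            kmer_size <= 15)
  structure(list(identity_min = identity_min, kmer_size = as.integer(kmer_size),
                 both_strands = both_strands, assign_mode = assign_mode,
                 use_prefilter = use_prefilter),
            class = "cluster_params")
}

#' Pairwise sequence identity
#'
#' Identity of the optimal semi-global alignment: the shorter sequence is
#' aligned end to end, leading/trailing bases of the longer are free
#' (match +2, mismatch -1, gap -3; among equal-score alignments the one with
#' most matches). Identity = matched bases / shorter length, so an exact
#' substring scores 1.
#'
#' @param a,b nucleotide strings over `{A,C,G,T,N}` (`N` never matches).
#' @param strand `"forward"`, or `"reverse"` to reverse-complement `b` first.
#' @return identity in `[0, 1]`.
#' @examples
#' pairwise_identity("ACGTACGT", "ACGT") # 1
#' @export
pairwise_identity <- function(a, b, strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop_input("empty sequence")
  pair_identity_cpp(a, b, strand == "reverse")$identity
}

#' Greedy incremental identity clustering
#'
#' Records are processed in descending length order (ties by ascending id);
#' each joins the first existing cluster whose representative reaches
#' `identity_min` on either strand, else founds a new cluster. A shared
#' k-mer count bound (derived from the substitution budget at
#' `identity_min`) prefilters representative comparisons. Output is
#' invariant under input permutation.
#'
#' @param assembly an assembly set.
#' @param params a [cluster_params()].
#' @return an object of class `cluster_set`: a data.frame with columns
#'   `member_id`, `representative_id`, `identity`, `strand`, in canonical
#'   (length-descending) processing order.
#' @export
greedy_cluster <- function(assembly, params = cluster_params()) {
  if (length(assembly) == 0) stop_input("empty assembly")
  ids <- names(assembly)
  ord <- order(-Biostrings::width(assembly), ids, method = "radix")
  seqs <- as.character(assembly[ord])
  res <- greedy_cluster_cpp(unname(seqs), params$identity_min,
                            params$kmer_size, params$both_strands,
                            params$assign_mode == "best_hit",
                            params$use_prefilter)
  out <- data.frame(member_id = ids[ord],
                    representative_id = ids[ord][res$rep],
                    identity = res$identity,
                    strand = res$strand,
                    stringsAsFactors = FALSE)
  structure(out, class = c("cluster_set", "data.frame"), params = params)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d members in %d clusters\n",
              nrow(x), length(unique(x$representative_id))))
  invisible(x)
}

#' Representative sub-assembly of a clustering
#'
#' @param clusters a [greedy_cluster()] result.
#' @param assembly the assembly the clustering was computed on.
#' @return the sub-assembly of cluster representatives, in ingest order.
#' @export
cluster_representatives <- function(clusters, assembly) {
  reps <- unique(clusters$representative_id)
  dangling <- setdiff(reps, names(assembly))
  if (length(dangling))
    stop_input("representative id(s) absent from assembly: ",
               paste(dangling, collapse = ", "))
  assembly_subset(assembly, reps)
}

#' Write a cluster table as TSV
#'
#' Columns: `representative_id`, `member_id`, `identity` (4 decimals),
#' `strand`.
#'
#' @param clusters a [greedy_cluster()] result.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(clusters, path) {
  df <- data.frame(representative_id = clusters$representative_id,
                   member_id = clusters$member_id,
                   identity = sprintf("%.4f", clusters$identity),
                   strand = clusters$strand, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
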