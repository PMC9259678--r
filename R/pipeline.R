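# pipeline orchestration: expression filter per assembly -> pool -> identity
# clustering -> gene consolidation -> containment pruning -> mean-abundance
# filter, with a per-stage report ledger

#' Pipeline configuration
#'
#' Collects every stage's inputs and thresholds in one place. The study
#' constants live in the stage parameter objects: 1 TPM per condition,
#' 0.95 clustering identity, 0.90 containment coverage, 0.1 mean TPM, and
#' (optionally) the 0.71 hairpin score ceiling with 2 mature mismatches.
#'
#' @param assembly_paths named character vector of FASTA paths (names are
#'   assembler labels); alternatively pass loaded assemblies via
#'   `assemblies`.
#' @param assemblies optional list of assembly sets (overrides paths).
#' @param quant_paths per-sample `quant.sf` files; or pass a loaded
#'   [quant_table()] via `quant`.
#' @param quant optional [quant_table()] (overrides `quant_paths`).
#' @param sample_ids sample names matching `quant_paths`.
#' @param design_path sample design CSV; or pass `design` directly.
#' @param design optional [sample_design()].
#' @param thresholds a [filter_thresholds()].
#' @param cluster a [cluster_params()].
#' @param consolidate list of [consolidate_genes()] arguments.
#' @param containment a [containment_params()].
#' @param mirna optional list with `mature_path`/`matures`,
#'   `score_path`/`scores`, `score_max` (default 0.71), `max_mismatch`
#'   (default 2).
#' @param outdir optional output directory for stage artifacts.
#' @param library_groups optional named vector label -> library group
#'   (bookkeeping only, echoed in reports).
#' @param seed integer recorded in every report (no pipeline stage draws
#'   random numbers; the seed documents fixture provenance).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(assembly_paths = NULL, assemblies = NULL,
                            quant_paths = NULL, quant = NULL,
                            sample_ids = NULL,
                            design_path = NULL, design = NULL,
                            thresholds = filter_thresholds(),
                            cluster = cluster_params(),
                            consolidate = list(),
                            containment = containment_params(),
                            mirna = NULL, outdir = NULL,
                            library_groups = NULL, seed = 1L) {
  if (is.null(assemblies) && is.null(assembly_paths))
    stop_input("need `assembly_paths` or `assemblies`")
  for (p in c(assembly_paths, quant_paths, design_path))
    if (!is.null(p) && !file.exists(p)) stop_input("no such file: ", p)
  structure(list(assembly_paths = assembly_paths, assemblies = assemblies,
                 quant_paths = quant_paths, quant = quant,
                 sample_ids = sample_ids,
                 design_path = design_path, design = design,
                 thresholds = thresholds, cluster = cluster,
                 consolidate = consolidate, containment = containment,
                 mirna = mirna, outdir = outdir,
                 library_groups = library_groups, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_report <- function(stage, before, after, params = list(), notes = "",
                         seed = NA_integer_) {
  input_n <- length(before)
  kept_n <- length(after)
  list(stage = stage, input_n = input_n, kept_n = kept_n,
       removed_n = input_n - kept_n,
       stats_before = if (input_n) unclass(assembly_stats(before)) else NULL,
       stats_after = if (kept_n) unclass(assembly_stats(after)) else NULL,
       parameters = params, notes = notes, seed = seed)
}

#' Run the consolidation pipeline
#'
#' Stage order: (1) per-assembly expression filter at the per-condition TPM
#' floor; (2) pool all survivors; (3) greedy identity clustering, keeping
#' representatives; (4) gene consolidation; (5) containment pruning;
#' (6) mean-abundance filter. Each stage appends a report with the count
#' identity `kept_n + removed_n = input_n`; when `outdir` is set, the final
#' FASTA, gene map, cluster and hit tables, and a JSON ledger are written.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `pipeline_result`: list with `final` (the
#'   consolidated assembly), `reports`, `gene_groups`, `clusters`,
#'   `candidates` (when a miRNA block is configured) and `outputs` (paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  assemblies <- config$assemblies
  if (is.null(assemblies)) {
    labels <- names(config$assembly_paths) %||%
      tools::file_path_sans_ext(basename(config$assembly_paths))
    assemblies <- Map(read_assembly_fasta, config$assembly_paths, labels)
    names(assemblies) <- labels
  }
  if (is.null(names(assemblies)))
    names(assemblies) <- sprintf("assembly%02d", seq_along(assemblies))
  quant <- config$quant
  design <- config$design
  if (is.null(quant) && !is.null(config$quant_paths))
    quant <- read_quant(config$quant_paths, config$sample_ids)
  if (is.null(design) && !is.null(config$design_path))
    design <- read_design(config$design_path)
  reports <- list()
  seed <- config$seed

  # (1) per-assembly expression filter
  if (!is.null(quant) && !is.null(design)) {
    kept_ids <- expression_filter(quant, design, config$thresholds)
    for (lab in names(assemblies)) {
      before <- assemblies[[lab]]
      after <- assembly_subset(before, kept_ids)
      group <- if (!is.null(config$library_groups))
        unname(config$library_groups[lab]) else NA_character_
      reports[[length(reports) + 1L]] <- stage_report(
        paste0("expression_filter:", lab), before, after,
        params = list(condition_tpm_min = config$thresholds$condition_tpm_min,
                      library_group = group),
        seed = seed)
      assemblies[[lab]] <- after
    }
  }

  # (2) pool survivors
  all_ids <- unlist(lapply(assemblies, names), use.names = FALSE)
  validate_ids(all_ids)
  pooled <- do.call(c, unname(lapply(assemblies, function(a)
    as(a, "DNAStringSet"))))
  mc <- do.call(rbind, unname(lapply(assemblies, S4Vectors::mcols)))
  S4Vectors::mcols(pooled) <- mc
  reports[[length(reports) + 1L]] <- stage_report(
    "pool", pooled, pooled,
    params = list(n_assemblies = length(assemblies)), seed = seed)

  # (3) identity clustering
  clusters <- greedy_cluster(pooled, config$cluster)
  reps <- cluster_representatives(clusters, pooled)
  reports[[length(reports) + 1L]] <- stage_report(
    "identity_cluster", pooled, reps,
    params = config$cluster[c("identity_min", "kmer_size", "both_strands",
                              "assign_mode")],
    seed = seed)

  # (4) gene consolidation
  groups <- do.call(consolidate_genes, c(list(reps), config$consolidate))
  okay <- select_okay_set(groups, reps)
  reports[[length(reports) + 1L]] <- stage_report(
    "consolidate", reps, okay,
    params = c(attr(groups, "params"),
               list(n_genes = length(unique(groups$gene_id)))),
    seed = seed)

  # (5) containment pruning
  pruned <- containment_prune(okay, config$containment)
  reports[[length(reports) + 1L]] <- stage_report(
    "containment_prune", okay, pruned,
    params = config$containment[c("coverage_min", "block_identity_min",
                                  "kmer_size", "both_strands")],
    seed = seed)

  # (6) mean-abundance filter
  final <- pruned
  if (!is.null(quant)) {
    kept <- mean_abundance_filter(quant_subset(quant, names(pruned)),
                                  config$thresholds)
    final <- assembly_subset(pruned, kept)
    reports[[length(reports) + 1L]] <- stage_report(
      "mean_abundance_filter", pruned, final,
      params = list(mean_tpm_min = config$thresholds$mean_tpm_min),
      seed = seed)
  }

  candidates <- NULL
  if (!is.null(config$mirna)) {
    m <- config$mirna
    matures <- m$matures %||% read_mature_fasta(m$mature_path)
    scores <- m$scores %||% read_hairpin_scores(m$score_path)
    matches <- match_mature(final, matures,
                            max_mismatch = m$max_mismatch %||% 2L)
    candidates <- call_candidates(scores, matches,
                                  score_max = m$score_max %||% 0.71)
  }

  outputs <- list()
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    outputs$fasta <- write_assembly_fasta(
      final, file.path(config$outdir, "final.fasta"))
    outputs$gene_map <- write_gene_map(
      groups, file.path(config$outdir, "gene_map.tsv"))
    outputs$clusters <- write_cluster_tsv(
      clusters, file.path(config$outdir, "clusters.tsv"))
    outputs$hits <- write_containment_tsv(
      S4Vectors::metadata(pruned)$hits,
      file.path(config$outdir, "containment_hits.tsv"))
    outputs$ledger <- render_report(
      reports, file.path(config$outdir, "ledger.json"))
  }

  structure(list(final = final, reports = reports, gene_groups = groups,
                 clusters = clusters, candidates = candidates,
                 outputs = outputs),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Consolidation pipeline result\n")
  cat(report_table(x$reports), sep = "\n")
  cat(sprintf("\nFinal: %d transcripts, %d genes\n", length(x$final),
              length(unique(x$gene_groups$gene_id))))
  invisible(x)
}

report_table <- function(reports) {
  fmt <- function(v) formatC(v, format = "fg", big.mark = ",")
  hdr <- c("stage", "input_n", "kept_n", "removed_n", "n50_after",
           "gc_after", "median_after")
  rows <- lapply(reports, function(r) {
    sa <- r$stats_after
    c(r$stage, fmt(r$input_n), fmt(r$kept_n), fmt(r$removed_n),
      if (is.null(sa)) "-" else fmt(sa$n50),
      if (is.null(sa)) "-" else sprintf("%.2f", sa$gc_percent),
      if (is.null(sa)) "-" else fmt(sa$median_length))
  })
  m <- rbind(hdr, do.call(rbind, rows))
  widths <- apply(nchar(m), 2, max)
  apply(m, 1, function(r)
    paste(mapply(formatC, r, width = widths,
                 MoreArgs = list(flag = "-")), collapse = "  "))
}

#' Render the stage ledger
#'
#' Writes the report list as JSON (machine-readable) and returns the
#' human-readable stage table.
#'
#' @param reports the `reports` field of a [run_pipeline()] result.
#' @param path optional JSON destination.
#' @return the JSON path (when written) or the table lines, invisibly.
#' @export
render_report <- function(reports, path = NULL) {
  if (length(reports) == 0) stop_input("empty report list")
  if (!is.null(path)) {
    jsonlite::write_json(reports, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    return(invisible(path))
  }
  invisible(report_table(reports))
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [pipeline_config()] arguments; threshold/parameter blocks
#' (`thresholds`, `cluster`, `containment`, `consolidate`, `mirna`) are
#' passed to the corresponding constructors.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  ap <- unlist(y$assemblies)
  pipeline_config(
    assembly_paths = setNames(rel(unname(ap)), names(ap)),
    quant_paths = if (!is.null(y$quant)) rel(unlist(y$quant)),
    sample_ids = y$sample_ids,
    design_path = if (!is.null(y$design)) rel(y$design),
    thresholds = do.call(filter_thresholds, y$thresholds %||% list()),
    cluster = do.call(cluster_params, y$cluster %||% list()),
    consolidate = y$consolidate %||% list(),
    containment = do.call(containment_params, y$containment %||% list()),
    mirna = if (!is.null(y$mirna)) {
      m <- y$mirna
      if (!is.null(m$mature_path)) m$mature_path <- rel(m$mature_path)
      if (!is.null(m$score_path)) m$score_path <- rel(m$score_path)
      m
    },
    outdir = y$outdir, library_groups = unlist(y$library_groups),
    seed = y$seed %||% 1L)
}
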