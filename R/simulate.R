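# seeded synthetic multi-assembler transcriptomes with a ground-truth
# manifest: gene families with shared CDS cores and isoform-specific UTRs,
# mutated duplicate copies, contained fragments, contaminants, and
# condition-structured zero-inflated log-normal expression

ASSEMBLER_LABELS <- c("asmA", "asmB", "asmC", "asmD", "asmE")

#' Simulation parameters
#'
#' Defaults describe the study conditions the pipeline targets: a
#' multi-assembler pool of roughly 2,000 transfrags at ~36% GC with mutated
#' duplicates (1% substitution rate), contained fragments covering 93-99% of
#' their parent, unexpressed contaminants, and 12 samples structured by
#' season, area and sex.
#'
#' @param seed integer master seed; every substream is derived from it.
#' @param n_genes number of gene families.
#' @param isoforms_range integer (min, max) isoforms per gene, uniform.
#' @param len_meanlog,len_sdlog log-normal transcript length parameters.
#' @param len_range truncation bounds (bases) for transcript lengths.
#' @param gc_target target GC fraction in (0, 1).
#' @param dup_rate probability a transcript gains a mutated duplicate copy.
#' @param dup_mutation_rate per-base substitution probability of duplicates.
#' @param frag_rate probability a transcript gains a contained fragment.
#' @param frag_cov_range (lo, hi) fragment length as a fraction of parent.
#' @param contaminant_n number of unexpressed contaminant sequences.
#' @param n_samples number of samples (design cycles season/area/sex).
#' @param expr_meanlog,expr_sdlog log-normal baseline TPM parameters.
#' @param condition_sdlog log-normal spread of the per-season effect.
#' @param noise_sdlog log-normal per-sample measurement noise.
#' @param dropout probability an expressed value is zeroed in one sample.
#' @param n_matures,mature_len,arm_len,loop_len microRNA fixture geometry.
#' @param mirna_mismatches planted mismatch counts, cycled over precursors.
#' @param mirna_decoys number of high-score decoy transcripts.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(seed = 1L, n_genes = 550L, isoforms_range = c(1L, 4L),
                       len_meanlog = log(1200), len_sdlog = 0.55,
                       len_range = c(300L, 6000L), gc_target = 0.36,
                       dup_rate = 0.15, dup_mutation_rate = 0.01,
                       frag_rate = 0.25, frag_cov_range = c(0.93, 0.99),
                       contaminant_n = 120L, n_samples = 12L,
                       expr_meanlog = log(50), expr_sdlog = 1.2,
                       condition_sdlog = 0.5, noise_sdlog = 0.3,
                       dropout = 0.1, n_matures = 20L, mature_len = 22L,
                       arm_len = 60L, loop_len = 15L,
                       mirna_mismatches = c(0L, 1L, 2L, 3L),
                       mirna_decoys = 30L) {
  stopifnot(dup_rate >= 0, dup_rate <= 1, frag_rate >= 0, frag_rate <= 1,
            dup_mutation_rate >= 0, dup_mutation_rate <= 1,
            dropout >= 0, dropout <= 1,
            frag_cov_range[1] < frag_cov_range[2],
            frag_cov_range[1] > 0, frag_cov_range[2] < 1,
            gc_target > 0, gc_target < 1,
            len_range[1] >= 200, len_range[2] <= 20000,
            isoforms_range[1] >= 1, isoforms_range[2] >= isoforms_range[1],
            arm_len >= mature_len, n_samples >= 2)
  structure(as.list(environment()), class = "sim_params")
}

rand_seq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random CDS: ATG + non-stop codons + stop, GC-weighted codon sampling
rand_cds <- function(n_codons, gc) {
  stopifnot(n_codons >= 3)
  all_codons <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                      paste0), c("A", "C", "G", "T"), paste0))
  body <- setdiff(all_codons, STOP_CODONS)
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  w <- vapply(body, function(cd) prod(base_p[strsplit(cd, "")[[1]]]), numeric(1))
  paste0("ATG",
         paste(sample(body, n_codons - 2L, replace = TRUE, prob = w),
               collapse = ""),
         sample(STOP_CODONS, 1L))
}

mutate_seq <- function(seq, rate, n_forced = NULL) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pos <- if (is.null(n_forced)) which(runif(n) < rate)
         else sample.int(n, n_forced)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

trunc_lnorm <- function(n, meanlog, sdlog, range) {
  x <- round(rlnorm(n, meanlog, sdlog))
  pmin(pmax(x, range[1]), range[2])
}

#' Simulate a multi-assembler transcriptome with ground truth
#'
#' Gene families share an in-frame CDS core (35-60% of the shortest isoform)
#' flanked by isoform-specific UTRs, so true alternates are distinguishable
#' both at 95% clustering identity and at 90% containment coverage, while
#' duplicates (parent copies mutated at `dup_mutation_rate`) and fragments
#' (contiguous substrings, half reverse-complemented) are removable. Fully
#' reproducible from `params$seed`.
#'
#' @param params a [sim_params()].
#' @return list with `assembly` (an assembly set; `source` mcol cycles fake
#'   assembler labels) and `manifest` (data.frame: `id`, `role` in
#'   primary_isoform/alt_isoform/duplicate/fragment/contaminant, `parent_id`,
#'   `gene`, `frag_cov` to 3 decimals, `length`, `expressed`,
#'   `intended_survivor`).
#' @export
simulate_transcriptome <- function(params = sim_params()) {
  with_seed(params$seed + 1L, {
    ids <- character(); seqs <- character(); roles <- character()
    parents <- character(); genes <- character(); covs <- numeric()
    add <- function(id, seq, role, parent = NA_character_,
                    gene = NA_character_, cov = NA_real_) {
      ids[length(ids) + 1L] <<- id
      seqs[length(seqs) + 1L] <<- seq
      roles[length(roles) + 1L] <<- role
      parents[length(parents) + 1L] <<- parent
      genes[length(genes) + 1L] <<- gene
      covs[length(covs) + 1L] <<- cov
    }
    for (g in seq_len(params$n_genes)) {
      gid <- sprintf("G%04d", g)
      n_iso <- sample(seq(params$isoforms_range[1], params$isoforms_range[2]), 1L)
      lens <- trunc_lnorm(n_iso, params$len_meanlog, params$len_sdlog,
                          params$len_range)
      core_codons <- max(34L, floor(runif(1, 0.35, 0.60) * min(lens) / 3))
      core <- rand_cds(core_codons, params$gc_target)
      core_len <- nchar(core)
      iso_seqs <- character(n_iso)
      for (i in seq_len(n_iso)) {
        utr_total <- max(20L, lens[i] - core_len)
        u5 <- floor(runif(1, 0.3, 0.7) * utr_total)
        iso_seqs[i] <- paste0(rand_seq(u5, params$gc_target), core,
                              rand_seq(utr_total - u5, params$gc_target))
      }
      prim <- which.max(nchar(iso_seqs))
      for (i in seq_len(n_iso)) {
        add(sprintf("%s.%d", gid, i), iso_seqs[i],
            if (i == prim) "primary_isoform" else "alt_isoform", gene = gid)
      }
    }
    n_iso_total <- length(ids)
    # mutated duplicate copies (near-identical transfrags from a second
    # assembler)
    dup_of <- which(runif(n_iso_total) < params$dup_rate)
    for (p in dup_of) {
      add(paste0(ids[p], "_d1"),
          mutate_seq(seqs[p], params$dup_mutation_rate),
          "duplicate", parent = ids[p], gene = genes[p])
    }
    # contained fragments, half reverse-complemented
    frag_of <- which(runif(n_iso_total) < params$frag_rate)
    for (p in frag_of) {
      L <- nchar(seqs[p])
      cov <- runif(1, params$frag_cov_range[1], params$frag_cov_range[2])
      flen <- round(cov * L)
      start <- sample.int(L - flen + 1L, 1L)
      fseq <- substr(seqs[p], start, start + flen - 1L)
      if (runif(1) < 0.5) fseq <- revcomp(fseq)
      add(paste0(ids[p], "_f1"), fseq, "fragment", parent = ids[p],
          gene = genes[p], cov = round(flen / L, 3))
    }
    for (k in seq_len(params$contaminant_n)) {
      add(sprintf("C%04d", k),
          rand_seq(trunc_lnorm(1, params$len_meanlog, params$len_sdlog,
                               params$len_range), params$gc_target),
          "contaminant")
    }
    manifest <- data.frame(
      id = ids, role = roles, parent_id = parents, gene = genes,
      frag_cov = covs, length = nchar(seqs),
      expressed = roles != "contaminant",
      intended_survivor = roles %in% c("primary_isoform", "alt_isoform"),
      stringsAsFactors = FALSE)
    assembly <- assembly_set(seqs, ids,
                             source = rep_len(ASSEMBLER_LABELS, length(ids)))
    # reassign duplicates to a different assembler than their parent
    src <- assembly_sources(assembly)
    list(assembly = assembly, manifest = manifest, source = src)
  })
}

default_design <- function(n_samples) {
  sample_design(data.frame(
    sample = sprintf("S%02d", seq_len(n_samples)),
    season = rep_len(c("summer", "winter"), n_samples),
    area = rep_len(c("south_georgia", "lazarev_sea", "bransfield"), n_samples),
    sex = rep_len(c("male", "female", "female", "male"), n_samples),
    stringsAsFactors = FALSE))
}

#' Simulate condition-structured expression tables
#'
#' Baseline abundance is log-normal per transcript, modulated by a
#' log-normal per-season effect and per-sample noise, zeroed at the dropout
#' rate; contaminants are unexpressed everywhere. Each sample's TPM column
#' is renormalized to sum to one million.
#'
#' @param manifest the manifest of [simulate_transcriptome()].
#' @param params the same [sim_params()].
#' @param dir optional directory: writes `quant.sf`-dialect files under
#'   `dir/<sample>/quant.sf` plus `design.csv`.
#' @return list with `quant` (a [quant_table()]), `design`
#'   (a [sample_design()]), `true_level_mean` (transcripts x season levels,
#'   pre-normalization generating means) and, when written, `paths`.
#' @export
simulate_quant <- function(manifest, params = sim_params(), dir = NULL) {
  with_seed(params$seed + 2L, {
    design <- default_design(params$n_samples)
    n <- nrow(manifest)
    season <- design$factors$season
    season_levels <- unique(unname(season))
    base <- rlnorm(n, params$expr_meanlog, params$expr_sdlog)
    eff <- matrix(rlnorm(n * length(season_levels), 0, params$condition_sdlog),
                  n, length(season_levels),
                  dimnames = list(manifest$id, season_levels))
    true_level_mean <- base * eff
    true_level_mean[!manifest$expressed, ] <- 0
    raw <- matrix(0, n, params$n_samples,
                  dimnames = list(manifest$id, design$sample_ids))
    for (s in seq_len(params$n_samples)) {
      lv <- season[[design$sample_ids[s]]]
      val <- true_level_mean[, lv] * rlnorm(n, 0, params$noise_sdlog)
      val[runif(n) < params$dropout] <- 0
      raw[, s] <- val
    }
    tpm <- sweep(raw, 2, colSums(raw), "/") * 1e6
    reads <- round(tpm * manifest$length / 1000, 2)
    quant <- quant_table(tpm, reads)
    out <- list(quant = quant, design = design,
                true_level_mean = true_level_mean)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      paths <- character(params$n_samples)
      for (s in seq_len(params$n_samples)) {
        sdir <- file.path(dir, design$sample_ids[s])
        dir.create(sdir, showWarnings = FALSE)
        paths[s] <- file.path(sdir, "quant.sf")
        df <- data.frame(Name = manifest$id, Length = manifest$length,
                         EffectiveLength = pmax(manifest$length - 150L, 10L),
                         TPM = sprintf("%.6f", tpm[, s]),
                         NumReads = sprintf("%.2f", reads[, s]))
        write.table(df, paths[s], sep = "\t", quote = FALSE, row.names = FALSE)
      }
      design_path <- file.path(dir, "design.csv")
      dd <- data.frame(sample = design$sample_ids,
                       lapply(design$factors, unname),
                       stringsAsFactors = FALSE)
      utils::write.csv(dd, design_path, row.names = FALSE, quote = FALSE)
      out$paths <- paths
      out$design_path <- design_path
    }
    out
  })
}

#' Simulate a microRNA screening fixture
#'
#' Planted precursors are hairpins (arm + loop + reverse-complemented arm)
#' with one mature sequence embedded in the 5' arm at a planted mismatch
#' count, and synthetic classifier scores at or below 0.71; decoys draw
#' scores above 0.71. The manifest states which records the screening rule
#' should call.
#'
#' @param params a [sim_params()].
#' @return list with `assembly`, `matures` (named character), `scores`
#'   (named numeric) and `manifest` (data.frame: `id`, `mature_id`,
#'   `mismatches`, `score`, `expected_candidate`).
#' @export
simulate_mirna_fixture <- function(params = sim_params()) {
  with_seed(params$seed + 3L, {
    matures <- setNames(
      vapply(seq_len(params$n_matures), function(i)
        rand_seq(params$mature_len, 0.5), character(1)),
      sprintf("mir-%03d", seq_len(params$n_matures)))
    ids <- character(); seqs <- character(); mat_id <- character()
    mm <- integer(); score <- numeric()
    for (i in seq_len(params$n_matures)) {
      m <- params$mirna_mismatches[(i - 1L) %% length(params$mirna_mismatches) + 1L]
      planted <- if (m > 0) mutate_seq(matures[[i]], 0, n_forced = m)
                 else matures[[i]]
      slack <- params$arm_len - params$mature_len
      at <- if (slack > 0) sample.int(slack + 1L, 1L) else 1L
      arm <- paste0(rand_seq(at - 1L, 0.5), planted,
                    rand_seq(slack - at + 1L, 0.5))
      ids <- c(ids, sprintf("hp%03d", i))
      seqs <- c(seqs, paste0(arm, rand_seq(params$loop_len, 0.3), revcomp(arm)))
      mat_id <- c(mat_id, names(matures)[i])
      mm <- c(mm, m)
      score <- c(score, round(runif(1, 0.2, 0.71), 3))
    }
    for (k in seq_len(params$mirna_decoys)) {
      dseq <- rand_seq(2L * params$arm_len + params$loop_len, 0.5)
      if (k %% 2 == 0) { # embedded mature but disqualifying score
        mi <- (k %% params$n_matures) + 1L
        substr(dseq, 10L, 9L + params$mature_len) <- matures[[mi]]
      }
      ids <- c(ids, sprintf("dc%03d", k))
      seqs <- c(seqs, dseq)
      mat_id <- c(mat_id, NA_character_)
      mm <- c(mm, NA_integer_)
      score <- c(score, round(runif(1, 0.72, 1.0), 3))
    }
    manifest <- data.frame(id = ids, mature_id = mat_id, mismatches = mm,
                           score = score,
                           expected_candidate = !is.na(mm) & mm <= 2L &
                             score <= 0.71,
                           stringsAsFactors = FALSE)
    list(assembly = assembly_set(seqs, ids, source = "mirna_sim"),
         matures = matures, scores = setNames(score, ids),
         manifest = manifest)
  })
}

#' Write a complete synthetic data set to a directory
#'
#' Emits per-assembler FASTA files, per-sample `quant.sf` tables, a design
#' CSV, a mature-miRNA FASTA, a hairpin score TSV and the ground-truth
#' manifests as JSON.
#'
#' @param params a [sim_params()].
#' @param dir output directory (created).
#' @return invisibly, the list of written paths.
#' @export
simulate_to_dir <- function(params = sim_params(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- simulate_transcriptome(params)
  qt <- simulate_quant(tr$manifest, params, dir = file.path(dir, "quant"))
  mir <- simulate_mirna_fixture(params)
  src <- assembly_sources(tr$assembly)
  fasta_paths <- character(0)
  for (lab in unique(src)) {
    p <- file.path(dir, paste0(lab, ".fasta"))
    write_assembly_fasta(tr$assembly[src == lab], p)
    fasta_paths <- c(fasta_paths, p)
  }
  mature_path <- file.path(dir, "matures.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(mir$matures), mature_path)
  score_path <- file.path(dir, "hairpin_scores.tsv")
  write.table(data.frame(transcript_id = names(mir$scores),
                         score = mir$scores),
              score_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(transcriptome = tr$manifest,
                            mirna = mir$manifest),
                       manifest_path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  mir_fasta <- file.path(dir, "mirna_transcripts.fasta")
  write_assembly_fasta(mir$assembly, mir_fasta)
  invisible(list(fasta = fasta_paths, quant = qt$paths,
                 design = qt$design_path, matures = mature_path,
                 scores = score_path, manifest = manifest_path,
                 mirna_fasta = mir_fasta))
}
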