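# independent oracles and fixture builders used across the suite; all are
# written without touching the package's own algorithm code paths

BASES <- c("A", "C", "G", "T")

rseq <- function(n, gc = 0.5) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# plant exactly n substitutions at distinct positions
plant_subs <- function(seq, n) {
  ch <- strsplit(seq, "")[[1]]
  for (p in sample.int(length(ch), n)) {
    ch[p] <- sample(setdiff(BASES, ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# 5' UTR whose length is a multiple of 3 and which ends with an in-frame
# stop, so planted CDS cores cannot be extended upstream by chance
guarded_utr5 <- function(n) {
  n <- max(3L, 3L * ceiling(n / 3))
  paste0(rseq(n - 3L), "TAA")
}

rc <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# naive N50: walk the sorted lengths accumulating until at least half
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  acc <- 0
  for (l in s) {
    acc <- acc + l
    if (acc >= half) return(l)
  }
}

# per-character counting oracle for the full stats panel
oracle_stats <- function(seqs) {
  chars <- unlist(strsplit(seqs, ""))
  acgt <- sum(chars %in% BASES)
  lens <- nchar(seqs)
  list(n_transcripts = length(seqs),
       gc_percent = 100 * sum(chars %in% c("G", "C")) / acgt,
       median_length = median(lens),
       n50 = oracle_n50(lens),
       total_bases = sum(lens))
}

# textbook semi-global DP (shorter sequence global, longer's ends free),
# maximising score (match +2 / mismatch -1 / gap -3), then matches; plain
# R matrices, independent of the package's packed-integer implementation
oracle_semiglobal <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  p <- strsplit(a, "")[[1]]; s <- strsplit(b, "")[[1]]
  m <- length(p); n <- length(s)
  S <- matrix(0, m + 1, n + 1); M <- matrix(0L, m + 1, n + 1)
  S[, 1] <- -3 * (0:m)
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      hit <- p[i - 1] != "N" && p[i - 1] == s[j - 1]
      cand_s <- c(S[i - 1, j - 1] + if (hit) 2 else -1,
                  S[i - 1, j] - 3, S[i, j - 1] - 3)
      cand_m <- c(M[i - 1, j - 1] + as.integer(hit), M[i - 1, j], M[i, j - 1])
      best <- max(cand_s)
      k <- which(cand_s == best)
      S[i, j] <- best
      M[i, j] <- max(cand_m[k])
    }
  }
  final <- S[m + 1, ]
  best <- max(final)
  matches <- max(M[m + 1, final == best])
  list(score = best, matches = matches, identity = matches / m)
}

# sliding-window Hamming oracle for mature matching (forward coordinates,
# both strands); returns rows (transcript_id, mature_id, start, strand,
# mismatches)
oracle_mature_matches <- function(tx, matures, max_mm = 2L) {
  out <- list()
  for (tn in names(tx)) {
    t_ch <- strsplit(tx[[tn]], "")[[1]]
    for (mn in names(matures)) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") matures[[mn]] else rc(matures[[mn]])
        p_ch <- strsplit(pat, "")[[1]]
        L <- length(p_ch)
        if (L > length(t_ch)) next
        for (s0 in 0:(length(t_ch) - L)) {
          win <- t_ch[(s0 + 1):(s0 + L)]
          mm <- sum(win != p_ch | win == "N" | p_ch == "N")
          if (mm <= max_mm)
            out[[length(out) + 1L]] <- data.frame(
              transcript_id = tn, mature_id = mn, start = s0,
              strand = strand, mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(transcript_id = character(), mature_id = character(),
                      start = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# brute-force 6-frame longest-ATG-ORF oracle (length and completeness only)
oracle_longest_orf_len <- function(seq, min_cds = 90L) {
  best <- 0L
  for (s in c(seq, rc(seq))) {
    L <- nchar(s)
    for (off in 0:2) {
      i <- off + 1L
      while (i + 2 <= L) {
        if (substr(s, i, i + 2) == "ATG") {
          j <- i
          len <- NA_integer_
          while (j + 2 <= L) {
            if (substr(s, j, j + 2) %in% c("TAA", "TAG", "TGA")) {
              len <- j + 3L - i
              break
            }
            j <- j + 3L
          }
          if (is.na(len)) len <- (((L - i + 1L) %/% 3L)) * 3L
          if (len >= min_cds && len > best) best <- len
        }
        i <- i + 3L
      }
    }
  }
  best
}

# quant fixture: named TPM matrix -> quant.sf-dialect files on disk
write_quant_fixture <- function(tpm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(ncol(tpm))
  for (k in seq_len(ncol(tpm))) {
    sdir <- file.path(dir, colnames(tpm)[k])
    dir.create(sdir, showWarnings = FALSE)
    paths[k] <- file.path(sdir, "quant.sf")
    write.table(data.frame(Name = rownames(tpm), Length = 500L,
                           EffectiveLength = 350L,
                           TPM = sprintf("%.6f", tpm[, k]),
                           NumReads = sprintf("%.2f", tpm[, k] * 0.5)),
                paths[k], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths
}

simple_design <- function(samples, ...) {
  sample_design(data.frame(sample = samples, ..., stringsAsFactors = FALSE))
}
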