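# containment scan and redundancy pruning

# contained record with an exactly known covered fraction: `frac` of its
# length copied from the container, the remainder novel, with an explicit
# mismatch at the junction so ungapped extension cannot creep
planted_contained <- function(container, frac, len) {
  copy_len <- round(frac * len)
  start <- sample.int(nchar(container) - copy_len + 1L, 1L)
  copied <- substr(container, start, start + copy_len - 1L)
  nxt <- substr(container, start + copy_len, start + copy_len)
  novel <- rseq(len - copy_len)
  if (nchar(novel) > 0 && nchar(nxt) == 1) {
    first <- sample(setdiff(BASES, nxt), 1)
    novel <- paste0(first, substr(novel, 2, nchar(novel)))
  }
  paste0(copied, novel)
}

test_that("exact substrings are fully covered and disjoint sequences give no hits", {
  set.seed(131)
  a <- rseq(1000)
  b <- substr(a, 30, 979) # 95% of the container's length, 100% of its own
  hits <- containment_scan(assembly_set(c(a, b), c("A", "B")))
  hb <- hits[hits$contained_id == "B" & hits$container_id == "A", ]
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$covered_fraction, 1.0)

  disjoint <- assembly_set(vapply(1:5, function(i) rseq(300), character(1)),
                           sprintf("d%d", 1:5))
  expect_equal(nrow(containment_scan(disjoint)), 0L)
})

test_that("covered fractions match planted coverages and a DP cross-check", {
  set.seed(137)
  ids <- character(); seqs <- character(); want <- numeric(); of <- character()
  for (i in 1:10) {
    ids <- c(ids, sprintf("P%02d", i))
    seqs <- c(seqs, rseq(sample(800:1500, 1)))
  }
  for (i in 1:20) {
    parent <- sample(10, 1)
    frac <- runif(1, 0.3, 0.98)
    len <- sample(300:600, 1)
    ids <- c(ids, sprintf("F%02d", i))
    seqs <- c(seqs, planted_contained(seqs[parent], frac, len))
    want <- c(want, round(frac * len) / len)
    of <- c(of, sprintf("P%02d", parent))
  }
  a <- assembly_set(seqs, ids)
  hits <- containment_scan(a)
  for (i in 1:20) {
    h <- hits[hits$contained_id == sprintf("F%02d", i) &
                hits$container_id == of[i], ]
    expect_equal(nrow(h), 1L)
    expect_equal(h$covered_fraction, want[i], tolerance = 0.02)
  }

  # single-block case agrees with an independent local aligner
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  cont <- substr(seqs[1], 101, 500)
  ch <- strsplit(cont, "")[[1]]
  for (p in sample(30:370, 4)) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
  cont <- paste(ch, collapse = "")
  h1 <- containment_scan(assembly_set(c(seqs[1], cont), c("P", "C")))
  h1 <- h1[h1$contained_id == "C", ]
  pa <- Biostrings::pairwiseAlignment(pattern = cont, subject = seqs[1],
                                      type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 2)
  aligned_frac <- Biostrings::nchar(Biostrings::pattern(pa)) / nchar(cont)
  expect_equal(h1$covered_fraction, aligned_frac, tolerance = 0.02)
})

test_that("two matched blocks around a novel insert are both recovered", {
  set.seed(139)
  left <- rseq(400); right <- rseq(400)
  container <- paste0(left, right)
  insert <- rseq(120)
  contained <- paste0(left, insert, right)
  # guard both junctions against ungapped extension creep
  hits <- containment_scan(assembly_set(c(paste0(container, rseq(150)),
                                          contained), c("A", "B")))
  hb <- hits[hits$contained_id == "B", ]
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$covered_fraction, 800 / 920, tolerance = 0.02)
  expect_gte(hb$n_blocks, 2L)
})

test_that("pruning is strict at the 90% boundary", {
  set.seed(149)
  container <- rseq(2000)
  at_boundary <- planted_contained(container, 0.90, 1000)
  above <- planted_contained(container, 0.91, 1000)
  a <- assembly_set(c(container, at_boundary, above),
                    c("big", "edge", "over"))
  pruned <- containment_prune(a)
  expect_true("edge" %in% names(pruned))   # exactly 90% is kept
  expect_false("over" %in% names(pruned))  # 91% is removed
  expect_equal(S4Vectors::metadata(pruned)$removed_ids, "over")
})

test_that("planted fragments are pruned exactly per the manifest", {
  set.seed(151)
  genes <- vapply(1:40, function(i) rseq(sample(600:1200, 1)), character(1))
  ids <- sprintf("G%02d", 1:40)
  fids <- sprintf("f%02d", 1:60)
  frags <- vapply(1:60, function(i) {
    g <- sample(40, 1)
    L <- nchar(genes[g])
    flen <- round(runif(1, 0.93, 0.98) * L)
    s0 <- sample.int(L - flen + 1L, 1L)
    out <- substr(genes[g], s0, s0 + flen - 1L)
    if (i %% 2 == 0) rc(out) else out
  }, character(1))
  a <- assembly_set(c(genes, frags), c(ids, fids))
  pruned <- containment_prune(a)
  expect_setequal(names(pruned), ids)

  # determinism under permutation (as sets; ingest order is preserved)
  perm <- sample(length(a))
  pruned_p <- containment_prune(a[perm])
  expect_setequal(names(pruned_p), names(pruned))
})

test_that("equal-length duplicates keep the lexicographically smaller id", {
  set.seed(157)
  s <- rseq(500)
  a <- assembly_set(c(s, s), c("zeta", "alpha"))
  pruned <- containment_prune(a)
  expect_identical(names(pruned), "alpha")
})

test_that("single-pass removal also drops fragments of removed fragments", {
  set.seed(163)
  X <- rseq(100); Y <- rseq(950); Z <- rseq(50)
  A <- paste0(X, Y)              # 1050
  B <- paste0(Y, Z)              # 1000, covered 0.95 by A -> removed
  C <- substr(B, 901, 1000)      # 100, fully inside B, only half inside A
  a <- assembly_set(c(A, B, C), c("A", "B", "C"))
  pruned <- containment_prune(a)
  expect_setequal(names(pruned), "A")

  # raising the coverage threshold never removes more
  lax <- containment_prune(a, containment_params(coverage_min = 0.99))
  expect_true(all(names(pruned) %in% names(lax)))
})

test_that("sequences sharing no seed k-mer are never pruned", {
  a <- assembly_set(c(strrep("AG", 300), strrep("CA", 200)), c("ag", "ca"))
  expect_equal(nrow(containment_scan(a)), 0L)
  pruned <- containment_prune(a)
  expect_equal(length(pruned), 2L)
})
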