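# semi-global identity and greedy incremental clustering

test_that("pairwise identity handles identity, containment and reverse strand", {
  set.seed(2)
  s <- rseq(400)
  expect_equal(pairwise_identity(s, s), 1)
  expect_equal(pairwise_identity(substr(s, 50, 249), s), 1)
  expect_equal(pairwise_identity(s, rc(s), "reverse"), 1)
  expect_lt(pairwise_identity(rseq(300), rseq(300)), 0.8)
})

test_that("pairwise identity matches the textbook semi-global DP oracle", {
  set.seed(17)
  for (i in 1:60) {
    la <- sample(30:90, 1)
    a <- rseq(la)
    b <- if (i %% 3 == 0) rseq(sample(30:90, 1))
         else plant_subs(substr(a, 1, sample(20:la, 1)),
                         sample(0:4, 1))
    got <- metamerge:::pair_identity_cpp(a, b, FALSE)
    want <- oracle_semiglobal(a, b)
    expect_equal(got$score, want$score)
    expect_equal(got$identity, want$identity, tolerance = 1e-9)
  }
})

test_that("alignment scores agree with an independent aligner", {
  set.seed(18)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                  baseOnly = TRUE)
  for (i in 1:25) {
    a <- rseq(sample(40:120, 1))
    b <- plant_subs(a, sample(0:6, 1))
    got <- metamerge:::pair_identity_cpp(a, b, FALSE)
    pa <- Biostrings::pairwiseAlignment(
      pattern = a, subject = b, type = "global-local",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 3)
    expect_equal(got$score, Biostrings::score(pa))
  }
})

test_that("clustering merges at 96% but not at 94% identity", {
  set.seed(41)
  s <- rseq(1000)
  near <- plant_subs(s, 40)   # 0.96 identity
  far <- plant_subs(s, 60)    # 0.94 identity
  expect_gte(pairwise_identity(near, s), 0.95)
  expect_lt(pairwise_identity(far, s), 0.95)

  a2 <- assembly_set(c(s, near), c("ref", "near"))
  cl2 <- greedy_cluster(a2)
  expect_equal(length(unique(cl2$representative_id)), 1L)
  a3 <- assembly_set(c(s, far), c("ref", "far"))
  cl3 <- greedy_cluster(a3)
  expect_equal(length(unique(cl3$representative_id)), 2L)

  # exact duplicates collapse, reverse-complements merge with strand "-"
  a4 <- assembly_set(c(s, s, rc(s)), c("a", "b", "c"))
  cl4 <- greedy_cluster(a4)
  expect_equal(unique(cl4$representative_id), "a")
  expect_equal(cl4$strand[cl4$member_id == "c"], "-")
})

test_that("planted families are recovered exactly", {
  set.seed(53)
  founders <- vapply(1:20, function(i) rseq(sample(250:400, 1)), character(1))
  ids <- character(); seqs <- character(); fam <- integer()
  for (f in 1:20) {
    for (m in 1:5) {
      s <- if (m == 1) founders[f]
           else plant_subs(founders[f], ceiling(0.02 * nchar(founders[f])))
      ids <- c(ids, sprintf("f%02dm%d", f, m))
      seqs <- c(seqs, s)
      fam <- c(fam, f)
    }
  }
  a <- assembly_set(seqs, ids)
  cl <- greedy_cluster(a)
  expect_equal(length(unique(cl$representative_id)), 20L)
  got <- setNames(cl$representative_id, cl$member_id)[ids]
  expect_equal(rand_index(got, setNames(fam, ids)), 1)

  # every member reaches the floor against its representative, and every
  # representative is at least as long as its members
  lens <- setNames(nchar(seqs), ids)
  for (k in seq_len(nrow(cl))) {
    expect_gte(cl$identity[k], 0.95)
    expect_gte(lens[cl$representative_id[k]], lens[cl$member_id[k]])
  }
  # founded representatives are mutually below the identity floor
  reps <- unique(cl$representative_id)
  seqs_by_id <- setNames(seqs, ids)
  for (i in seq_along(reps)) {
    for (j in seq_len(i - 1L)) {
      idf <- pairwise_identity(seqs_by_id[[reps[i]]], seqs_by_id[[reps[j]]])
      idr <- pairwise_identity(seqs_by_id[[reps[i]]], seqs_by_id[[reps[j]]],
                               "reverse")
      expect_lt(max(idf, idr), 0.95)
    }
  }
})

test_that("clustering is permutation-invariant and the prefilter is lossless", {
  set.seed(67)
  founders <- vapply(1:8, function(i) rseq(300), character(1))
  seqs <- c(founders, vapply(founders, plant_subs, character(1), n = 5),
            vapply(1:4, function(i) rseq(150), character(1)))
  ids <- sprintf("t%02d", seq_along(seqs))
  a <- assembly_set(seqs, ids)
  cl <- greedy_cluster(a)
  perm <- sample(length(a))
  cl_p <- greedy_cluster(a[perm])
  expect_equal(cl, cl_p, ignore_attr = TRUE)

  cl_nf <- greedy_cluster(a, cluster_params(use_prefilter = FALSE))
  expect_equal(cl, cl_nf, ignore_attr = TRUE)
})

test_that("representatives sub-assembly mirrors the clustering", {
  set.seed(71)
  seqs <- vapply(1:6, function(i) rseq(200), character(1))
  a <- assembly_set(seqs, sprintf("u%d", 1:6))
  cl <- greedy_cluster(a)
  reps <- cluster_representatives(cl, a)
  expect_equal(length(reps), length(unique(cl$representative_id)))
  expect_identical(names(reps), names(a)) # duplicate-free: identity

  cl$representative_id[1] <- "ghost"
  expect_error(cluster_representatives(cl, a), "ghost")
})
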