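# ORF calling and CDS-driven gene consolidation

test_that("ORF calling finds the longest ATG-initiated frame on both strands", {
  orf <- find_longest_orf("ATGAAATAG", min_cds = 9L)
  expect_equal(orf$cds_length, 9L)
  expect_equal(orf$protein, "MK")
  expect_true(orf$complete)
  expect_equal(orf$frame, 1L)
  expect_equal(orf$cds_start, 0L)

  # the reverse complement yields the same protein via a reverse frame
  orf_rc <- find_longest_orf(rc("ATGAAATAG"), min_cds = 9L)
  expect_equal(orf_rc$protein, "MK")
  expect_lt(orf_rc$frame, 0L)
  expect_equal(orf_rc$cds_length, 9L)

  expect_null(find_longest_orf("CCCCCC", min_cds = 9L))
  # open-ended ORF at a contig edge is allowed but incomplete
  orf_open <- find_longest_orf("ATGAAAGAAGAA", min_cds = 12L)
  expect_false(orf_open$complete)
  expect_equal(orf_open$cds_length, 12L)
  expect_equal(orf_open$protein, "MKEE")
})

test_that("ORF length agrees with a brute-force 6-frame oracle", {
  set.seed(83)
  for (i in 1:60) {
    s <- rseq(sample(90:240, 1))
    got <- find_longest_orf(s, min_cds = 30L)
    want <- oracle_longest_orf_len(s, 30L)
    if (is.null(got)) expect_equal(want, 0L)
    else expect_equal(got$cds_length, want)
  }
})

make_family <- function(core, n_iso, id_prefix, seed_utr = 100) {
  ids <- sprintf("%s.%d", id_prefix, seq_len(n_iso))
  seqs <- vapply(seq_len(n_iso), function(i)
    paste0(guarded_utr5(sample(seed_utr:(2 * seed_utr), 1)), core,
           rseq(sample(seed_utr:(2 * seed_utr), 1))), character(1))
  list(ids = ids, seqs = seqs)
}

test_that("mutually dissimilar coding transcripts are singleton noclass", {
  set.seed(91)
  seqs <- vapply(1:5, function(i)
    paste0(rseq(60), metamerge:::rand_cds(50, 0.5), rseq(60)), character(1))
  gg <- consolidate_genes(assembly_set(seqs, sprintf("x%d", 1:5)))
  expect_equal(nrow(gg), 5L)
  expect_true(all(gg$category == "noclass"))
  expect_equal(length(unique(gg$gene_id)), 5L)
})

test_that("a CDS embedded in a longer UTR context is a high-identity alternate", {
  set.seed(97)
  core <- metamerge:::rand_cds(80, 0.5)
  full <- paste0(guarded_utr5(150), core, rseq(150))
  short <- paste0(guarded_utr5(42), core, rseq(40))
  gg <- consolidate_genes(assembly_set(c(full, short), c("long", "short")))
  expect_equal(length(unique(gg$gene_id)), 1L)
  expect_equal(gg$category[gg$transcript_id == "long"], "main")
  expect_equal(gg$category[gg$transcript_id == "short"], "althi")
})

test_that("planted gene families give one main plus high-identity alternates", {
  set.seed(101)
  fams <- lapply(1:5, function(f)
    make_family(metamerge:::rand_cds(100, 0.45), 3, sprintf("g%d", f)))
  ids <- unlist(lapply(fams, `[[`, "ids"))
  seqs <- unlist(lapply(fams, `[[`, "seqs"))
  a <- assembly_set(seqs, ids)
  gg <- consolidate_genes(a)
  expect_equal(length(unique(gg$gene_id)), 5L)
  tab <- table(gg$gene_id)
  expect_true(all(tab == 3))
  cats <- split(gg$category, gg$gene_id)
  for (ct in cats) expect_equal(sort(ct), c("althi", "althi", "main"))

  # partition property and permutation invariance of the grouping
  expect_setequal(gg$transcript_id, ids)
  expect_equal(anyDuplicated(gg$transcript_id), 0L)
  perm <- sample(length(a))
  gg_p <- consolidate_genes(a[perm])
  expect_equal(gg[order(gg$transcript_id), c("gene_id", "category")],
               gg_p[order(gg_p$transcript_id), c("gene_id", "category")],
               ignore_attr = TRUE)
})

test_that("noncoding transcripts become singleton groups and profiles drop them", {
  set.seed(103)
  coding <- paste0(rseq(50), metamerge:::rand_cds(60, 0.5), rseq(50))
  noncod <- "CACACACACACACACACACACACACACACACACACACACACACACACACA"
  a <- assembly_set(c(coding, noncod), c("cod", "non"))
  gg <- consolidate_genes(a)
  expect_equal(gg$category[gg$transcript_id == "non"], "noncoding")
  expect_false(gg$coding[gg$transcript_id == "non"])

  kept <- select_okay_set(gg, a)
  expect_identical(names(kept), names(a)) # default profile keeps everything
  kept2 <- select_okay_set(gg, a, drop = "noncoding")
  expect_identical(names(kept2), "cod")
  expect_error(select_okay_set(gg, a, drop = "mystery"), "unknown")
})

test_that("short-CDS members are classified as partial", {
  set.seed(107)
  core <- metamerge:::rand_cds(120, 0.5)          # 360 nt CDS
  part_core <- substr(core, 1, 180)               # truncated, no stop
  full <- paste0(guarded_utr5(81), core, rseq(80))
  partial <- paste0(guarded_utr5(21), part_core)
  gg <- consolidate_genes(assembly_set(c(full, partial), c("full", "p")))
  expect_equal(length(unique(gg$gene_id)), 1L)
  expect_equal(gg$category[gg$transcript_id == "p"], "part")
  expect_error(consolidate_genes(assembly_set("ATG", "x"), althi_min = 0.5,
                                 altmid_min = 0.9), "altmid_min")
})
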