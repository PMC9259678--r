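# quant.sf ingest, per-condition expression filter and mean-abundance filter

test_that("quant.sf ingest assembles the union matrix and validates format", {
  dir <- withr::local_tempdir()
  tpm <- matrix(c(10, 0, 3, 7), 2, 2,
                dimnames = list(c("t1", "t2"), c("s1", "s2")))
  paths <- write_quant_fixture(tpm, dir)
  q <- read_quant(paths)
  expect_equal(q$sample_ids, c("s1", "s2"))
  expect_equal(q$tpm, tpm, tolerance = 1e-9)

  # missing column
  bad <- file.path(dir, "bad.sf")
  writeLines(c("Name\tLength\tEffectiveLength\tNumReads", "t1\t5\t3\t2"), bad)
  expect_error(read_quant(bad, "sx"), "TPM")
  # non-numeric TPM names the line
  writeLines(c("Name\tLength\tEffectiveLength\tTPM\tNumReads",
               "t1\t5\t3\t1.5\t2", "t2\t5\t3\toops\t2"), bad)
  expect_error(read_quant(bad, "sx"), "line 3")
})

test_that("transcripts absent from one file get TPM 0 with a warning", {
  dir <- withr::local_tempdir()
  p1 <- write_quant_fixture(matrix(c(5, 2), 2, 1,
                                   dimnames = list(c("t1", "t2"), "s1")), dir)
  p2 <- write_quant_fixture(matrix(9, 1, 1, dimnames = list("t1", "s2")),
                            file.path(dir, "b"))
  expect_warning(q <- read_quant(c(p1, p2)), "absent")
  expect_equal(unname(q$tpm["t2", "s2"]), 0)
})

test_that("generated quantification fixtures round-trip through the reader", {
  p <- sim_params(seed = 3, n_genes = 25, contaminant_n = 5, n_samples = 6)
  tr <- simulate_transcriptome(p)
  dir <- withr::local_tempdir()
  qt <- simulate_quant(tr$manifest, p, dir = dir)
  q2 <- read_quant(qt$paths)
  expect_equal(q2$transcript_ids, tr$manifest$id)
  expect_equal(q2$tpm, qt$quant$tpm, tolerance = 1e-4)
})

test_that("condition level means equal naive per-group averaging", {
  set.seed(11)
  tpm <- matrix(runif(120, 0, 50), 20, 6,
                dimnames = list(sprintf("t%02d", 1:20), sprintf("s%d", 1:6)))
  q <- quant_table(tpm)
  d <- simple_design(sprintf("s%d", 1:6),
                     season = rep(c("summer", "winter"), each = 3))
  lm <- condition_level_means(q, d, "season")
  for (tid in rownames(tpm)) {
    expect_equal(lm[tid, "summer"], mean(tpm[tid, 1:3]))
    expect_equal(lm[tid, "winter"], mean(tpm[tid, 4:6]))
  }
  # single all-sample level and singleton levels
  d1 <- simple_design(sprintf("s%d", 1:6), batch = rep("all", 6))
  expect_equal(condition_level_means(q, d1, "batch")[, "all"], rowMeans(tpm))
  ds <- simple_design(sprintf("s%d", 1:6), rep = sprintf("r%d", 1:6))
  lms <- condition_level_means(q, ds, "rep")
  expect_equal(unname(lms), unname(tpm))

  expect_error(condition_level_means(q, d, "nope"), "unknown factor")
  d_missing <- simple_design(sprintf("s%d", 1:5), season = rep("x", 5))
  expect_error(condition_level_means(q, d_missing, "season"), "missing")
})

test_that("expression filter keeps any transcript reaching the floor in some level", {
  tpm <- matrix(0, 3, 4, dimnames = list(c("dead", "seasonal", "flat"),
                                         sprintf("s%d", 1:4)))
  tpm["seasonal", 1:2] <- c(1.2, 0.8) # summer mean exactly 1.0
  tpm["flat", ] <- 0.4
  q <- quant_table(tpm)
  d <- simple_design(sprintf("s%d", 1:4),
                     season = c("summer", "summer", "winter", "winter"))
  kept <- expression_filter(q, d)
  expect_true("seasonal" %in% kept)   # boundary inclusive ("at least 1 TPM")
  expect_false("dead" %in% kept)
  expect_false("flat" %in% kept)
})

test_that("expression filter equals the exhaustive (factor, level) oracle", {
  set.seed(23)
  tpm <- matrix(rlnorm(50 * 8, meanlog = -0.5, sdlog = 2), 50, 8,
                dimnames = list(sprintf("t%02d", 1:50), sprintf("s%d", 1:8)))
  q <- quant_table(tpm)
  d <- simple_design(sprintf("s%d", 1:8),
                     season = rep(c("su", "wi"), 4),
                     area = rep(c("a1", "a2"), each = 4),
                     sex = c("m", "m", "f", "f", "f", "m", "f", "m"))
  kept <- expression_filter(q, d)
  oracle_keep <- vapply(rownames(tpm), function(tid) {
    for (f in names(d$factors)) {
      lv <- d$factors[[f]]
      for (l in unique(lv)) {
        if (mean(tpm[tid, names(lv)[lv == l]]) >= 1) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  expect_identical(kept, rownames(tpm)[oracle_keep])

  # monotone in the threshold, idempotent, permutation-invariant
  kept2 <- expression_filter(q, d, filter_thresholds(condition_tpm_min = 2))
  expect_true(all(kept2 %in% kept))
  qk <- quant_table(tpm[kept, , drop = FALSE])
  expect_identical(expression_filter(qk, d), kept)
  perm <- sample(8)
  qp <- quant_table(tpm[, perm])
  expect_identical(sort(expression_filter(qp, d)), sort(kept))
})

test_that("mean-abundance filter discards strictly-below means only", {
  tpm <- matrix(c(0.1, 0.1, 0.1, 0.1,
                  0.0999, 0.0999, 0.0999, 0.0999,
                  5, 0, 0, 0), 3, 4, byrow = TRUE,
                dimnames = list(c("edge", "under", "ok"), sprintf("s%d", 1:4)))
  kept <- mean_abundance_filter(quant_table(tpm))
  expect_true("edge" %in% kept)    # mean exactly 0.1 survives
  expect_false("under" %in% kept)
  expect_true("ok" %in% kept)

  set.seed(31)
  tpm <- matrix(rlnorm(100 * 4, -2, 2), 100, 4,
                dimnames = list(sprintf("t%03d", 1:100), sprintf("s%d", 1:4)))
  kept <- mean_abundance_filter(quant_table(tpm))
  expect_identical(kept, rownames(tpm)[rowMeans(tpm) >= 0.1])
  qk <- quant_table(tpm[kept, , drop = FALSE])
  expect_identical(mean_abundance_filter(qk), kept)
})
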