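test_that("unknown species inherit predictions from their gap pattern", {
  # sp6 is unknown and duplicates sp1 (confident "yes"): same label
  fit <- gapnet(toy_alignment(), toy_labels(), grid = tiny_grid(),
                seed = 5, config = quick_config())
  pred <- predict_unknown(fit)
  expect_equal(pred$species, "sp6")
  expect_equal(pred$label,
               as.character(predict(fit, species = "sp1")[[1]]))

  # an all-gap unknown row where the "no" class lost the gene entirely
  aln <- new_alignment(
    paste0("t", 1:7),
    c("ACGTACGTAA", "ACGAACGTAT", "ACGCACGTAC",
      "----------", "---------A", "----------", "----------"))
  lab <- make_labels(paste0("t", 1:7),
                     c("yes", "yes", "yes", "no", "no", "no", "unknown"))
  fit2 <- gapnet(aln, lab, grid = tiny_grid(), seed = 6,
                 config = quick_config())
  expect_equal(as.character(predict(fit2)[["t7"]]), "no")
})

test_that("region scanning applies the candidate rule and survives failures", {
  reg_good <- block_region(n_species = 16, p = 60, block = 21:30, n_no = 7,
                           seed = 2)
  # a region with no variable columns must fail but not stop the scan
  aln_bad <- new_alignment(names(reg_good$labels),
                           rep("ACGT", length(reg_good$labels)),
                           region_id = "allsame")
  scan <- scan_regions(list(good = reg_good$alignment, bad = aln_bad),
                       reg_good$labels, grid = tiny_grid(),
                       config = quick_config(), seed = 4)
  expect_equal(nrow(scan), 2L)
  expect_false(scan$failed[scan$region_id == "good"])
  expect_true(scan$failed[scan$region_id == "bad"])
  expect_false(scan$candidate[scan$region_id == "bad"])
  good <- scan[scan$region_id == "good", ]
  expect_equal(good$candidate, good$min_cv_error <= 0.1)

  # candidate flag is a pure function of error and threshold
  scan_tight <- scan_regions(list(good = reg_good$alignment),
                             reg_good$labels, grid = tiny_grid(),
                             config = quick_config(), seed = 4,
                             threshold = -1)
  expect_false(any(scan_tight$candidate))

  # rule = "min" flags the minimum-error region
  scan_min <- scan_regions(list(good = reg_good$alignment, bad = aln_bad),
                           reg_good$labels, grid = tiny_grid(),
                           config = quick_config(), seed = 4, rule = "min")
  expect_equal(scan_min$candidate, !scan_min$failed)
})

test_that("scanning regions one at a time equals scanning them in a batch", {
  r1 <- block_region(n_species = 14, p = 50, block = 11:18, n_no = 6,
                     seed = 13)
  r2 <- block_region(n_species = 14, p = 50, block = 31:38, n_no = 6,
                     seed = 14)
  r2$alignment$species <- r1$alignment$species
  rownames(r2$alignment$seq) <- r1$alignment$species
  both <- scan_regions(list(a = r1$alignment, b = r2$alignment),
                       r1$labels, grid = tiny_grid(),
                       config = quick_config(), seed = 99)
  solo <- scan_regions(list(b = r2$alignment), r1$labels,
                       grid = tiny_grid(), config = quick_config(),
                       seed = 99)
  expect_equal(both$min_cv_error[both$region_id == "b"],
               solo$min_cv_error)
  expect_equal(both$L[both$region_id == "b"], solo$L)
})

test_that("benchmark metrics implement the TPR/FPR definitions", {
  mk_scan <- function(err, called) {
    df <- data.frame(region_id = paste0("r", seq_along(err)),
                     min_cv_error = err, candidate = called,
                     failed = FALSE)
    attr(df, "threshold") <- 0.1
    class(df) <- c("gapnet_scan", "data.frame")
    df
  }
  res <- mk_scan(rep(0.05, 4), rep(TRUE, 4))
  nul <- mk_scan(rep(0.4, 4), rep(FALSE, 4))
  m <- benchmark_metrics(res, truth = rep(TRUE, 4), null_results = nul)
  expect_equal(m$tpr, 1.0)
  expect_equal(m$fpr, 0.0)
  expect_equal(m$mean_cv_error, 0.05)

  # 183 of 200 associated regions called
  res2 <- mk_scan(rep(0.05, 200), c(rep(TRUE, 183), rep(FALSE, 17)))
  expect_equal(benchmark_metrics(res2, rep(TRUE, 200))$tpr, 0.915)

  expect_error(benchmark_metrics(res, truth = rep(FALSE, 4)),
               "TPR undefined")
})
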