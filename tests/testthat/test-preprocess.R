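test_that("acquisition QC applies an inclusive minimum-signal boundary", {
  lay <- toy_layout(n = 1, r = 1, n_neg = 1, n_pos = 1)
  scan_with_total <- function(total) {
    # one substrate spot carrying the whole signal, controls at zero
    toy_scan(lay, matrix(total, 1, 1), neg = 0, pos = 0)
  }
  expect_true(acquisition_qc(scan_with_total(1.2e6))$pass)
  expect_true(acquisition_qc(scan_with_total(1e6))$pass)    # boundary in
  qc <- acquisition_qc(scan_with_total(999999))
  expect_false(qc$pass)
  expect_match(qc$reason, "below minimum")
  # threshold is configurable
  expect_true(acquisition_qc(scan_with_total(10), min_total_hits = 10)$pass)
})

test_that("replicate QC flags the outlier replicate and keeps the substrate", {
  lay <- toy_layout(n = 3, r = 3)
  vals <- rbind(c(100, 102, 98),      # tight triplicate: CV ~ 0.016
                c(100, 100, 10000),   # gross outlier
                c(5, NA, NA))         # single surviving replicate
  sc <- replicate_qc(toy_scan(lay, vals), lay)
  qc <- sc$qc[order(sc$qc$substrate_id), ]

  expect_false(qc$high_cv[1])
  expect_equal(qc$n_surviving[1], 3)

  expect_true(qc$high_cv[2])
  expect_equal(qc$n_surviving[2], 2)   # outlier ejected, substrate retained
  flagged <- sc$spots[sc$spots$flagged, ]
  expect_equal(flagged$raw_intensity, 10000)

  expect_true(qc$dropout[3])           # < min_replicates survivors
  expect_false(qc$dropout[2])
})

test_that("replicate QC ejects at most one replicate per substrate", {
  lay <- toy_layout(n = 1, r = 3)
  # still wildly dispersed after one ejection: no second pass
  sc <- replicate_qc(toy_scan(lay, matrix(c(1, 1000, 1e6), 1)), lay)
  expect_equal(sum(sc$spots$flagged), 1)
  expect_equal(sc$qc$n_surviving, 2)
})

test_that("background correction subtracts the negative-control mean and clips", {
  lay <- toy_layout(n = 3, r = 1, n_neg = 2, n_pos = 1)
  sc <- toy_scan(lay, matrix(c(120, 30, 50), 3, 1), neg = 50, pos = 900)
  out <- background_correct(sc)
  got <- out$spots$raw_intensity[out$spots$control_type == "none"]
  expect_equal(sort(got), c(0, 0, 70))  # 120-50, 30-50 clipped, 50-50
  # controls untouched
  expect_equal(out$spots$raw_intensity[out$spots$control_type == "negative"],
               c(50, 50))
  # zero background is the identity
  sc0 <- toy_scan(lay, matrix(c(120, 30, 50), 3, 1), neg = 0, pos = 900)
  expect_equal(background_correct(sc0)$spots$raw_intensity[
    sc0$spots$control_type == "none"], c(120, 30, 50))

  no_neg <- toy_scan(toy_layout(n = 2, r = 1, n_neg = 0, n_pos = 1),
                     matrix(c(1, 2), 2, 1))
  expect_error(background_correct(no_neg), "negative-control")
})

test_that("triplicate summarization takes the median of survivors", {
  lay <- toy_layout(n = 3, r = 3)
  vals <- rbind(c(3, 5, 100), c(7, 7, 7), c(4, 6, NA))
  sc <- replicate_qc(toy_scan(lay, vals), lay, cv_threshold = Inf)
  prof <- summarize_triplicates(sc, lay)
  v <- unname(prof$values[order(names(prof$values))])
  expect_equal(v, c(5, 7, 5))  # median; two survivors -> mean
})

test_that("quantile normalization matches the brute-force oracle", {
  # worked two-array example
  x <- cbind(a = c(1, 2, 3), b = c(6, 4, 2))
  got <- quantile_normalize(x)
  expect_equal(unname(got[, 1]), c(1.5, 3, 4.5))
  expect_equal(unname(got[, 2]), c(4.5, 3, 1.5))

  # identical arrays are a fixed point
  y <- cbind(c(4, 1, 9), c(4, 1, 9))
  expect_equal(quantile_normalize(y), y, ignore_attr = TRUE)

  # ties share the mean of their tied reference values
  z <- cbind(c(1, 1, 2), c(3, 5, 7))
  gz <- quantile_normalize(z)
  expect_equal(unname(gz[, 1]), c(2.5, 2.5, 4.5))
  expect_equal(gz, oracle_quantile_normalize(z), ignore_attr = TRUE)

  # random matrices up to 50 x 8, including injected ties
  set.seed(42)
  for (i in 1:60) {
    n <- sample(2:50, 1); k <- sample(2:8, 1)
    m <- matrix(rlnorm(n * k, 5, 1), n, k)
    if (i %% 3 == 0 && n > 3) m[1:3, 1] <- m[1, 1]  # 3-way tie
    expect_equal(quantile_normalize(m), oracle_quantile_normalize(m),
                 tolerance = 1e-13, ignore_attr = TRUE)
  }

  expect_error(quantile_normalize(matrix(1:3, 3, 1)), ">= 2 arrays")
})

test_that("quantile normalization equalizes distributions and preserves ranks", {
  set.seed(7)
  m <- matrix(rlnorm(200 * 5, 6, 1), 200, 5)
  got <- quantile_normalize(m)
  sorted <- apply(got, 2, sort)
  for (j in 2:5) expect_equal(sorted[, j], sorted[, 1], tolerance = 1e-9)
  for (j in 1:5) expect_equal(order(got[, j]), order(m[, j]))
})

test_that("quantile normalization agrees with limma on tie-free complete data", {
  skip_if_not_installed("limma")
  set.seed(11)
  m <- matrix(rlnorm(40 * 4, 5, 1), 40, 4)
  expect_equal(quantile_normalize(m), limma::normalizeQuantiles(m),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("missing values are imputed on the reference and flagged", {
  set.seed(3)
  m <- matrix(rlnorm(30 * 4, 5, 1), 30, 4)
  m[5, 2] <- NA
  got <- quantile_normalize(m)
  expect_true(attr(got, "imputed")[5, 2])
  expect_equal(sum(attr(got, "imputed")), 1)
  expect_false(is.na(got[5, 2]))
  # imputed value sits near the substrate's level in the other arrays
  expect_gt(got[5, 2], min(got[5, -2]) * 0.5)
  expect_lt(got[5, 2], max(got[5, -2]) * 2)
})

test_that("preprocess_scans excludes failing arrays and returns a normalized matrix", {
  lay <- toy_layout(n = 40, r = 3)
  anno <- generate_annotation(40, 5, 3, seed = 1)
  tr <- synthetic_truth("K001", boost = 2, seed = 9)
  scans <- simulate_arrays(lay, anno$substrates, tr, 3)
  # shrink one scan's signal far below threshold
  scans[[2]]$spots$raw_intensity <- scans[[2]]$spots$raw_intensity * 1e-6
  scans[[2]]$total_hits <- sum(scans[[2]]$spots$raw_intensity)

  expect_message(pp <- preprocess_scans(scans, lay, min_total_hits = 1e3),
                 "excluding array")
  expect_equal(pp$excluded, scans[[2]]$sample_id)
  expect_equal(ncol(pp$matrix), 2)
  expect_equal(nrow(pp$matrix), 40)
  sorted <- apply(pp$matrix, 2, sort)
  expect_equal(sorted[, 1], sorted[, 2], tolerance = 1e-9)

  # both normalization orders run and give same-shaped output
  pp2 <- preprocess_scans(simulate_arrays(lay, anno$substrates, tr, 3), lay,
                          min_total_hits = 0,
                          normalize = "before_summarize")
  expect_equal(dim(pp2$matrix), c(40, 3))
})
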