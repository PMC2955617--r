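test_that("generate_annotation honours counts, tags and determinism", {
  a <- generate_annotation(1024, 120, 8, 0.2, 0.27, seed = 1)
  expect_equal(nrow(a$kinases), 120)
  cc <- sum(vapply(a$kinases$category_list,
                   function(x) "cell_cycle" %in% x, logical(1)))
  expect_equal(cc / 120, 0.27, tolerance = 0.02)
  # every kinase has at least one substrate
  expect_setequal(a$substrates$kinases, a$kinases$kinase_id)

  b <- generate_annotation(1024, 120, 8, 0.2, 0.27, seed = 1)
  expect_identical(a$substrates, b$substrates)
  expect_identical(a$pathways, b$pathways)

  c2 <- generate_annotation(1024, 120, 8, 0.2, 0.27, seed = 2)
  expect_false(identical(a$substrates, c2$substrates))
})

test_that("multi_map_rate = 0 yields a one-to-at-most-one substrate map", {
  a <- generate_annotation(200, 20, 5, multi_map_rate = 0, seed = 3)
  expect_true(all(lengths(a$substrates$map) == 1))
})

test_that("infeasible annotation parameters raise a parameter error", {
  expect_error(generate_annotation(50, 20, 8, multi_map_rate = 0, seed = 1),
               "infeasible")
  expect_error(generate_annotation(10, 20, 1, seed = 1), "n_substrates")
})

test_that("planted pathway covers exactly the chosen kinases", {
  a <- generate_annotation(200, 20, 5, seed = 4,
                           planted_kinases = c("K001", "K007"))
  expect_setequal(a$pathways$sets$PW_planted, c("K001", "K007"))
})

test_that("simulated arrays are deterministic, nonnegative, and account total_hits", {
  lay <- toy_layout(n = 30, r = 3)
  anno <- generate_annotation(30, 5, 3, seed = 1)
  tr <- synthetic_truth(c("K001", "K002"), boost = 3, seed = 11,
                        dropout_rate = 0.05)
  s1 <- simulate_arrays(lay, anno$substrates, tr, 2)
  s2 <- simulate_arrays(lay, anno$substrates, tr, 2)
  expect_identical(s1[[1]]$spots, s2[[1]]$spots)
  expect_identical(s1[[2]]$spots, s2[[2]]$spots)
  for (s in s1) {
    expect_true(all(s$spots$raw_intensity >= 0))
    expect_equal(s$total_hits, sum(s$spots$raw_intensity))
  }
  # dropout removes some spots
  expect_lt(nrow(s1[[1]]$spots), nrow(lay$spots))
})

test_that("controls sit at the extremes of the background distribution", {
  lay <- toy_layout(n = 50, r = 3, n_neg = 4, n_pos = 4)
  anno <- generate_annotation(50, 5, 3, seed = 1)
  tr <- synthetic_truth("K001", boost = 1, replicate_cv = 0,
                        dropout_rate = 0, seed = 5)
  sc <- simulate_arrays(lay, anno$substrates, tr, 1)[[1]]
  neg <- sc$spots$raw_intensity[sc$spots$control_type == "negative"]
  pos <- sc$spots$raw_intensity[sc$spots$control_type == "positive"]
  subs <- sc$spots$raw_intensity[sc$spots$control_type == "none"]
  expect_lt(max(neg), quantile(subs, 0.05))
  expect_gt(min(pos), quantile(subs, 0.95))
})

test_that("boosted substrates separate from background at boost 3 and not at boost 1", {
  lay <- toy_layout(n = 100, r = 3)
  anno <- generate_annotation(100, 10, 5, multi_map_rate = 0, seed = 2)
  active <- c("K001", "K002")
  active_subs <- names(anno$substrates$map)[
    vapply(anno$substrates$map, function(k) any(k %in% active), logical(1))]

  # boost 3, no dropout: active mean exceeds background mean in every sample
  tr3 <- synthetic_truth(active, boost = 3, replicate_cv = 0.1,
                         dropout_rate = 0, seed = 21)
  for (sc in simulate_arrays(lay, anno$substrates, tr3, 4)) {
    sp <- sc$spots[sc$spots$control_type == "none", ]
    on <- sp$substrate_id %in% active_subs
    expect_gt(mean(sp$raw_intensity[on]), mean(sp$raw_intensity[!on]))
  }

  # boost 1 (null): active and inactive substrates exchangeable in
  # distribution -- the two-sample t rejects at roughly its nominal rate
  pvals <- vapply(1:100, function(s) {
    tr1 <- synthetic_truth(active, boost = 1, replicate_cv = 0.1,
                           dropout_rate = 0, seed = 1000 + s)
    sc <- simulate_arrays(lay, anno$substrates, tr1, 1)[[1]]
    sp <- sc$spots[sc$spots$control_type == "none", ]
    # replicate spots of one substrate are correlated by design, so test
    # on the per-substrate means
    lev <- tapply(sp$raw_intensity, sp$substrate_id, mean)
    on <- names(lev) %in% active_subs
    t.test(lev[on], lev[!on])$p.value
  }, numeric(1))
  expect_lt(mean(pvals < 0.05), 0.12)
  expect_gt(mean(pvals < 0.5), 0.3)
})

test_that("increasing boost never degrades expected planted rank", {
  lay <- toy_layout(n = 100, r = 3)
  anno <- generate_annotation(100, 10, 5, seed = 2)
  planted <- c("K003", "K004")
  mean_rank <- function(boost) {
    ranks <- vapply(1:8, function(s) {
      tr <- synthetic_truth(planted, boost = boost, seed = 3000 + s)
      scans <- simulate_arrays(lay, anno$substrates, tr, 3)
      pp <- preprocess_scans(scans, lay, min_total_hits = 0)
      avg <- group_average(pp$matrix)
      act <- score_kinases(select_top_substrates(avg, 20), avg,
                           anno$substrates)
      rk <- match(planted, act$kinase_id)
      rk[is.na(rk)] <- nrow(act) + 1L  # absent from the list: worst rank
      mean(rk)
    }, numeric(1))
    mean(ranks)
  }
  r1 <- mean_rank(1); r2 <- mean_rank(2.5); r3 <- mean_rank(5)
  expect_lte(r2, r1)
  expect_lte(r3, r2)
})

test_that("simulated viability tables follow the 4PL truth", {
  # exact midpoint identity with no noise
  tr <- viability_truth(lower = 0, upper = 1, ec50 = 100, hill = 1,
                        noise_sd = 0, seed = 1)
  tab <- simulate_viability(c(10, 50, 100, 500), tr, n_replicates = 2)
  dr <- normalize_plate(tab)
  expect_equal(dr$viability$viability[dr$viability$dose == 100],
               c(0.5, 0.5))

  # floor lower = 0.60: saturating dose plateaus near 40% decrease
  tr6 <- viability_truth(lower = 0.60, upper = 1, ec50 = 100, hill = 1,
                         noise_sd = 0, seed = 1)
  tab6 <- simulate_viability(c(10, 100, 1e4, 1e6), tr6, n_replicates = 2)
  dr6 <- normalize_plate(tab6)
  expect_equal(min(dr6$viability$viability), 0.60, tolerance = 0.01)

  # quadruplicate design: 4 rows per dose
  tab4 <- simulate_viability(default_dose_grid("dasatinib")$doses,
                             viability_truth(seed = 2), n_replicates = 4)
  treated <- tab4[tab4$role == "treated", ]
  expect_true(all(table(treated$dose) == 4))
  # blank and vehicle wells present so normalization is exercised
  expect_true(all(c("blank", "vehicle") %in% tab4$role))

  expect_error(simulate_viability(c(-1, 10), viability_truth(seed = 1)),
               "positive")
})

test_that("truth constructors validate their invariants", {
  expect_error(synthetic_truth("K1", boost = 0.5), "boost")
  expect_error(synthetic_truth("K1", dropout_rate = 1.5), "dropout")
  expect_error(viability_truth(lower = 0.8, upper = 0.5), "lower")
  expect_error(viability_truth(ec50 = -1), "ec50")
  expect_error(viability_truth(hill = 0), "hill")
})
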