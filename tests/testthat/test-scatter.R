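test_that("correction factor is the log-ratio of ROI means", {
  Tm <- matrix(1, 6, 6)
  f <- matrix(FALSE, 6, 6); f[1:3, ] <- TRUE
  # identical ROI values -> c = 0
  expect_equal(estimate_correction(Tm, f, !f), 0)
  # mean ratio 1.0202 -> c = 0.0200 (direct logarithm oracle)
  Tm[f] <- 1.0202
  expect_equal(estimate_correction(Tm, f, !f), log(1.0202))
  expect_equal(round(estimate_correction(Tm, f, !f), 4), 0.02)
  # error paths
  expect_error(estimate_correction(Tm, matrix(FALSE, 6, 6), !f), "empty")
  Tm[f] <- -1
  expect_error(estimate_correction(Tm, f, !f), "non-positive")
})

test_that("correction estimate recovers the simulated container offset", {
  p <- small_params()
  cs <- sapply(1:2, function(pj) {
    tr <- make_lung_phantom(p, "C1", pj)
    fp <- forward_project(tr, p)
    tri <- normalize_to_water(retrieve_signals(fp$sample, fp$reference),
                              tr$water_roi)
    estimate_correction(tri$T_map, tr$formalin_roi, tr$water_roi,
                        tri$valid_mask)
  })
  expect_equal(mean(cs), 0.02, tolerance = 0.1)  # +- 0.002 absolute
  expect_lt(abs(mean(cs) - 0.02), 0.002)
})

test_that("normalized scatter reproduces the worked group values", {
  # emphysema group medians: S(T = 1.11, V = 0.66, c = 0.02) ~ 4.93
  r <- normalized_scatter(1.11, 0.66, 0.02, TRUE)
  expect_equal(r$S, -log(0.66) / (log(1.11) - 0.02), tolerance = 1e-12)
  expect_equal(round(r$S, 1), 4.9)
  # control side: 10.86
  r2 <- normalized_scatter(1.06, 0.66, 0.02, TRUE)
  expect_equal(round(r2$S, 2), 10.86)
  # no scatter: V = 1 -> S = 0
  expect_equal(normalized_scatter(1.11, 1, 0.02, TRUE)$S, 0)
})

test_that("S is invariant under thickness doubling (T,V) -> (T^2, V^2)", {
  set.seed(3)
  Tv <- matrix(runif(400, 1.02, 1.3), 20)
  Vv <- matrix(runif(400, 0.3, 0.95), 20)
  m <- matrix(TRUE, 20, 20)
  s1 <- normalized_scatter(Tv, Vv, 0, m)
  s2 <- normalized_scatter(Tv^2, Vv^2, 0, m)
  expect_equal(s1$S, s2$S, tolerance = 1e-12)
})

test_that("undefined pixels are floored out and counted", {
  Tv <- matrix(c(1.1, exp(0.02), 1.1, 0.9), 2)
  Vv <- matrix(0.7, 2, 2)
  r <- normalized_scatter(Tv, Vv, 0.02, matrix(TRUE, 2, 2))
  expect_equal(sum(r$defined_mask), 2)
  expect_equal(r$n_undefined, 2)
  expect_true(all(is.finite(r$S)))
  expect_true(all(r$S >= 0))
})

test_that("group summaries: levels, counts, quartile ordering, null p", {
  p <- small_params(n_projections = 3)
  mk <- function(id, pj) {
    tr <- make_lung_phantom(p, id, pj)
    fp <- forward_project(tr, p)
    tri <- normalize_to_water(retrieve_signals(fp$sample, fp$reference),
                              tr$water_roi)
    normalized_scatter(tri$T_map, tri$V_map, 0.02,
                       tr$lung_mask & tri$valid_mask,
                       specimen_id = id, projection_index = pj,
                       group_label = specimen_group(id))
  }
  res <- c(lapply(1:3, function(j) mk("E1", j)),
           lapply(1:3, function(j) mk("C1", j)))
  px <- summarize_groups(res, "per_pixel")
  expect_equal(nrow(px), 6)
  expect_true(all(px$q1 <= px$median & px$median <= px$q3))
  expect_true(all(px$p_value > 0 & px$p_value <= 1))
  # S separates the groups, V does not
  med <- function(par, grp)
    px$median[px$parameter == par & px$group == grp]
  expect_lt(med("S", "emphysema"), med("S", "control"))
  expect_lt(px$p_value[px$parameter == "S"][1], 1e-10)

  ind <- summarize_groups(res, "per_individual")
  expect_true(all(ind$n == 1))  # one specimen per group here

  # two identical groups -> p ~ 1
  res_null <- res
  for (k in 4:6) {
    res_null[[k]] <- res[[k - 3]]
    res_null[[k]]$group_label <- "control"
    res_null[[k]]$specimen_id <- "C1"
  }
  pn <- summarize_groups(res_null, "per_pixel")
  expect_gt(min(pn$p_value), 0.95)
})

test_that("per-individual level counts one value per specimen", {
  p <- phantom_params(image_height = 48, image_width = 48,
                      n_projections = 2, n_per_group = 3)
  res <- list()
  for (id in cohort_specimens(p)) for (pj in 1:2) {
    tr <- make_lung_phantom(p, id, pj)
    sig <- true_signal_maps(tr, p)
    res[[paste(id, pj)]] <- normalized_scatter(
      sig$T_map, sig$V_map, p$container_log_offset, tr$lung_mask,
      specimen_id = id, projection_index = pj,
      group_label = specimen_group(id))
  }
  ind <- summarize_groups(res, "per_individual")
  expect_true(all(ind$n == 3))
})
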