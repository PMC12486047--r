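test_that("generated surfaces have exact constructed thickness and mirrored hemispheres", {
  s <- generate_surface(fold_amplitude = 0, lateral_slope = 0,
                        thickness = 2.5)
  for (h in s$hemispheres) {
    d <- sqrt(rowSums((h$pial - h$white)^2))
    expect_equal(d, rep(2.5, length(d)), tolerance = 1e-12)
  }
  # folded sheets: offset along the analytic normal keeps the distance exact
  s2 <- generate_surface(thickness = 3.1)
  d2 <- sqrt(rowSums((s2$hemispheres$R$pial - s2$hemispheres$R$white)^2))
  expect_equal(d2, rep(3.1, length(d2)), tolerance = 1e-9)
  # mirrored about the midline plane
  expect_equal(s$hemispheres$L$pial[, "x"], -s$hemispheres$R$pial[, "x"])
  expect_equal(s$hemispheres$L$pial[, c("y", "z")],
               s$hemispheres$R$pial[, c("y", "z")])
})

test_that("ROI labels are assigned by half-open rostro-caudal band", {
  bands <- list(SMA = c(45, 70), M1 = c(20, 45), S1 = c(0, 20),
                CAUDAL = c(-40, 0))
  s <- generate_surface(bands = bands)
  for (h in s$hemispheres) {
    y <- h$pial[, "y"]
    # oracle: direct comparison against the declared half-open intervals
    expect_identical(h$labels == "M1", y >= 20 & y < 45)
    expect_identical(h$labels == "SMA", y >= 45 & y < 70)
    expect_identical(h$labels == "CAUDAL", y >= -40 & y < 0)
  }
})

test_that("surface generation rejects bad parameters", {
  expect_error(generate_surface(thickness = 0), "thickness")
  expect_error(generate_surface(thickness = -1), "thickness")
  bad <- list(SMA = c(30, 70), M1 = c(20, 45), S1 = c(0, 20),
              CAUDAL = c(-40, 0))
  expect_error(generate_surface(bands = bad), "overlap|ordered")
})

test_that("generators are deterministic given the seed", {
  a <- generate_surface(seed = 7)
  b <- generate_surface(seed = 7)
  expect_identical(a, b)
  s <- a
  va <- generate_vessel_and_stent(s, seed = 3)
  vb <- generate_vessel_and_stent(s, seed = 3)
  expect_identical(va, vb)
  expect_false(identical(generate_vessel_and_stent(s, seed = 4)$stent,
                         va$stent))
  sch <- tiny_schedule()
  expect_identical(generate_recording(sch, n_channels = 2, fs = 500, seed = 5),
                   generate_recording(sch, n_channels = 2, fs = 500, seed = 5))
  expect_identical(generate_slice_profile(50, 25, seed = 9),
                   generate_slice_profile(50, 25, seed = 9))
  expect_identical(generate_cohort(3, seed = 11, light = TRUE),
                   generate_cohort(3, seed = 11, light = TRUE))
})

test_that("stent segmentation lies on the lumen wall over the requested span", {
  s <- generate_surface(fold_amplitude = 0)
  vs <- generate_vessel_and_stent(s, lumen_radius = 3.55, stent_length = 40,
                                  rostral_tip = 60, seed = 2)
  expect_equal(range(vs$stent[, "y"]), c(20, 60))
  # straight profile: wall points sit exactly at the lumen radius
  d <- sqrt(vs$stent[, "x"]^2 + (vs$stent[, "z"] -
                                   vs$vessel$centerline[1, "z"])^2)
  expect_equal(unname(d), rep(3.55, nrow(vs$stent)), tolerance = 1e-9)
  # straight dorsal profile gives a collinear centerline
  cl <- vs$vessel$centerline
  expect_lt(max(abs(cl[, "z"] - cl[1, "z"])), 1e-12)
  expect_lt(max(abs(cl[, "x"])), 1e-12)
  expect_error(
    generate_vessel_and_stent(s, rostral_tip = 69, stent_length = 200),
    "outside"
  )
})

test_that("planted burst counts follow the requested Poisson process", {
  sch <- motor_test_schedule() # ten 10-s MOVE epochs
  counts <- vapply(1:4, function(seed) {
    rec <- generate_recording(sch, n_channels = 1, n_active = 1, fs = 500,
                              move_burst_rate = 3, rest_burst_rate = 0,
                              seed = seed)
    length(rec$burst_truth[[1]])
  }, numeric(1))
  # 3 /s over 100 s of MOVE: ~300, within 3 Poisson SDs
  expect_true(all(abs(counts - 300) < 3 * sqrt(300)))

  rec <- generate_recording(sch, n_channels = 16, n_active = 9, fs = 500,
                            seed = 1)
  planted <- vapply(rec$burst_truth, length, numeric(1))
  expect_identical(sum(planted[10:16] > 0), 0L)
  expect_true(all(planted[1:9] > 0))
})

test_that("equal move and rest rates give zero expected rate contrast", {
  sch <- tiny_schedule()
  diffs <- vapply(1:20, function(seed) {
    rec <- generate_recording(sch, n_channels = 1, fs = 500,
                              move_burst_rate = 2, rest_burst_rate = 2,
                              seed = seed)
    on <- rec$burst_truth[[1]]
    mv <- sch$label == "MOVE"
    cnt <- vapply(seq_len(nrow(sch)), function(e)
      sum(on >= sch$start[e] & on < sch$end[e]), numeric(1))
    mean(cnt[mv]) - mean(cnt[!mv])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 1e-9)
})

test_that("recording errors are raised for invalid configurations", {
  sch <- tiny_schedule()
  expect_error(generate_recording(sch, n_channels = 4, n_active = 5),
               "n_active")
  expect_error(generate_recording(sch, move_burst_rate = -1), "rates")
  expect_error(recording(matrix(0, 100, 2), fs = 300), "400")
})

test_that("move epochs carry more high-gamma power than rest when rates differ", {
  sch <- tiny_schedule()
  wins <- vapply(1:20, function(seed) {
    rec <- tiny_recording(seed, move_rate = 3, rest_rate = 0.5,
                          n_channels = 2)
    filt <- bandpass_highgamma(rec)
    rmask <- rest_mask_from_schedule(sch, rec$fs, nrow(rec$signal))
    mmask <- !rmask
    var(filt$signal[mmask, 1]) > var(filt$signal[rmask, 1])
  }, logical(1))
  expect_lt(binom.test(sum(wins), length(wins), p = 0.5,
                       alternative = "greater")$p.value, 0.01)
})

test_that("slice profiles are symmetric, respect the spread limit and reject bad input", {
  p <- generate_slice_profile(41, 20, spread = 5, noise_sd = 0, seed = 1)
  expect_equal(p$activity, rev(p$activity))
  expect_equal(which.max(p$activity) - 1L, 20L)
  d <- generate_slice_profile(41, 20, spread = 0, noise_sd = 0, seed = 1)
  expect_equal(sum(d$activity > 0), 1L)
  expect_equal(which(d$activity > 0) - 1L, 20L)
  expect_true(all(generate_slice_profile(50, 10, noise_sd = 2,
                                         seed = 2)$activity >= 0))
  expect_error(generate_slice_profile(41, 20, spread = -1), "spread")
  expect_error(generate_slice_profile(41, 50), "peak_slice")
})

test_that("planted strengths follow the configured overlap relation", {
  # zero slope, zero noise: constant strengths
  co <- generate_cohort(5, relation = list(intercept = 1.3, slope = 0,
                                           noise_sd = 0),
                        seed = 3, light = TRUE)
  expect_equal(co$cohort$planted_strength, rep(1.3, 5))
  # positive slope, zero noise: strengths ordered with overlap
  co2 <- generate_cohort(8, relation = list(intercept = 0, slope = 0.02,
                                            noise_sd = 0),
                         seed = 4, light = TRUE)
  ord <- order(co2$cohort$planted_overlap_pct)
  expect_true(all(diff(co2$cohort$planted_strength[ord]) >= 0))
  expect_error(generate_cohort(2), "participants")
  expect_error(generate_cohort(5, factor_config = list(tip_range = c(40, 40))),
               "degenerate")
})

test_that("large-cohort overlap-strength correlation matches a direct simulation oracle", {
  rel <- list(intercept = 0.2, slope = 0.02, noise_sd = 0.3)
  co <- generate_cohort(200, relation = rel, seed = 5, light = TRUE)
  rho_gen <- cor(co$cohort$planted_overlap_pct, co$cohort$planted_strength,
                 method = "spearman")
  # independent large-sample oracle of the same generative model
  # (placement uniform over the tip range, participant-specific M1 band)
  set.seed(42)
  fc <- cohort_config()
  nn <- 20000
  tip <- runif(nn, fc$tip_range[1], fc$tip_range[2])
  ctr <- mean(fc$bands$M1) + runif(nn, -fc$m1_center_jitter,
                                   fc$m1_center_jitter)
  wid <- runif(nn, fc$m1_width_range[1], fc$m1_width_range[2])
  lo <- ctr - wid / 2; hi <- ctr + wid / 2
  ov <- 100 * pmax(0, pmin(tip, hi) - pmax(tip - fc$stent_length, lo)) /
    fc$stent_length
  st <- rel$intercept + rel$slope * ov + rnorm(nn, 0, rel$noise_sd)
  rho_oracle <- cor(ov, st, method = "spearman")
  expect_lt(abs(rho_gen - rho_oracle), 0.1)
})

test_that("generated geometry satisfies the type invariants across random configs", {
  set.seed(123)
  for (i in 1:100) {
    sp <- runif(1, 1.5, 3)
    s <- generate_surface(spacing = sp,
                          fold_amplitude = runif(1, 0, 3),
                          thickness = runif(1, 1.5, 3.5),
                          seed = i)
    for (h in s$hemispheres) {
      expect_equal(nrow(h$pial), nrow(h$white))
      expect_true(all(is.finite(h$pial)) && all(is.finite(h$white)))
      expect_true(all(h$labels %in% c("SMA", "M1", "S1", "CAUDAL", "OTHER")))
      expect_true(max(h$triangles) <= nrow(h$pial) && min(h$triangles) >= 1)
    }
    vs <- generate_vessel_and_stent(
      s, lumen_radius = runif(1, 2.5, 4.5),
      rostral_tip = runif(1, 30, 65), clearance = runif(1, 3, 7),
      n_stent_points = 40, seed = i
    )
    # nearest discrete centerline sample is up to half a step from the
    # interpolated centre the wall points were built around
    d <- nearest_vertex_distance(vs$stent, vs$vessel$centerline)
    expect_true(all(d <= max(vs$vessel$radius) + 0.05))
    expect_true(all(diff(vs$vessel$centerline[, 2]) < 0))
  }
})
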