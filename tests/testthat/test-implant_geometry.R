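test_that("stent line fitting follows the centerline for the device length", {
  v <- straight_vessel(80, 0)
  seg <- matrix(c(0, 60, 0), 1, dimnames = list(NULL, c("x", "y", "z")))
  line <- fit_stent_line(seg, v, length = 25)
  expect_equal(range(line$points[, "y"]), c(35, 60))
  expect_equal(line$arc_length, 25, tolerance = 0.1)
  expect_equal(unname(line$tip["y"]), 60, tolerance = 0.26)

  # circular-arc centerline, radius 100: arc length against quadrature
  th <- seq(0.6, 0, by = -0.002)
  cl <- cbind(x = 0, y = 100 * sin(th), z = 100 * (1 - cos(th)))
  va <- vessel_model(cl, 3)
  seg2 <- matrix(c(0, 100 * sin(0.55), 0), 1)
  la <- fit_stent_line(seg2, va, length = 25)
  expect_equal(la$arc_length, 25, tolerance = 0.1)
  # oracle: a radius-100 arc of length 25 subtends 0.25 rad
  chord <- sqrt(sum((la$points[nrow(la$points), ] - la$points[1, ])^2))
  expect_equal(chord, 2 * 100 * sin(0.25 / 2), tolerance = 0.1)

  expect_error(fit_stent_line(matrix(c(0, 10, 0), 1), v, length = 25),
               "exhausted")
  expect_error(fit_stent_line(seg[0, , drop = FALSE], v), "empty")
})

test_that("stent-to-cortex distances match analytic scenes", {
  # cylindrical sheet of radius 6 around the line axis
  th <- seq(0, pi, length.out = 60)
  ys <- seq(30, 55, by = 1)
  g <- expand.grid(th = th, y = ys)
  right <- g$th <= pi / 2
  cyl <- cbind(x = 6 * cos(g$th), y = g$y, z = 6 * sin(g$th))
  s_cyl <- manual_surface(pial_L = cyl[!right, ], pial_R = cyl[right, ],
                          labels_L = rep("M1", sum(!right)),
                          labels_R = rep("M1", sum(right)))
  line <- straight_line(35, 50)
  d <- stent_to_cortex(line, s_cyl)
  expect_equal(d$mean, 6, tolerance = 0.05)
  expect_equal(d$min, 6, tolerance = 0.05)

  # flat sheets at lateral distances 4 and 8
  gz <- expand.grid(y = seq(30, 55, 0.5), z = seq(-6, 6, 0.5))
  s_fl <- manual_surface(
    pial_L = cbind(x = -8, y = gz$y, z = gz$z),
    pial_R = cbind(x = 4, y = gz$y, z = gz$z)
  )
  d2 <- stent_to_cortex(straight_line(35, 50), s_fl)
  expect_equal(d2$mean, 6, tolerance = 1e-9)
  expect_equal(d2$min, 4, tolerance = 1e-9)
  expect_true(d2$min <= d2$mean)
  expect_error(stent_to_cortex(line, s_cyl, roi = "S1"), "absent")
})

test_that("nearest-vertex distances equal an exhaustive all-pairs scan", {
  set.seed(77)
  verts_L <- cbind(x = runif(250, -30, -2), y = runif(250, 0, 70),
                   z = runif(250, 20, 45))
  verts_R <- cbind(x = runif(250, 2, 30), y = runif(250, 0, 70),
                   z = runif(250, 20, 45))
  s <- manual_surface(verts_L, verts_R)
  line <- straight_line(30, 55, z = 48)
  d <- stent_to_cortex(line, s)
  # brute-force double loop oracle
  brute <- sapply(list(verts_L, verts_R), function(v) {
    apply(line$points, 1, function(p)
      min(apply(v, 1, function(q) sqrt(sum((p - q)^2)))))
  })
  expect_equal(d$mean, mean(rowMeans(brute)), tolerance = 1e-12)
  expect_equal(d$min, min(brute), tolerance = 1e-12)
})

test_that("rostro-caudal ROI overlap matches interval arithmetic", {
  s <- generate_surface(bands = list(SMA = c(50, 70), M1 = c(10, 50),
                                     S1 = c(0, 10), CAUDAL = c(-40, 0)))
  ov <- roi_overlap(straight_line(20, 45, z = 45), s)
  expect_equal(unname(ov["M1"]), 100)

  s2 <- generate_surface(bands = list(SMA = c(55, 70), M1 = c(30, 55),
                                      S1 = c(10, 30), CAUDAL = c(-40, 10)))
  ov2 <- roi_overlap(straight_line(20, 45, z = 45), s2)
  expect_equal(unname(ov2["M1"]), 60) # 15 of 25 mm
  expect_equal(unname(ov2["S1"]), 40)
  expect_equal(unname(ov2["SMA"]), 0) # disjoint
  expect_equal(sum(ov2), 100, tolerance = 0.1)

  # exhaustive disjoint bands: percentages sum to 100
  s3 <- generate_surface()
  ov3 <- roi_overlap(straight_line(12, 37, z = 45), s3)
  expect_equal(sum(ov3), 100, tolerance = 0.1)
})

test_that("sinus width averages the lumen diameter along the line", {
  line <- straight_line(35, 60)
  expect_equal(sinus_width(straight_vessel(radius = 3.55), line), 7.1)
  # linearly varying radius: mean of the diameter endpoints
  ys <- seq(80, 0, by = -0.5)
  v_lin <- vessel_model(cbind(x = 0, y = ys, z = 0),
                        3 + (ys - 35) / 25 * 1 * (ys >= 35 & ys <= 60) +
                          1 * (ys > 60))
  expect_equal(sinus_width(v_lin, line), 7.0, tolerance = 0.02)
  # piecewise radii against a trapezoid-rule oracle
  set.seed(3)
  rad <- runif(length(ys), 2.5, 4.5)
  v_pw <- vessel_model(cbind(x = 0, y = ys, z = 0), rad)
  w <- sinus_width(v_pw, line)
  yy <- line$points[, "y"]
  rr <- approx(ys, rad, xout = yy)$y
  trap <- sum((2 * rr[-1] + 2 * rr[-length(rr)]) / 2 *
                abs(diff(yy))) / (max(yy) - min(yy))
  expect_lt(abs(w / trap - 1), 0.01)
})

test_that("cortical thickness recovers constructed pial-white offsets", {
  expect_equal(cortical_thickness(generate_surface(thickness = 2.5,
                                                   fold_amplitude = 0),
                                  "M1"), 2.5)
  flat <- generate_surface(thickness = 1, fold_amplitude = 0,
                           lateral_slope = 0)
  ident <- flat
  for (h in names(ident$hemispheres))
    ident$hemispheres[[h]]$white <- ident$hemispheres[[h]]$pial
  expect_equal(cortical_thickness(ident, "M1"), 0)
  # planted per-vertex offsets recovered exactly
  set.seed(9)
  planted <- flat
  offs <- list()
  for (h in names(planted$hemispheres)) {
    nh <- nrow(planted$hemispheres[[h]]$pial)
    o <- runif(nh, 1, 4)
    offs[[h]] <- o
    planted$hemispheres[[h]]$white <-
      planted$hemispheres[[h]]$pial - cbind(0, 0, o)
  }
  keep <- lapply(planted$hemispheres, function(h) h$labels == "M1")
  expect_equal(cortical_thickness(planted, "M1"),
               mean(c(offs$L[keep$L], offs$R[keep$R])))
  broken <- flat
  broken$hemispheres$L$white <- broken$hemispheres$L$white[-1, ]
  expect_error(cortical_thickness(broken, "M1"), "unpaired")
})

test_that("geometric summaries are invariant under rigid translation", {
  set.seed(15)
  s <- generate_surface(seed = 2)
  vs <- generate_vessel_and_stent(s, rostral_tip = 55, seed = 2)
  line <- fit_stent_line(vs$stent, vs$vessel)
  base <- list(d = stent_to_cortex(line, s), ov = roi_overlap(line, s),
               w = sinus_width(vs$vessel, line),
               th = cortical_thickness(s, "M1"))
  for (i in 1:5) {
    shift <- rnorm(3, 0, 20)
    s2 <- s
    for (h in names(s2$hemispheres)) {
      s2$hemispheres[[h]]$pial <-
        sweep(s2$hemispheres[[h]]$pial, 2, shift, "+")
      s2$hemispheres[[h]]$white <-
        sweep(s2$hemispheres[[h]]$white, 2, shift, "+")
    }
    line2 <- line
    line2$points <- sweep(line$points, 2, shift, "+")
    v2 <- vs$vessel
    v2$centerline <- sweep(v2$centerline, 2, shift, "+")
    expect_equal(stent_to_cortex(line2, s2)$mean, base$d$mean,
                 tolerance = 1e-9)
    expect_equal(stent_to_cortex(line2, s2)$min, base$d$min,
                 tolerance = 1e-9)
    # overlap percentages are unchanged (the ROI intervals themselves
    # shift rigidly with the scene)
    expect_equal(as.vector(roi_overlap(line2, s2)), as.vector(base$ov),
                 tolerance = 1e-9)
    expect_equal(sinus_width(v2, line2), base$w, tolerance = 1e-9)
    expect_equal(cortical_thickness(s2, "M1"), base$th, tolerance = 1e-9)
  }
})

test_that("global minimum distance bounds every per-ROI minimum", {
  s <- generate_surface(seed = 4)
  vs <- generate_vessel_and_stent(s, rostral_tip = 50, seed = 4)
  line <- fit_stent_line(vs$stent, vs$vessel)
  all_min <- stent_to_cortex(line, s)$min
  for (r in c("SMA", "M1", "S1", "CAUDAL"))
    expect_lte(all_min, stent_to_cortex(line, s, roi = r)$min + 1e-12)
})

test_that("sweeping the tip rostrally moves M1 overlap as the band layout predicts", {
  s <- generate_surface()
  ov_at <- function(tip) {
    vs <- generate_vessel_and_stent(s, rostral_tip = tip, seed = 1)
    line <- fit_stent_line(vs$stent, vs$vessel)
    unname(roi_overlap(line, s)["M1"])
  }
  # M1 spans [20, 45): overlap rises while the tip approaches the rostral
  # M1 edge and falls once the device slides past it into SMA
  rising <- vapply(seq(32, 44, by = 3), ov_at, numeric(1))
  falling <- vapply(seq(46, 64, by = 3), ov_at, numeric(1))
  expect_true(all(diff(rising) > 0))
  expect_true(all(diff(falling) < 0))
})
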