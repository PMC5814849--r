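test_that("segments decompose into the expected links", {
  # duplex: one rigid rod of n * rise
  expect_equal(dnawalker:::segment_links(segment_spec("duplex", 18)),
               18 * 0.34)
  # ss shorter than one Kuhn length: a single rigid link of true contour
  expect_equal(dnawalker:::segment_links(segment_spec("ss", 2)), 2 * 0.63)
  # ss with a partial terminal link keeping its true contour
  links <- dnawalker:::segment_links(segment_spec("ss", 15))
  expect_equal(links, c(rep(1.5, 6), 15 * 0.63 - 9))
  expect_equal(sum(links), 15 * 0.63)
})

test_that("chord from arc handles flat limit, diameter and wrap-around", {
  expect_equal(chord_from_arc(10, 1e6), 10, tolerance = 1e-6)
  expect_equal(chord_from_arc(pi * 7, 7), 14)
  expect_lt(chord_from_arc(2 * pi * 7, 7), 1e-6)
  # beyond half-circumference the shorter way is used
  R <- 60 / (2 * pi)
  expect_equal(chord_from_arc(45, R), chord_from_arc(15, R))
})

test_that("maximum reach is the contour sum plus capture radius", {
  des <- rod_design(5, capture_radius = 0.5)
  expect_equal(max_reach(des), 10.5)
  d0 <- walker_default_design()
  expect_equal(max_reach(d0),
               dnawalker:::arm_contour(d0$arm_bound) +
                 dnawalker:::arm_contour(d0$arm_fuel) + 1)
  # two rods anchored d apart on a flat wall meet iff d <= b1 + b2 + delta
  expect_equal(
    contact_probability(des, track_flat(10.6), n = 100, seed = 1)$p_contact, 0)
})

test_that("single rigid rod pivoting at a flat wall samples the upper hemisphere", {
  ed <- sample_end_density(rod_arm(5), track_flat(), n = 2e4, seed = 3)
  r <- sqrt(rowSums(ed$ends^2))
  expect_equal(max(abs(r - 5)), 0, tolerance = 1e-9)
  expect_true(all(ed$ends[, 3] >= 0))
  # height uniform on [0, b]: mean b/2 within 3 sigma
  se <- (5 / sqrt(12)) / sqrt(2e4)
  expect_lt(abs(mean(ed$ends[, 3]) - 2.5), 3 * se)
  # free pivot: acceptance is one half at a flat wall
  expect_equal(ed$acceptance_rate, 0.5, tolerance = 0.02)
})

test_that("two-link freely-jointed chain matches the closed-form end distance pdf", {
  ed <- sample_end_density(two_link_arm(), track_free(), n = 1e5, seed = 8)
  r <- sqrt(rowSums(ed$ends^2))
  b <- 1.5
  expect_lte(max(r), 2 * b + 1e-9)
  # pdf r/(2 b^2) on [0, 2b]  =>  CDF r^2 / (4 b^2); per-bin 3 sigma
  breaks <- seq(0, 2 * b, length.out = 9)
  cdf <- breaks^2 / (4 * b^2)
  p_bin <- diff(cdf)
  obs <- as.numeric(table(cut(r, breaks, include.lowest = TRUE)))
  exp_n <- 1e5 * p_bin
  z <- (obs - exp_n) / sqrt(1e5 * p_bin * (1 - p_bin))
  expect_true(all(abs(z) < 3))
})

test_that("sampler is deterministic and bounded by contour", {
  des <- walker_default_design()
  e1 <- sample_end_density(des$arm_bound, track_flat(), n = 2000, seed = 42)
  e2 <- sample_end_density(des$arm_bound, track_flat(), n = 2000, seed = 42)
  expect_identical(e1$ends, e2$ends)
  r <- sqrt(rowSums(e1$ends^2))
  contour <- dnawalker:::arm_contour(des$arm_bound)
  expect_lte(stats::quantile(r, 0.95), contour)
  expect_lte(max(r), contour + 1e-9)
  # anchor below the surface is a geometry error
  expect_error(
    sample_end_density(des$arm_bound, track_flat(), anchor = c(0, 0, -1),
                       n = 10, seed = 1),
    "geometry error"
  )
})

test_that("same-anchor rod pair reproduces the sphere-point distance law", {
  # both ends uniform on a radius-b sphere: P(|r1 - r2| <= delta) = delta^2/(4 b^2)
  des <- walker_design(rod_arm(5), rod_arm(5), capture_radius = 0.5)
  cd <- contact_probability(des, track_free(0), n = 1e5, seed = 17,
                            method = "direct")
  p_true <- 0.5^2 / (4 * 25)
  expect_lt(abs(cd$p_contact - p_true), 3 * sqrt(p_true * (1 - p_true) / 1e5))
})

test_that("overlap-integral and direct-hit estimators agree on the default design", {
  des <- walker_default_design()
  for (d in c(5, 10)) {
    co <- contact_probability(des, track_flat(d), n = 2e5, seed = 42)
    cd <- contact_probability(des, track_flat(d), n = 2e5, seed = 42,
                              method = "direct")
    expect_lt(abs(co$p_contact - cd$p_contact),
              3 * sqrt(co$stderr^2 + cd$stderr^2))
  }
})

test_that("contact vanishes exactly beyond reach and persists inside it", {
  des <- walker_default_design()
  reach <- max_reach(des)
  co <- contact_probability(des, track_flat(1.05 * reach), n = 100, seed = 1)
  expect_identical(co$p_contact, 0)
  expect_identical(co$dG_rel, NA_real_)
  co2 <- contact_probability(des, track_flat(15), n = 2e4, seed = 5,
                             ref_p = 1e-4)
  expect_gt(co2$p_contact, 0)
  expect_true(is.finite(co2$dG_rel))
})

test_that("barrier differences follow from contact ratios", {
  expect_equal(delta_barrier(0.01, 0.01), 0)
  expect_equal(delta_barrier(0.01 / exp(1), 0.01), 1.0)
  expect_identical(delta_barrier(0, 0.01), Inf)
  expect_error(delta_barrier(0.01, 0), "undefined reference")
})

test_that("a huge-radius cylinder reproduces the flat track", {
  des <- walker_default_design()
  for (d in c(10, 20, 30)) {
    cf <- contact_probability(des, track_flat(d), n = 5e4, seed = 9)
    cc <- contact_probability(des, track_cylinder(d, radius = 1e6), n = 5e4,
                              seed = 9)
    expect_lt(abs(cf$p_contact - cc$p_contact),
              3 * sqrt(cf$stderr^2 + cc$stderr^2) + 1e-12)
  }
})

test_that("wrap-around makes far arcs reachable on the curled track", {
  des <- walker_default_design()
  R <- 60 / (2 * pi)
  # 45 nm arc on a 60 nm circumference is a 15 nm arc the other way
  c45 <- contact_probability(des, track_cylinder(45, radius = R), n = 2e4,
                             seed = 12)
  c15 <- contact_probability(des, track_cylinder(15, radius = R), n = 2e4,
                             seed = 12)
  expect_equal(c45$p_contact, c15$p_contact)
  expect_gt(c45$p_contact, 0)
  # while the flat model at the same arc separation is beyond reach
  expect_identical(
    contact_probability(des, track_flat(45), n = 100, seed = 1)$p_contact, 0)
})

test_that("hairpin mixture interpolates between open and folded designs", {
  des <- walker_default_design()
  expect_equal(apply_hairpin(des, hairpin_model(0, 6))$p_open, 0.5)
  hm_open <- apply_hairpin(des, hairpin_model(20, 6))
  hm_fold <- apply_hairpin(des, hairpin_model(-20, 6))
  # folding shortens the fuel overhang and hence the reach
  expect_lt(max_reach(hm_fold$folded), max_reach(des))
  p_no <- contact_probability(des, track_flat(10), n = 2e4, seed = 3)
  p_op <- contact_probability(hm_open, track_flat(10), n = 2e4, seed = 3)
  # essentially always open: indistinguishable from no hairpin
  expect_lt(abs(p_op$p_contact - p_no$p_contact),
            3 * sqrt(p_op$stderr^2 + p_no$stderr^2) + 1e-12)
  # fully folded: steps beyond the folded reach become impossible
  d_far <- max_reach(hm_fold$folded) + 1
  expect_lt(d_far, max_reach(des))
  p_far <- contact_probability(hm_fold, track_flat(d_far), n = 2e4, seed = 3)
  expect_lt(p_far$p_contact / 1,
            contact_probability(des, track_flat(d_far), n = 2e4,
                                seed = 3)$p_contact + 1e-12)
  expect_lt(p_far$p_contact, 1e-8)
  expect_error(apply_hairpin(des, hairpin_model(-2, 99)), "exceeds")
})

test_that("conformation dumps are plain text with one bead per line", {
  f <- tempfile(fileext = ".xyz")
  write_conformations_xyz(rod_arm(5), track_flat(), f, n = 3, seed = 1,
                          arm_id = "rod")
  lines <- readLines(f)
  expect_length(lines, 3 * 2)  # anchor + end per conformation
  expect_match(lines[1], "^rod 0 ")
  unlink(f)
})

test_that("predicted yield curve anchors the calibration point exactly", {
  des <- walker_default_design()
  yc <- predict_yield_curve(des, track_flat(), d_grid = c(12, 20, 30),
                            F1_list = c(1e-9, 1e-8, 1e-5),
                            calibration = default_calibration,
                            n = 2e4, seed = 31, n_boot = 5)
  ct <- attr(yc, "contacts")
  expect_equal(ct$dG_rel_kBT[ct$d_nm == 12], 0)
  at_ref <- yc[yc$step_size_nm == 12, ]
  expect_equal(at_ref$yield,
               yield_from_rates(3, 2.3e5, at_ref$fuel_conc_M))
  # yield decreasing in F1 at fixed d
  for (d in unique(yc$step_size_nm)) {
    g <- yc[yc$step_size_nm == d, ]
    g <- g[order(g$fuel_conc_M), ]
    expect_true(all(diff(g$yield) <= 0))
  }
  # contact probability non-increasing over d >= 20 (3 sigma slack)
  yc2 <- predict_yield_curve(des, track_flat(),
                             d_grid = c(20, 25, 30, 35, 40),
                             F1_list = 1e-8, calibration = default_calibration,
                             n = 5e4, seed = 32, n_boot = 10)
  c2 <- attr(yc2, "contacts")
  dp <- diff(c2$p_contact)
  tol <- 3 * sqrt(c2$p_stderr[-1]^2 + c2$p_stderr[-nrow(c2)]^2)
  expect_true(all(dp <= tol))
})
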