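# Traditional protocol: circle fitting, arc disambiguation, and the
# seven-point claw measurement.

seven <- function(...) structure(list(...), class = "seven_points")

test_that("fit_circle recovers circumcircles and rejects degenerate input", {
  res <- fit_circle(c(0, 1), c(1, 0), c(0, -1))
  expect_equal(res$center, c(0, 0), tolerance = 1e-12)
  expect_equal(res$radius, 1, tolerance = 1e-12)
  expect_error(fit_circle(c(0, 0), c(1, 0), c(2, 0)), "collinear")

  set.seed(5)
  for (i in 1:20) {
    ctr <- c(3, -2); r <- 5
    ang <- sort(runif(3, 0, 2 * pi))
    if (min(diff(ang)) < 0.05) next
    pts <- lapply(ang, function(a) ctr + r * c(cos(a), sin(a)))
    fit <- fit_circle(pts[[1]], pts[[2]], pts[[3]])
    expect_lt(max(abs(fit$center - ctr)), 1e-9)
    expect_lt(abs(fit$radius - r), 1e-9)
  }
})

test_that("subtended_arc_deg picks the arc containing `through`", {
  expect_equal(subtended_arc_deg(c(0, 0), c(1, 0), c(-1, 0), c(0, 1)), 180)
  expect_equal(subtended_arc_deg(c(0, 0), c(1, 0), c(0, 1),
                                 c(sqrt(2) / 2, sqrt(2) / 2)), 90)
  # reflex arc: through on the far side
  expect_equal(subtended_arc_deg(c(0, 0), c(1, 0), c(0, 1), c(0, -1)), 270)
  expect_error(subtended_arc_deg(c(0, 0), c(1, 0), c(0, 1), c(1, 0)),
               "coincides")
  expect_error(subtended_arc_deg(c(0, 0), c(1, 0), c(0, 1), c(2, 2)),
               "equidistant")

  # dense-sampling oracle: chord-sum arc length / radius vs returned angle
  set.seed(8)
  for (i in 1:10) {
    ctr <- runif(2, -3, 3); r <- runif(1, 0.5, 4)
    a_ang <- runif(1, 0, 2 * pi)
    span <- runif(1, 0.2, 5.8)
    b_ang <- a_ang + span
    t_ang <- a_ang + runif(1, 0.02, 0.98) * span
    p_of <- function(a) ctr + r * c(cos(a), sin(a))
    got <- subtended_arc_deg(ctr, p_of(a_ang), p_of(b_ang), p_of(t_ang))
    dense <- seq(a_ang, b_ang, length.out = 20001)
    chord_len <- sum(sqrt(rowSums((t(vapply(dense[-1], p_of, numeric(2))) -
                                   t(vapply(dense[-length(dense)], p_of,
                                            numeric(2))))^2)))
    expect_lt(abs(got - 180 / pi * chord_len / r), 1e-6)
  }
})

test_that("measure_claw handles coincident structures and scale equivariance", {
  ctr <- c(2, 1); r <- 10
  on_circ <- function(a) ctr + r * c(cos(a * pi / 180), sin(a * pi / 180))
  pts <- seven(sheath_tip = on_circ(100), core_tip = on_circ(100),
               articulation_mid = on_circ(0),
               core_dorsal_lip = on_circ(0), sheath_dorsal_lip = on_circ(0),
               core_arc_mid = on_circ(50), sheath_arc_mid = on_circ(50))
  m <- measure_claw(pts)
  expect_equal(m$core_arc_deg, 100, tolerance = 1e-9)
  expect_equal(m$sheath_arc_deg, 100, tolerance = 1e-9)
  expect_equal(m$length_ratio, 1, tolerance = 1e-12)

  # doubling all coordinates: arcs and ratio unchanged, lengths doubled
  cl <- make_claw(claw_params(theta_sheath = 110, theta_core = 95,
                              length_ratio = 0.8), seed = 4)
  p1 <- extract_seven_points(cl$config)
  cfg2 <- cl$config; cfg2$coords <- 2 * cfg2$coords
  p2 <- extract_seven_points(cfg2)
  m1 <- measure_claw(p1); m2 <- measure_claw(p2)
  expect_equal(m2$core_arc_deg, m1$core_arc_deg, tolerance = 1e-9)
  expect_equal(m2$sheath_arc_deg, m1$sheath_arc_deg, tolerance = 1e-9)
  expect_equal(m2$core_length, 2 * m1$core_length, tolerance = 1e-9)
  expect_equal(m2$length_ratio, m1$length_ratio, tolerance = 1e-12)
})

test_that("measurements are invariant under rigid motion", {
  cl <- make_claw(claw_params(), seed = 6)
  m0 <- measure_claw(extract_seven_points(cl$config))
  set.seed(9)
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    cfg <- cl$config
    cfg$coords <- cfg$coords %*% t(R) + rep(runif(2, -9, 9), each = 83)
    m <- measure_claw(extract_seven_points(cfg))
    expect_equal(m$core_arc_deg, m0$core_arc_deg, tolerance = 1e-8)
    expect_equal(m$sheath_arc_deg, m0$sheath_arc_deg, tolerance = 1e-8)
    expect_equal(m$length_ratio, m0$length_ratio, tolerance = 1e-10)
  }
})

test_that("generator ground truth is recovered exactly on noise-free claws", {
  cl <- make_claw(claw_params(theta_sheath = 110, theta_core = 95,
                              noise_sd = 0), seed = 12)
  m <- measure_claw(extract_seven_points(cl$config))
  expect_lt(abs(m$sheath_arc_deg - 110), 1e-6)
  expect_lt(abs(m$core_arc_deg - 95), 1e-6)
  expect_lt(abs(m$length_ratio - cl$truth$length_ratio), 1e-6)
  expect_equal(m$core_length, cl$truth$core_length, tolerance = 1e-9)
})

test_that("extract_seven_points is deterministic and handles LM1 = LM2", {
  cl <- make_claw(claw_params(noise_sd = 0), seed = 2)
  p1 <- extract_seven_points(cl$config)
  p2 <- extract_seven_points(cl$config)
  expect_identical(p1, p2)

  cfg <- cl$config
  cfg$coords[2, ] <- cfg$coords[1, ]
  p <- extract_seven_points(cfg)
  expect_equal(p$articulation_mid, unname(cfg$coords[1, ]), tolerance = 1e-15,
               ignore_attr = TRUE)

  # equal-arc-length semilandmarks: extracted arc midpoints sit within 2
  # degrees of the true angular midpoints
  check_mid <- function(lip, mid, tip) {
    circ <- fit_circle(lip, mid, tip)
    ang <- function(pt) atan2(pt[2] - circ$center[2], pt[1] - circ$center[1]) * 180 / pi
    full <- subtended_arc_deg(circ$center, lip, tip, mid)
    half1 <- min((ang(mid) - ang(lip)) %% 360, (ang(lip) - ang(mid)) %% 360)
    expect_lt(abs(half1 - full / 2), 2)
  }
  check_mid(p1$core_dorsal_lip, p1$core_arc_mid, p1$core_tip)
  check_mid(p1$sheath_dorsal_lip, p1$sheath_arc_mid, p1$sheath_tip)
})

test_that("measure_claws excludes degenerate specimens with a warning", {
  claws <- make_test_claws(4, seed = 31)
  # force specimen 2 degenerate: flatten its core dorsal points onto a line
  claws[[2]]$coords[c(1, 13, 4), ] <- cbind(c(0, 1, 2), c(0, 0, 0))
  expect_warning(res <- measure_claws(claws), "excluded")
  expect_identical(nrow(res), 3L)
  expect_identical(attr(res, "excluded"), "claw_002")
})
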