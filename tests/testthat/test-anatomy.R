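make_landmarks <- function(side = "right", hip = c(0, 0, 400),
                           ankle = c(0, 0, -390), groove_angle = 0) {
  th <- groove_angle * pi / 180
  landmark_set(side = side, hip_center = hip, ankle_center = ankle,
               intercondylar_notch = c(0, 0, 0),
               proximal_tibia_center = c(0, 0, -30),
               medial_epicondylar_sulcus = c(-36, -4, -14),
               lateral_epicondyle = c(36, -4, -14),
               trochlear_groove = c(30 * sin(th), 30 * cos(th), -4))
}

test_that("mechanical axes are the normalized landmark differences", {
  lm <- make_landmarks()
  expect_equal(femoral_mechanical_axis(lm), c(0, 0, 1))
  expect_equal(tibial_mechanical_axis(lm), c(0, 0, 1))
  lm2 <- make_landmarks(hip = c(0, 40, 398))
  expect_equal(femoral_mechanical_axis(lm2), c(0, 40, 398) / sqrt(40^2 + 398^2))
  # antisymmetry: swapping endpoints negates the axis
  lm3 <- landmark_set(side = "right", hip_center = c(0, 0, 0),
                      ankle_center = lm$ankle_center,
                      intercondylar_notch = c(0, 40, 398),
                      proximal_tibia_center = lm$proximal_tibia_center,
                      medial_epicondylar_sulcus = lm$medial_epicondylar_sulcus,
                      lateral_epicondyle = lm$lateral_epicondyle,
                      trochlear_groove = lm$trochlear_groove)
  expect_equal(femoral_mechanical_axis(lm3), -femoral_mechanical_axis(lm2))
  expect_error(landmark_set(side = "right", hip_center = c(0, 0, 0),
                            ankle_center = c(0, 0, -1),
                            intercondylar_notch = c(0, 0, 0),
                            proximal_tibia_center = c(0, 0, 0),
                            medial_epicondylar_sulcus = c(-1, 0, 0),
                            lateral_epicondyle = c(1, 0, 0),
                            trochlear_groove = c(0, 1, 0)), "coincide")
})

test_that("build_frame yields an orthonormal anatomical triad on both sides", {
  for (side in c("right", "left")) {
    lm <- make_landmarks(side = side)
    if (side == "left") { # mirror the landmarks
      for (nm in c("medial_epicondylar_sulcus", "lateral_epicondyle",
                   "trochlear_groove"))
        lm[[nm]][1] <- -lm[[nm]][1]
    }
    fr <- build_frame(lm)
    M <- cbind(fr$x, fr$y, fr$z)
    expect_equal(crossprod(M), diag(3), tolerance = 1e-9)
    expect_equal(abs(det(M)), 1, tolerance = 1e-9)
    # y points anterior (toward the trochlear groove)
    expect_gt(sum(fr$y * (lm$trochlear_groove - lm$intercondylar_notch)), 0)
    # x points lateral
    lat <- lm$lateral_epicondyle - lm$medial_epicondylar_sulcus
    expect_gt(sum(fr$x * lat), 0)
  }
  # Gram-Schmidt against a QR-based oracle on random landmark perturbations
  set.seed(21)
  for (i in 1:10) {
    lm <- make_landmarks(hip = c(rnorm(2, 0, 20), 400))
    lm$lateral_epicondyle <- lm$lateral_epicondyle + rnorm(3, 0, 2)
    fr <- build_frame(lm)
    z <- femoral_mechanical_axis(lm)
    ep <- lm$lateral_epicondyle - lm$medial_epicondylar_sulcus
    q <- qr.Q(qr(cbind(z, ep)))
    x_qr <- q[, 2] * sign(sum(q[, 2] * ep))
    expect_equal(fr$x, x_qr, tolerance = 1e-9)
  }
  # degenerate anatomy: epicondylar axis along the mechanical axis
  lm_bad <- make_landmarks()
  lm_bad$medial_epicondylar_sulcus <- c(0, 0, -40)
  lm_bad$lateral_epicondyle <- c(0, 0, 40)
  expect_error(build_frame(lm_bad), "degenerate")
})

test_that("compute_hka is signed varus-positive on the coronal projection", {
  lm <- make_landmarks()
  fr <- build_frame(lm)
  expect_equal(compute_hka(c(0, 0, 1), c(0, 0, 1), fr), 0)
  # distal tibia deviated laterally (ankle lateral) => varus positive
  for (deg in c(3, 8.2, -5)) {
    a <- deg * pi / 180
    tib <- c(-sin(a), 0, cos(a))  # ankle displaced laterally for deg > 0
    expect_equal(compute_hka(c(0, 0, 1), tib, fr), deg, tolerance = 1e-9)
    expect_equal(compute_hka(c(0, 0, 1), c(sin(a), 0, cos(a)), fr), -deg,
                 tolerance = 1e-9)
  }
  # tilting 5 deg in the coronal plane: dot with the femoral axis = cos(5 deg)
  a <- 5 * pi / 180
  expect_equal(sum(c(0, 0, 1) * c(-sin(a), 0, cos(a))), cos(a))
})

test_that("TEA and WSL follow their landmark definitions", {
  lm <- make_landmarks()
  fr <- build_frame(lm)
  tea <- axis_tea(lm, fr)
  expect_equal(tea$direction, fr$x, tolerance = 1e-12)
  expect_equal(sum(tea$direction * fr$z), 0, tolerance = 1e-9)
  # perturbing an epicondyle along z leaves the projected direction unchanged
  lm_z <- lm; lm_z$lateral_epicondyle <- lm$lateral_epicondyle + c(0, 0, 7)
  expect_equal(axis_tea(lm_z, build_frame(lm))$direction, tea$direction,
               tolerance = 1e-9)

  # groove straight anterior: Whiteside's line along -y, cut reference = x
  wsl <- axis_wsl(lm, fr)
  expect_equal(wsl$direction, fr$x, tolerance = 1e-12)
  # rotating the groove by theta about z rotates the reference by -theta
  for (th in c(-6, 4, 12)) {
    w <- axis_wsl(make_landmarks(groove_angle = th), fr)
    ang <- atan2(sum(w$direction * fr$y), sum(w$direction * fr$x)) * 180 / pi
    expect_equal(ang, -th, tolerance = 1e-9)
  }
  # degenerate: groove directly proximal to the notch
  lm_bad <- lm; lm_bad$trochlear_groove <- c(0, 0, 25)
  expect_error(axis_wsl(lm_bad, fr), "parallel")
})

test_that("axis_pca finds posterior extremes and applies exact external rotation", {
  k <- generate_knee(symmetric_params(), id = "sym")
  fr <- build_frame(k$landmarks)
  pca <- axis_pca(k$femur, fr, rotation_deg = 3)
  raw <- pca$diagnostics$raw_direction
  expect_equal(raw, fr$x, tolerance = 1e-9)          # symmetric condyles
  # always exactly 3 degrees between raw and returned direction
  expect_equal(acos(sum(raw * pca$direction)) * 180 / pi, 3, tolerance = 1e-9)
  # external rotation sense: lateral end moves posteriorly
  expect_lt(sum(pca$direction * fr$y), 0)
  # asymmetric condyles: angle matches the generator's closed-form truth
  k2 <- generate_knee(knee_params(post_offset_asym = 2), id = "a")
  fr2 <- build_frame(k2$landmarks)
  pca2 <- axis_pca(k2$femur, fr2, rotation_deg = 3)
  ang <- atan2(sum(pca2$direction * fr2$y), sum(pca2$direction * fr2$x)) * 180 / pi
  expect_equal(ang, atan2(2, 44) * 180 / pi - 3, tolerance = 1e-6)
  expect_equal(atan2(2, 44) * 180 / pi, 2.602562, tolerance = 1e-6)
})

test_that("axis_fea recovers exact arc centers and the closed-form angle", {
  # equal-radius coaxial condylar arcs -> FEA parallel to TEA
  k <- generate_knee(symmetric_params(), id = "sym")
  fr <- build_frame(k$landmarks)
  fea <- axis_fea(k$femur, fr)
  expect_equal(fea$direction, fr$x, tolerance = 1e-9)
  # fitted centers match the generator's arc centers to 1e-6 mm
  for (cd in c("medial", "lateral")) {
    ctr <- fea$diagnostics$centers[[cd]]
    expect_equal(ctr[2], unname(k$truth$post_center_y[cd]), tolerance = 1e-6)
    expect_equal(ctr[3], unname(k$truth$post_center_z[cd]), tolerance = 1e-6)
    expect_equal(fea$diagnostics$circles[[cd]]$radius,
                 unname(k$truth$post_radius[cd]), tolerance = 1e-6)
  }
  # centers offset 2 mm in y across 44 mm -> atan2(2, 44) = 2.60 deg to TEA
  k2 <- generate_knee(knee_params(r_distal_lat = 24, r_post_med = 20,
                                  r_post_lat = 20, dist_offset_asym = 0,
                                  post_offset_asym = 2), id = "o")
  fr2 <- build_frame(k2$landmarks)
  fea2 <- axis_fea(k2$femur, fr2)
  ang <- atan2(sum(fea2$direction * fr2$y), sum(fea2$direction * fr2$x)) * 180 / pi
  expect_equal(ang, atan2(2, 44) * 180 / pi, tolerance = 1e-6)
})

test_that("all reference axes are unit, in-plane and lateral-positive", {
  set.seed(33)
  for (i in 1:5) {
    k <- generate_knee(knee_params(
      hka = runif(1, -10, 15), post_offset_asym = runif(1, 0, 4),
      dist_offset_asym = runif(1, 0, 1.5),
      trochlear_orientation = runif(1, -5, 5),
      side = sample(c("left", "right"), 1),
      wear_fem_med = runif(1, 0, 2), noise_sd = 0.05, seed = i), id = "r")
    fr <- build_frame(k$landmarks)
    for (ax in reference_axes(k, fr)) {
      expect_equal(sqrt(sum(ax$direction^2)), 1, tolerance = 1e-9)
      expect_lt(abs(sum(ax$direction * fr$z)), 1e-9)
      expect_gt(sum(ax$direction * fr$x), 0)
    }
  }
})
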