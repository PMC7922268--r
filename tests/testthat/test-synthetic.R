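test_that("generate_knee is deterministic given its seed", {
  p <- knee_params(noise_sd = 0.1, seed = 42)
  a <- generate_knee(p, id = "a")
  b <- generate_knee(p, id = "b")
  expect_identical(a$femur$vertices, b$femur$vertices)
  expect_identical(a$tibia$vertices, b$tibia$vertices)
  c2 <- generate_knee(knee_params(noise_sd = 0.1, seed = 43), id = "c")
  expect_false(identical(a$femur$vertices, c2$femur$vertices))
  # generation does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_knee(p)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("ground-truth round-trip: axes and HKA recovered noise-free", {
  set.seed(17)
  for (i in 1:4) {
    p <- knee_params(hka = runif(1, -12, 18),
                     post_offset_asym = runif(1, 0, 4),
                     dist_offset_asym = runif(1, -0.5, 1.5),
                     trochlear_orientation = runif(1, -5, 5),
                     r_post_lat = runif(1, 17, 21),
                     wear_fem_med = runif(1, 0, 2),
                     wear_tib_lat = runif(1, 0, 1),
                     side = sample(c("left", "right"), 1))
    k <- generate_knee(p, id = "t")
    fr <- build_frame(k$landmarks)
    hka <- compute_hka(femoral_mechanical_axis(k$landmarks),
                       tibial_mechanical_axis(k$landmarks), fr)
    expect_equal(hka, p$hka, tolerance = 1e-6)
    ax <- reference_axes(k, fr)
    ang <- function(a) atan2(sum(a$direction * fr$y),
                             sum(a$direction * fr$x)) * 180 / pi
    expect_equal(ang(ax$TEA), unname(k$truth$angles["TEA"]), tolerance = 1e-6)
    expect_equal(ang(ax$WSL), unname(k$truth$angles["WSL"]), tolerance = 1e-6)
    expect_equal(ang(ax$PCA), unname(k$truth$angles["PCA_raw"]) - 3,
                 tolerance = 1e-6)
    expect_equal(ang(ax$FEA), unname(k$truth$angles["FEA"]), tolerance = 1e-6)
  }
})

test_that("HKA recovery tolerates surface noise (landmark-driven)", {
  k <- generate_knee(knee_params(hka = 8.2, noise_sd = 0.1, seed = 5), id = "n")
  fr <- build_frame(k$landmarks)
  hka <- compute_hka(femoral_mechanical_axis(k$landmarks),
                     tibial_mechanical_axis(k$landmarks), fr)
  expect_equal(hka, 8.2, tolerance = 0.2)
})

test_that("every noise-free resected thickness matches the analytic gap oracle", {
  set.seed(23)
  for (i in 1:3) {
    p <- knee_params(hka = runif(1, -8, 12),
                     post_offset_asym = runif(1, 0, 3.5),
                     dist_offset_asym = runif(1, 0, 1.5),
                     plateau_asym = runif(1, -1, 1),
                     tibial_slope = runif(1, 0, 6),
                     trochlear_orientation = runif(1, -4, 4),
                     wear_fem_med = runif(1, 0, 2),
                     wear_tib_med = runif(1, 0, 2),
                     r_post_lat = runif(1, 17, 21),
                     side = sample(c("left", "right"), 1))
    k <- generate_knee(p, id = "o")
    rec <- simulate_knee(k)
    for (m in c("TEA", "WSL", "PCA", "FEA")) {
      want <- oracle_gaps(k, m)
      got <- rec[rec$method == m, ]
      expect_equal(got$ext_med, want$ext_med, tolerance = 0.02)
      expect_equal(got$ext_lat, want$ext_lat, tolerance = 0.02)
      expect_equal(got$flex_med, want$flex_med, tolerance = 0.02)
      expect_equal(got$flex_lat, want$flex_lat, tolerance = 0.02)
    }
  }
})

test_that("posterior offset asymmetry moves flexion MLI by the plane-rotation closed form", {
  base <- simulate_knee(generate_knee(symmetric_params(), id = "s"))
  d <- 2
  k2 <- generate_knee(knee_params(r_distal_lat = 24, r_post_lat = 20,
                                  dist_offset_asym = 0, post_offset_asym = d,
                                  plateau_asym = 0, tibial_slope = 0), id = "a")
  rec <- simulate_knee(k2)
  # PCA reference angle = atan2(d, 44) - 3 deg; flexion MLI changes from the
  # symmetric case by d (extreme offset) minus the plane-rotation terms
  # posterior thickness difference lat - med = 44 sin(a) - d cos(a) where a
  # is the reference's in-plane angle (condyle half-width terms cancel)
  m0 <- base$mli_flex[base$method == "PCA"]
  m2 <- rec$mli_flex[rec$method == "PCA"]
  a2 <- atan2(d, 44) - 3 * pi / 180
  a0 <- -3 * pi / 180
  predicted <- (44 * sin(a2) - d * cos(a2)) - 44 * sin(a0)
  expect_equal(m2 - m0, predicted, tolerance = 0.05)
})

test_that("generate_cohort is reproducible and matches its spec distributions", {
  spec <- cohort_spec(n_varus = 50, n_valgus = 10, seed = 7)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$knees[[3]]$femur$vertices, c2$knees[[3]]$femur$vertices)
  expect_equal(nrow(c1$truth), 60)
  expect_equal(sum(c1$truth$group == "varus"), 50)
  # group labels recovered by classification of measured HKA
  rec <- simulate_cohort(c1$knees[1:10])
  hka_true <- c1$truth$hka_true[match(rec$knee_id, c1$truth$knee_id)]
  expect_equal(rec$hka, hka_true, tolerance = 1e-6)
  strong <- abs(hka_true) > 0.5
  expect_equal(rec$group[strong],
               c1$truth$group[match(rec$knee_id, c1$truth$knee_id)][strong])
})

test_that("drawn HKA means are within 3 SE of the spec means at n = 500", {
  tr <- generate_cohort(cohort_spec(n_varus = 500, n_valgus = 0, seed = 11))$truth
  # truncated-normal mean of the varus HKA distribution (analytic)
  m <- 8.2; s <- 3.6; lo <- 0.1; hi <- 22.7
  a <- (lo - m) / s; b <- (hi - m) / s
  mu_trunc <- m + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  se <- s / sqrt(500)
  expect_lt(abs(mean(tr$hka_true) - mu_trunc), 3 * se)
})

test_that("parameter validation rejects impossible knees", {
  expect_error(knee_params(r_post_med = -1), "radii")
  expect_error(knee_params(wear_fem_med = 4), "wear")
  expect_error(knee_params(noise_sd = -0.1), ">= 0")
  expect_error(cohort_spec(n_varus = -1), "counts")
  expect_error(cohort_spec(dists = list(nonsense = c(mean = 0, sd = 1, lo = 0, hi = 1))),
               "unknown distribution")
})
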