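# Shared fixtures and independent closed-form oracles.

# fully symmetric, neutral, unworn knee
symmetric_params <- function(...) {
  knee_params(hka = 0, r_distal_lat = 24, r_post_lat = 20,
              dist_offset_asym = 0, post_offset_asym = 0,
              trochlear_orientation = 0, plateau_asym = 0, tibial_slope = 0,
              wear_fem_med = 0, wear_fem_lat = 0,
              wear_tib_med = 0, wear_tib_lat = 0, noise_sd = 0, ...)
}

# closed-form gap oracle from generator truth (independent of the mesh
# pipeline): distal/tibial thickness from facet extremes, posterior
# thickness from the in-plane reference angle and the cylinder extremes
oracle_gaps <- function(knee, method, depth = 9, pca_rotation_deg = 3) {
  tr <- knee$truth
  alpha <- switch(method,
                  TEA = tr$angles[["TEA"]],
                  WSL = tr$angles[["WSL"]],
                  PCA = tr$angles[["PCA_raw"]] - pca_rotation_deg,
                  FEA = tr$angles[["FEA"]]) * pi / 180
  # distal femoral (normal = -z): deeper compartment is the lower extreme
  dz <- tr$fem_dist_ext_z
  th_ext <- depth - (dz - min(dz))
  # proximal tibial (normal = +z in tibial coordinates)
  tz <- tr$tib_ext_z
  th_tib <- depth - (max(tz) - tz)
  # posterior femoral: in-plane unit normal (sin a, -cos a), score of each
  # condyle = sin(a) * (x_center + sign * half-width) - cos(a) * y_extreme
  cw2 <- tr$params$condyle_width / 2
  sa <- sin(alpha); ca <- cos(alpha)
  score <- sa * (tr$condyle_x + sign(sa) * cw2) - ca * tr$fem_post_ext_y
  th_post <- depth - (max(score) - score)
  list(ext_med = unname(th_ext["medial"] + th_tib["medial"]),
       ext_lat = unname(th_ext["lateral"] + th_tib["lateral"]),
       flex_med = unname(th_post["medial"] + th_tib["medial"]),
       flex_lat = unname(th_post["lateral"] + th_tib["lateral"]))
}

# reference axis at a given in-plane angle (degrees, anterior-positive)
ref_axis_result_for_test <- function(frame, angle_deg) {
  th <- angle_deg * pi / 180
  structure(list(method = "TEST",
                 direction = cos(th) * frame$x + sin(th) * frame$y,
                 diagnostics = list()),
            class = "reference_axis")
}

# brute-force geometric circle fit (total least squares via Nelder-Mead),
# independent of the algebraic fit
geometric_circle_fit <- function(pts) {
  obj <- function(par) {
    r <- sqrt((pts[, 1] - par[1])^2 + (pts[, 2] - par[2])^2)
    sum((r - mean(r))^2)
  }
  start <- c(mean(pts[, 1]), mean(pts[, 2]))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 5000))
  r <- sqrt((pts[, 1] - fit$par[1])^2 + (pts[, 2] - fit$par[2])^2)
  list(center = fit$par, radius = mean(r))
}
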