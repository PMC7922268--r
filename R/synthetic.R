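# Parametric synthetic knee generator and cohort sampler.
#
# Condyles are analytic primitives: the distal femoral facets are circular
# arcs (cylinders with medio-lateral axes) as are the posterior facets, and
# the tibial plateau facets are gently domed spherical caps. This gives a
# closed-form ground truth for every extreme point, reference axis and
# resected thickness. Cartilage is modeled as an outward radial offset of
# the bone surface; compartment-specific wear shrinks that offset (and may
# eat into the bone up to a small allowance), which is how varus knees get
# medial and valgus knees lateral cartilage loss.
#
# Canonical construction frame: intercondylar notch at the origin,
# x = lateral, y = anterior, z = proximal. Left knees are exact mirrors
# (x negated) of the same canonical anatomy, which makes left/right mirror
# symmetry of the whole pipeline exact.

# fixed scaffold geometry (mm): positions that anchor the parametric facets
.kg_geom <- list(
  hip_z = 412,            # hip center height above the notch
  dist_ext_z = -26,       # healthy distal condylar extreme
  post_ext_y = -30,       # healthy posterior condylar extreme
  dist_center_y = -4,     # sagittal y of the distal arc centers
  post_center_z = -10,    # sagittal z of the posterior arc centers
  dist_phi = c(-36, 26),  # distal facet angular span (0 = distal extreme)
  post_phi = c(66, 110),  # posterior facet span (90 = posterior extreme)
  epi_y = -4, epi_z = -14,          # epicondylar landmark position
  groove_len = 30, groove_z = -4,   # trochlear groove landmark offset
  ptc_z = -30,            # proximal tibia center below the notch
  tibia_len = 330,        # proximal tibia center to ankle center
  plat_ext_z = -28,       # healthy plateau apex
  plat_sep = 38,          # medio-lateral spacing of plateau apexes
  plat_dome_r = 80,       # plateau dome radius
  plat_foot_r = 14        # plateau facet footprint radius
)

#' Synthetic knee parameters
#'
#' Defaults describe a neutral, symmetric, unworn knee of typical Asian
#' adult dimensions; the cohort sampler draws per-knee variations around
#' them. All lengths mm, angles degrees.
#'
#' @param side `"right"` or `"left"`.
#' @param hka HKA deformity imposed on the tibial mechanical axis (varus
#'   positive).
#' @param r_distal_med,r_distal_lat,r_post_med,r_post_lat Bone radii of the
#'   distal and posterior condylar arcs.
#' @param condyle_sep Medio-lateral spacing between condyle centers (also
#'   the posterior inter-extreme spacing on noise-free knees).
#' @param condyle_width Medio-lateral width of each condylar facet.
#' @param epicondylar_width Distance between the epicondylar landmarks.
#' @param dist_offset_asym Lateral distal extreme sits this much proximal to
#'   the medial one (healthy cartilage surface).
#' @param post_offset_asym Lateral posterior extreme sits this much anterior
#'   to the medial one (healthy cartilage surface); with `condyle_sep` 44 mm,
#'   2.3 mm is a 3 degree condylar twist relative to the TEA.
#' @param trochlear_orientation Axial rotation of Whiteside's line (degrees,
#'   positive tilts the groove laterally).
#' @param cartilage Cartilage thickness per surface (2 mm femoral + 2 mm
#'   tibial = 4 mm per compartment when healthy).
#' @param wear_fem_med,wear_fem_lat,wear_tib_med,wear_tib_lat
#'   Compartment-specific cartilage wear per surface.
#' @param wear_post_frac Fraction of the femoral compartment wear applied to
#'   the posterior condylar facet (default 0.25). Coronal-deformity
#'   osteoarthritis erodes the extension-facing distal femoral and tibial
#'   surfaces far more than the posterior condyles, which stay relatively
#'   preserved; this is what makes the worn compartment's extension gap
#'   shrink more than its flexion gap.
#' @param plateau_asym Lateral plateau apex minus medial plateau apex
#'   (healthy).
#' @param tibial_slope Posterior slope of the plateau facets (degrees).
#' @param bone_loss_allowance Wear may exceed the cartilage by at most this
#'   much (subchondral bone loss).
#' @param noise_sd Gaussian surface noise SD added to every vertex
#'   coordinate (landmarks stay exact).
#' @param seed Integer seed for the noise.
#' @param resolution List with `phi_step_deg` (condylar arc sampling),
#'   `nx` (medio-lateral samples per facet), `plateau_nr`, `plateau_na`
#'   (radial/angular plateau samples). Defaults keep the thickness
#'   discretization error below 0.02 mm.
#' @return Object of class `knee_params` (validated list).
#' @export
knee_params <- function(side = "right", hka = 0,
                        r_distal_med = 24, r_distal_lat = 23,
                        r_post_med = 20, r_post_lat = 19,
                        condyle_sep = 44, condyle_width = 24,
                        epicondylar_width = 72,
                        dist_offset_asym = 0.5, post_offset_asym = 2.3,
                        trochlear_orientation = 0,
                        cartilage = 2,
                        wear_fem_med = 0, wear_fem_lat = 0,
                        wear_tib_med = 0, wear_tib_lat = 0,
                        wear_post_frac = 0.25,
                        plateau_asym = 0, tibial_slope = 3,
                        bone_loss_allowance = 1,
                        noise_sd = 0, seed = 1L,
                        resolution = list()) {
  p <- as.list(environment())
  p$side <- match.arg(side, c("right", "left"))
  res <- list(phi_step_deg = 2, nx = 17, plateau_nr = 8, plateau_na = 24)
  res[names(resolution)] <- resolution
  p$resolution <- res
  radii <- c(r_distal_med, r_distal_lat, r_post_med, r_post_lat)
  if (any(!is.finite(unlist(p[sapply(p, is.numeric)]))))
    stop("knee parameters must be finite", call. = FALSE)
  if (any(radii <= 0)) stop("condylar radii must be > 0", call. = FALSE)
  if (cartilage < 0 || noise_sd < 0)
    stop("cartilage and noise_sd must be >= 0", call. = FALSE)
  wear <- c(wear_fem_med, wear_fem_lat, wear_tib_med, wear_tib_lat)
  if (any(wear < 0) || any(wear > cartilage + bone_loss_allowance))
    stop("wear must lie in [0, cartilage + bone_loss_allowance]", call. = FALSE)
  if (wear_post_frac < 0 || wear_post_frac > 1)
    stop("wear_post_frac must lie in [0, 1]", call. = FALSE)
  if (any(radii + cartilage - rep(c(wear_fem_med, wear_fem_lat), 2) <= 5))
    stop("geometrically impossible parameters: effective radius too small",
         call. = FALSE)
  structure(p, class = "knee_params")
}

# grid of an arc facet: circle center (cy, cz) in the sagittal plane, radius
# R, swept over phi (0 = straight distal, 90 = straight posterior), extruded
# medio-laterally over x
.arc_patch <- function(x_range, cy, cz, R, phi_range_deg, phi_step_deg, nx) {
  phi <- seq(phi_range_deg[1], phi_range_deg[2],
             by = phi_step_deg) * pi / 180
  x <- seq(x_range[1], x_range[2], length.out = nx)
  g <- expand.grid(phi = phi, x = x)
  verts <- cbind(g$x, cy - R * sin(g$phi), cz - R * cos(g$phi))
  list(vertices = verts, nu = length(phi), nv = nx)
}

.grid_faces <- function(nu, nv, offset = 0L) {
  i <- rep(seq_len(nu - 1L), nv - 1L)
  j <- rep(seq_len(nv - 1L), each = nu - 1L)
  a <- (j - 1L) * nu + i
  b <- a + 1L; cq <- a + nu; d <- cq + 1L
  rbind(cbind(a, b, d), cbind(a, d, cq)) + offset
}

.dome_patch <- function(cx, apex_z, dome_r, foot_r, slope_deg, nr, na) {
  r <- seq(0, foot_r, length.out = nr)
  th <- seq(0, 2 * pi, length.out = na + 1L)[-1L]
  g <- expand.grid(th = th, r = r)
  u <- g$r * cos(g$th); v <- g$r * sin(g$th)
  w <- sqrt(dome_r^2 - u^2 - v^2) - dome_r          # height below the apex
  pts <- cbind(u + cx, v, w + apex_z)
  # posterior slope: rotate about the x axis through the apex so that the
  # posterior (y < 0) edge drops
  s <- slope_deg * pi / 180
  apex <- c(cx, 0, apex_z)
  rel <- sweep(pts, 2, apex)
  rot <- cbind(rel[, 1],
               rel[, 2] * cos(s) - rel[, 3] * sin(s),
               rel[, 2] * sin(s) + rel[, 3] * cos(s))
  list(vertices = sweep(rot, 2, apex, "+"), nu = na, nv = nr)
}

#' Generate one synthetic knee model
#'
#' Deterministic given the parameter object (including its seed). Emits
#' labeled femoral and tibial surfaces, exact landmarks and a `truth` list
#' holding every derived ground-truth quantity (HKA, in-plane reference-axis
#' angles, facet extremes and arc centers) for oracle testing.
#'
#' @param params A [knee_params()] object.
#' @param id Knee identifier stored on the model.
#' @return A [knee_model()].
#' @export
generate_knee <- function(params = knee_params(), id = "synthetic") {
  stopifnot(inherits(params, "knee_params"))
  p <- params; G <- .kg_geom; res <- p$resolution
  x_med <- -p$condyle_sep / 2; x_lat <- p$condyle_sep / 2
  cw2 <- p$condyle_width / 2

  # ---- femur: per-condyle effective radii and arc centers ----------------
  wear_f <- c(medial = p$wear_fem_med, lateral = p$wear_fem_lat)
  asym_d <- c(medial = 0, lateral = p$dist_offset_asym)
  asym_p <- c(medial = 0, lateral = p$post_offset_asym)
  r_d <- c(medial = p$r_distal_med, lateral = p$r_distal_lat)
  r_p <- c(medial = p$r_post_med, lateral = p$r_post_lat)
  cx <- c(medial = x_med, lateral = x_lat)

  Rd_h <- r_d + p$cartilage            # healthy cartilage radii
  Rp_h <- r_p + p$cartilage
  z_cd <- G$dist_ext_z + asym_d + Rd_h # arc centers (fixed by healthy extremes)
  y_cp <- G$post_ext_y + asym_p + Rp_h
  Rd <- Rd_h - wear_f                  # worn effective radii; posterior
  Rp <- Rp_h - wear_f * p$wear_post_frac  # facets are partially preserved

  patches <- list(); comp <- character(0); regn <- character(0)
  faces <- NULL; nvert <- 0L
  add_patch <- function(pat, compartment, region) {
    faces <<- rbind(faces, .grid_faces(pat$nu, pat$nv, offset = nvert))
    nvert <<- nvert + nrow(pat$vertices)
    patches[[length(patches) + 1L]] <<- pat$vertices
    comp <<- c(comp, rep(compartment, nrow(pat$vertices)))
    regn <<- c(regn, rep(region, nrow(pat$vertices)))
  }
  for (cd in c("medial", "lateral")) {
    xr <- c(cx[[cd]] - cw2, cx[[cd]] + cw2)
    add_patch(.arc_patch(xr, G$dist_center_y, z_cd[[cd]], Rd[[cd]],
                         G$dist_phi, res$phi_step_deg, res$nx), cd, "distal")
    add_patch(.arc_patch(xr, y_cp[[cd]], G$post_center_z, Rp[[cd]],
                         G$post_phi, res$phi_step_deg, res$nx), cd, "posterior")
  }
  # simple V-groove trochlea (anterior, unlabeled; not used by any metric)
  tz <- seq(-20, -2, length.out = 7)
  tx <- seq(-12, 12, length.out = 9)
  tg <- expand.grid(z = tz, x = tx)
  troch <- list(vertices = cbind(tg$x, 10 - 0.25 * abs(tg$x), tg$z),
                nu = 7L, nv = 9L)
  add_patch(troch, "none", "trochlea")
  fem_verts <- do.call(rbind, patches)
  fem_comp <- comp; fem_regn <- regn; fem_faces <- faces

  # ---- tibia (canonical: plateau up, then coronal HKA rotation) ----------
  wear_t <- c(medial = p$wear_tib_med, lateral = p$wear_tib_lat)
  # healthy apex (cartilage surface) minus compartment wear
  apex_z <- c(medial = G$plat_ext_z, lateral = G$plat_ext_z + p$plateau_asym) -
    wear_t
  px <- c(medial = -G$plat_sep / 2, lateral = G$plat_sep / 2)
  tib_patches <- list(); tib_comp <- character(0); tib_regn <- character(0)
  tib_faces <- NULL; nvert_t <- 0L
  for (cd in c("medial", "lateral")) {
    pat <- .dome_patch(px[[cd]], apex_z[[cd]], G$plat_dome_r, G$plat_foot_r,
                       p$tibial_slope, res$plateau_nr, res$plateau_na)
    tib_faces <- rbind(tib_faces, .grid_faces(pat$nu, pat$nv, offset = nvert_t))
    nvert_t <- nvert_t + nrow(pat$vertices)
    tib_patches[[length(tib_patches) + 1L]] <- pat$vertices
    tib_comp <- c(tib_comp, rep(cd, nrow(pat$vertices)))
    tib_regn <- c(tib_regn, rep("plateau", nrow(pat$vertices)))
  }
  tib_verts <- do.call(rbind, tib_patches)

  # impose the coronal deformity: rotate the tibia (and the ankle) about the
  # proximal tibia center so that HKA = p$hka (varus = ankle lateral)
  ptc <- c(0, 0, G$ptc_z)
  ankle_rel <- c(0, 0, -G$tibia_len)
  a <- -p$hka * pi / 180
  rot_y <- function(m, ang) {
    if (is.matrix(m))
      cbind(m[, 1] * cos(ang) + m[, 3] * sin(ang), m[, 2],
            -m[, 1] * sin(ang) + m[, 3] * cos(ang))
    else c(m[1] * cos(ang) + m[3] * sin(ang), m[2],
           -m[1] * sin(ang) + m[3] * cos(ang))
  }
  tib_verts <- sweep(rot_y(sweep(tib_verts, 2, ptc), a), 2, ptc, "+")
  ankle <- ptc + rot_y(ankle_rel, a)

  # ---- surface noise (landmarks stay exact) ------------------------------
  if (p$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(p$seed)
    fem_verts <- fem_verts + matrix(stats::rnorm(length(fem_verts), 0, p$noise_sd),
                                    ncol = 3)
    tib_verts <- tib_verts + matrix(stats::rnorm(length(tib_verts), 0, p$noise_sd),
                                    ncol = 3)
  }

  # ---- landmarks ---------------------------------------------------------
  th <- p$trochlear_orientation * pi / 180
  lm <- list(
    hip_center = c(0, 0, G$hip_z),
    ankle_center = ankle,
    intercondylar_notch = c(0, 0, 0),
    proximal_tibia_center = ptc,
    medial_epicondylar_sulcus = c(-p$epicondylar_width / 2, G$epi_y, G$epi_z),
    lateral_epicondyle = c(p$epicondylar_width / 2, G$epi_y, G$epi_z),
    trochlear_groove = c(G$groove_len * sin(th), G$groove_len * cos(th),
                         G$groove_z))

  # ---- ground truth (closed forms, independent of the mesh) --------------
  fem_dist_ext_z <- G$dist_ext_z + asym_d + wear_f   # worn distal extremes
  fem_post_ext_y <- G$post_ext_y + asym_p + wear_f * p$wear_post_frac
  tib_ext_z <- apex_z + G$plat_dome_r * (1 - cos(p$tibial_slope * pi / 180))
  truth <- list(
    hka = p$hka,
    angles = c(TEA = 0, WSL = -p$trochlear_orientation,
               PCA_raw = atan2(unname(diff(fem_post_ext_y)), p$condyle_sep) * 180 / pi,
               FEA = atan2(unname(diff(y_cp)), p$condyle_sep) * 180 / pi),
    fem_dist_ext_z = fem_dist_ext_z,
    fem_post_ext_y = fem_post_ext_y,
    tib_ext_z = tib_ext_z,
    post_center_y = y_cp, post_center_z = c(medial = G$post_center_z,
                                            lateral = G$post_center_z),
    post_radius = Rp, dist_radius = Rd,
    condyle_x = cx, params = p)

  # ---- side: left knees are exact mirrors of the canonical build ---------
  if (p$side == "left") {
    fem_verts[, 1] <- -fem_verts[, 1]
    tib_verts[, 1] <- -tib_verts[, 1]
    lm <- lapply(lm, function(v) { v[1] <- -v[1]; v })
  }

  knee_model(
    femur = bone_surface(fem_verts, fem_comp, fem_regn, faces = fem_faces),
    tibia = bone_surface(tib_verts, tib_comp, tib_regn, faces = tib_faces),
    landmarks = do.call(landmark_set, c(list(side = p$side), lm)),
    truth = truth, id = id)
}

# truncated-normal draws by rejection (vectorized)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lo), hi))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

.kg_default_dists <- list(
  hka_varus          = c(mean = 8.2,  sd = 3.6, lo = 0.1,   hi = 22.7),
  hka_valgus         = c(mean = -3.9, sd = 3.4, lo = -15.7, hi = 0),
  r_distal_med       = c(mean = 24,  sd = 1.5, lo = 18,  hi = 30),
  r_distal_lat       = c(mean = 23,  sd = 1.5, lo = 17,  hi = 29),
  r_post_med         = c(mean = 20,  sd = 1.2, lo = 15,  hi = 25),
  r_post_lat         = c(mean = 19,  sd = 1.2, lo = 14,  hi = 24),
  condyle_sep        = c(mean = 44,  sd = 2.5, lo = 36,  hi = 52),
  epicondylar_width  = c(mean = 72,  sd = 4,   lo = 60,  hi = 84),
  dist_offset_asym   = c(mean = 0.5, sd = 0.5, lo = -1,  hi = 2),
  post_offset_asym   = c(mean = 2.3, sd = 1.0, lo = -0.5, hi = 5),
  trochlear_orientation = c(mean = 0, sd = 2,  lo = -6,  hi = 6),
  plateau_asym       = c(mean = 0,   sd = 0.5, lo = -1.5, hi = 1.5),
  tibial_slope       = c(mean = 3,   sd = 1.5, lo = 0,   hi = 7),
  wear_major         = c(mean = 1.3, sd = 0.5, lo = 0,   hi = 2.5),
  wear_minor         = c(mean = 0.15, sd = 0.15, lo = 0, hi = 0.8))

#' Cohort specification
#'
#' Defaults emulate the study population: 631 varus knees (HKA 8.2 +/- 3.6,
#' range 0.1-22.7) and 107 valgus knees (HKA -3.9 +/- 3.4, range -15.7-0),
#' with the worn compartment linked to the deformity (medial wear in varus,
#' lateral wear in valgus).
#'
#' @param n_varus,n_valgus Group sizes.
#' @param seed Master seed; all randomness flows from it.
#' @param noise_sd Surface noise SD applied to every knee (mm).
#' @param dists Named list overriding entries of the default parameter
#'   distribution table (each a vector `c(mean=, sd=, lo=, hi=)`).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_varus = 631, n_valgus = 107, seed = 1L,
                        noise_sd = 0.05, dists = list()) {
  if (n_varus < 0 || n_valgus < 0) stop("counts must be >= 0", call. = FALSE)
  d <- .kg_default_dists
  for (nm in names(dists)) {
    if (!nm %in% names(d)) stop(sprintf("unknown distribution '%s'", nm),
                                call. = FALSE)
    d[[nm]] <- dists[[nm]]
  }
  if (any(vapply(d, function(v) v[["sd"]], 0) < 0))
    stop("distribution SDs must be >= 0", call. = FALSE)
  structure(list(n_varus = n_varus, n_valgus = n_valgus, seed = as.integer(seed),
                 noise_sd = noise_sd, dists = d),
            class = "cohort_spec")
}

#' Generate a synthetic knee cohort
#'
#' Draws per-knee parameters from the spec's truncated-normal distributions
#' (reproducibly from the master seed), generates every knee, and returns
#' the models together with a truth table recording every drawn parameter.
#'
#' @param spec A [cohort_spec()].
#' @return List with `knees` (list of `knee_model`), `truth` (data frame,
#'   one row per knee) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_varus + spec$n_valgus
  if (n == 0L) stop("empty cohort spec", call. = FALSE)
  group <- c(rep("varus", spec$n_varus), rep("valgus", spec$n_valgus))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)
  dr <- function(nm, k) {
    v <- spec$dists[[nm]]
    rtruncnorm(k, v[["mean"]], v[["sd"]], v[["lo"]], v[["hi"]])
  }
  hka <- c(dr("hka_varus", spec$n_varus), dr("hka_valgus", spec$n_valgus))
  tab <- data.frame(
    knee_id = sprintf("knee%04d", seq_len(n)),
    group = group,
    side = sample(c("left", "right"), n, replace = TRUE),
    hka_true = hka,
    r_distal_med = dr("r_distal_med", n), r_distal_lat = dr("r_distal_lat", n),
    r_post_med = dr("r_post_med", n), r_post_lat = dr("r_post_lat", n),
    condyle_sep = dr("condyle_sep", n),
    epicondylar_width = dr("epicondylar_width", n),
    dist_offset_asym = dr("dist_offset_asym", n),
    post_offset_asym = dr("post_offset_asym", n),
    trochlear_orientation = dr("trochlear_orientation", n),
    plateau_asym = dr("plateau_asym", n),
    tibial_slope = dr("tibial_slope", n),
    stringsAsFactors = FALSE)
  major_f <- dr("wear_major", n); major_t <- dr("wear_major", n)
  minor_f <- dr("wear_minor", n); minor_t <- dr("wear_minor", n)
  varus <- group == "varus"
  tab$wear_fem_med <- ifelse(varus, major_f, minor_f)
  tab$wear_tib_med <- ifelse(varus, major_t, minor_t)
  tab$wear_fem_lat <- ifelse(varus, minor_f, major_f)
  tab$wear_tib_lat <- ifelse(varus, minor_t, major_t)
  tab$noise_sd <- spec$noise_sd
  tab$seed <- sample.int(.Machine$integer.max, n)

  knees <- lapply(seq_len(n), function(i) {
    r <- tab[i, ]
    generate_knee(knee_params(
      side = r$side, hka = r$hka_true,
      r_distal_med = r$r_distal_med, r_distal_lat = r$r_distal_lat,
      r_post_med = r$r_post_med, r_post_lat = r$r_post_lat,
      condyle_sep = r$condyle_sep, epicondylar_width = r$epicondylar_width,
      dist_offset_asym = r$dist_offset_asym,
      post_offset_asym = r$post_offset_asym,
      trochlear_orientation = r$trochlear_orientation,
      wear_fem_med = r$wear_fem_med, wear_fem_lat = r$wear_fem_lat,
      wear_tib_med = r$wear_tib_med, wear_tib_lat = r$wear_tib_lat,
      plateau_asym = r$plateau_asym, tibial_slope = r$tibial_slope,
      noise_sd = r$noise_sd, seed = r$seed), id = r$knee_id)
  })
  list(knees = knees, truth = tab, spec = spec)
}
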