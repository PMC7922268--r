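# Anatomical landmarks, mechanical axes, the knee coordinate frame, HKA and
# the four posterior femoral reference axes (TEA, WSL, PCA+3deg, FEA).
#
# Frame convention (used everywhere downstream): origin at the intercondylar
# notch, z = femoral mechanical axis (proximal), x = medio-lateral pointing
# lateral, y = antero-posterior pointing anterior. The triad is orthonormal;
# it is right-handed in world coordinates for right knees and left-handed for
# left knees (an anatomical x-lat/y-ant/z-prox triad cannot be right-handed
# for both sides). No downstream construction relies on handedness: every
# orientation is fixed explicitly against a frame axis.

.landmark_names <- c("hip_center", "ankle_center", "intercondylar_notch",
                     "proximal_tibia_center", "medial_epicondylar_sulcus",
                     "lateral_epicondyle", "trochlear_groove")

#' Construct a validated knee landmark set
#'
#' @param side `"left"` or `"right"`.
#' @param hip_center,ankle_center,intercondylar_notch,proximal_tibia_center
#'   Numeric 3-vectors (mm).
#' @param medial_epicondylar_sulcus,lateral_epicondyle,trochlear_groove
#'   Numeric 3-vectors (mm). The trochlear-groove point is the deepest point
#'   of the groove (anterior), used for Whiteside's line and to orient the
#'   frame's anterior axis.
#' @return Object of class `landmark_set`.
#' @export
landmark_set <- function(side, hip_center, ankle_center, intercondylar_notch,
                         proximal_tibia_center, medial_epicondylar_sulcus,
                         lateral_epicondyle, trochlear_groove) {
  side <- match.arg(side, c("left", "right"))
  lm <- list(hip_center = hip_center, ankle_center = ankle_center,
             intercondylar_notch = intercondylar_notch,
             proximal_tibia_center = proximal_tibia_center,
             medial_epicondylar_sulcus = medial_epicondylar_sulcus,
             lateral_epicondyle = lateral_epicondyle,
             trochlear_groove = trochlear_groove)
  for (nm in names(lm)) check_vec3(lm[[nm]], nm)
  if (vnorm(lm$hip_center - lm$intercondylar_notch) < 1e-9)
    stop("hip center and intercondylar notch coincide", call. = FALSE)
  if (vnorm(lm$proximal_tibia_center - lm$ankle_center) < 1e-9)
    stop("proximal tibia center and ankle center coincide", call. = FALSE)
  structure(c(lm, list(side = side)), class = "landmark_set")
}

#' Femoral mechanical axis
#'
#' Unit vector from the intercondylar notch to the hip center (pointing
#' proximal).
#'
#' @param landmarks A [landmark_set()].
#' @return Unit 3-vector.
#' @export
femoral_mechanical_axis <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  normalize(landmarks$hip_center - landmarks$intercondylar_notch)
}

#' Tibial mechanical axis
#'
#' Unit vector from the ankle center to the proximal tibia center (pointing
#' proximal).
#'
#' @param landmarks A [landmark_set()].
#' @return Unit 3-vector.
#' @export
tibial_mechanical_axis <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  normalize(landmarks$proximal_tibia_center - landmarks$ankle_center)
}

#' Build the femoral anatomical frame
#'
#' z is the femoral mechanical axis (proximal); x is the epicondylar vector
#' (medial sulcus to lateral epicondyle) orthogonalized against z (lateral);
#' y completes the triad and is oriented anterior using the trochlear-groove
#' landmark.
#'
#' @param landmarks A [landmark_set()].
#' @return Object of class `anatomical_frame`: list with `origin`, unit
#'   vectors `x`, `y`, `z`, and `side`.
#' @export
build_frame <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  z <- femoral_mechanical_axis(landmarks)
  ep <- landmarks$lateral_epicondyle - landmarks$medial_epicondylar_sulcus
  if (vnorm(ep) < 1e-9) stop("epicondylar landmarks coincide", call. = FALSE)
  # degenerate anatomy: epicondylar vector within 0.5 deg of the mechanical axis
  cosang <- abs(sum(normalize(ep) * z))
  if (cosang > cos(0.5 * pi / 180))
    stop("degenerate anatomy: epicondylar axis parallel to mechanical axis",
         call. = FALSE)
  x <- normalize(ep - z * sum(ep * z))
  y <- normalize(cross3(z, x))
  ant <- landmarks$trochlear_groove - landmarks$intercondylar_notch
  if (sum(y * ant) < 0) y <- -y
  structure(list(origin = landmarks$intercondylar_notch,
                 x = x, y = y, z = z, side = landmarks$side),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat(sprintf("anatomical_frame (%s knee), origin (%.2f, %.2f, %.2f)\n",
              x$side, x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Hip-knee-ankle angle (HKA)
#'
#' Signed angle between the femoral and tibial mechanical axes measured on
#' the coronal plane (spanned by the frame's x and z). Positive = varus
#' (distal tibia deviated laterally), negative = valgus, 0 = neutral.
#'
#' @param fem_axis,tib_axis Unit 3-vectors, both pointing proximal.
#' @param frame An [build_frame()] anatomical frame.
#' @return Signed HKA in degrees.
#' @export
compute_hka <- function(fem_axis, tib_axis, frame) {
  stopifnot(inherits(frame, "anatomical_frame"))
  check_vec3(fem_axis, "fem_axis"); check_vec3(tib_axis, "tib_axis")
  af <- atan2(sum(fem_axis * frame$x), sum(fem_axis * frame$z))
  at <- atan2(sum(tib_axis * frame$x), sum(tib_axis * frame$z))
  (af - at) * 180 / pi
}

ref_axis_result <- function(method, direction, frame, diagnostics = list()) {
  # enforce the contract: unit, orthogonal to z, lateral-positive
  d <- direction - frame$z * sum(direction * frame$z)
  if (vnorm(d) < 1e-9)
    stop(sprintf("%s axis degenerate: no component orthogonal to the mechanical axis",
                 method), call. = FALSE)
  d <- normalize(d)
  structure(list(method = method, direction = d, diagnostics = diagnostics),
            class = "reference_axis")
}

#' @export
print.reference_axis <- function(x, ...) {
  cat(sprintf("reference_axis %s: (%.4f, %.4f, %.4f)\n", x$method,
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

in_plane_angle <- function(d, frame) {
  atan2(sum(d * frame$y), sum(d * frame$x)) * 180 / pi
}

from_in_plane_angle <- function(angle_deg, frame) {
  th <- angle_deg * pi / 180
  cos(th) * frame$x + sin(th) * frame$y
}

#' Surgical transepicondylar axis (TEA)
#'
#' Line from the medial epicondylar sulcus to the lateral epicondylar
#' prominence, projected orthogonal to the mechanical axis, lateral-positive.
#'
#' @param landmarks A [landmark_set()].
#' @param frame An anatomical frame.
#' @return A `reference_axis` (method `"TEA"`).
#' @export
axis_tea <- function(landmarks, frame) {
  stopifnot(inherits(landmarks, "landmark_set"), inherits(frame, "anatomical_frame"))
  v <- landmarks$lateral_epicondyle - landmarks$medial_epicondylar_sulcus
  res <- ref_axis_result("TEA", v, frame)
  if (sum(res$direction * frame$x) <= 0)
    stop("TEA orientation inconsistent with the frame's lateral axis", call. = FALSE)
  res
}

#' Whiteside's line cut reference (WSL)
#'
#' Whiteside's line runs from the deepest trochlear-groove point to the
#' intercondylar notch. The returned cut reference is its in-plane
#' perpendicular (the posterior condylar line set perpendicular to
#' Whiteside's line), oriented lateral-positive.
#'
#' @inheritParams axis_tea
#' @return A `reference_axis` (method `"WSL"`); diagnostics carry the
#'   projected Whiteside's line itself.
#' @export
axis_wsl <- function(landmarks, frame) {
  stopifnot(inherits(landmarks, "landmark_set"), inherits(frame, "anatomical_frame"))
  w <- landmarks$intercondylar_notch - landmarks$trochlear_groove
  w_ip <- w - frame$z * sum(w * frame$z)
  if (vnorm(w_ip) < 1e-9)
    stop("Whiteside's line is parallel to the mechanical axis", call. = FALSE)
  w_ip <- normalize(w_ip)
  perp <- cross3(frame$z, w_ip)
  if (sum(perp * frame$x) < 0) perp <- -perp
  ref_axis_result("WSL", perp, frame, diagnostics = list(whiteside_line = w_ip))
}

compartment_points <- function(surface, compartment, region = NULL) {
  keep <- surface$compartment == compartment
  if (!is.null(region)) keep <- keep & surface$region %in% region
  surface$vertices[keep, , drop = FALSE]
}

#' Posterior condylar axis with external rotation (PCA)
#'
#' The raw PCA is tangent to the most posterior points of the medial and
#' lateral condyles. The returned reference is the raw PCA externally
#' rotated (default 3 degrees) about the mechanical axis: the lateral end of
#' the axis is moved posteriorly, deepening the lateral posterior resection.
#'
#' @param femur_surface A `bone_surface` with medial/lateral compartment
#'   labels (see [bone_surface()]).
#' @param frame An anatomical frame.
#' @param rotation_deg External rotation added to the raw PCA (degrees,
#'   default 3).
#' @return A `reference_axis` (method `"PCA"`); diagnostics carry the raw
#'   PCA direction and the two posterior extreme points.
#' @export
axis_pca <- function(femur_surface, frame, rotation_deg = 3) {
  stopifnot(inherits(femur_surface, "bone_surface"),
            inherits(frame, "anatomical_frame"))
  pm <- compartment_points(femur_surface, "medial")
  pl <- compartment_points(femur_surface, "lateral")
  if (nrow(pm) == 0L || nrow(pl) == 0L)
    stop("femur surface is missing medial or lateral compartment labels",
         call. = FALSE)
  post <- -frame$y
  em <- extreme_point(pm, post)
  el <- extreme_point(pl, post)
  raw <- ref_axis_result("PCA", el - em, frame)
  if (sum(raw$direction * frame$x) < 0) raw$direction <- -raw$direction
  # external rotation: decrease the in-plane angle (lateral end posterior)
  a <- in_plane_angle(raw$direction, frame)
  d <- from_in_plane_angle(a - rotation_deg, frame)
  ref_axis_result("PCA", d, frame,
                  diagnostics = list(raw_direction = raw$direction,
                                     rotation_deg = rotation_deg,
                                     posterior_medial = em,
                                     posterior_lateral = el))
}

#' Flexion-extension axis (FEA)
#'
#' For each condyle, the posterior articular points are projected onto the
#' sagittal plane (normal = the frame's medio-lateral axis) and a
#' least-squares circle is fitted; the FEA joins the two back-embedded
#' circle centers, projected orthogonal to the mechanical axis,
#' lateral-positive.
#'
#' @param femur_surface A `bone_surface` whose `region` labels include
#'   `"posterior"` for the posterior articular facets.
#' @param frame An anatomical frame.
#' @return A `reference_axis` (method `"FEA"`); diagnostics carry both fitted
#'   circles and the 3D centers.
#' @export
axis_fea <- function(femur_surface, frame) {
  stopifnot(inherits(femur_surface, "bone_surface"),
            inherits(frame, "anatomical_frame"))
  basis <- cbind(frame$y, frame$z)   # sagittal plane coordinates (y, z)
  centers <- list(); circles <- list()
  for (side in c("medial", "lateral")) {
    pts <- compartment_points(femur_surface, side, region = "posterior")
    if (nrow(pts) < 10L)
      stop(sprintf("FEA: %s posterior articular region has < 10 points", side),
           call. = FALSE)
    uv <- project_to_plane(pts, frame$origin, basis)
    circ <- tryCatch(fit_circle_2d(uv), error = function(e)
      stop(sprintf("FEA: degenerate circle fit on the %s condyle (%s)",
                   side, conditionMessage(e)), call. = FALSE))
    xbar <- mean(drop(sweep(pts, 2, frame$origin) %*% frame$x))
    centers[[side]] <- frame$origin + xbar * frame$x +
      circ$center[1] * frame$y + circ$center[2] * frame$z
    circles[[side]] <- circ
  }
  d <- centers$lateral - centers$medial
  res <- ref_axis_result("FEA", d, frame,
                         diagnostics = list(circles = circles, centers = centers))
  if (sum(res$direction * frame$x) < 0) res$direction <- -res$direction
  res
}

#' Compute all four posterior femoral reference axes
#'
#' @param knee A `knee_model` (see [generate_knee()] or [read_knee()]).
#' @param frame Optional precomputed frame.
#' @param pca_rotation_deg External rotation for the PCA method (degrees).
#' @param methods Character subset of `c("TEA","WSL","PCA","FEA")`.
#' @return Named list of `reference_axis` objects.
#' @export
reference_axes <- function(knee, frame = NULL, pca_rotation_deg = 3,
                           methods = c("TEA", "WSL", "PCA", "FEA")) {
  stopifnot(inherits(knee, "knee_model"))
  if (is.null(frame)) frame <- build_frame(knee$landmarks)
  out <- list()
  for (m in methods) {
    out[[m]] <- switch(m,
      TEA = axis_tea(knee$landmarks, frame),
      WSL = axis_wsl(knee$landmarks, frame),
      PCA = axis_pca(knee$femur, frame, rotation_deg = pca_rotation_deg),
      FEA = axis_fea(knee$femur, frame),
      stop(sprintf("unknown reference method '%s'", m), call. = FALSE))
  }
  out
}
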