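# Virtual measured-resection cuts: distal femoral and proximal tibial planes
# perpendicular to the mechanical axes, posterior femoral planes parallel to
# a chosen reference axis, all at 9 mm from the extreme condyle/plateau, and
# per-compartment resected thickness measurement.

#' Construct a cut plane
#'
#' @param pl A [plane()]; positive halfspace = resected side.
#' @param cut_kind One of `"distal_femoral"`, `"proximal_tibial"`,
#'   `"posterior_femoral"`.
#' @param method Posterior reference tag (`"TEA"` etc.) or `NA`.
#' @param depth Resection depth in mm (> 0).
#' @return Object of class `cut_plane`.
#' @export
cut_plane <- function(pl, cut_kind, method = NA_character_, depth = 9) {
  stopifnot(inherits(pl, "plane"))
  cut_kind <- match.arg(cut_kind,
                        c("distal_femoral", "proximal_tibial", "posterior_femoral"))
  if (!is.numeric(depth) || depth <= 0) stop("depth must be > 0", call. = FALSE)
  structure(list(plane = pl, cut_kind = cut_kind, method = method, depth = depth),
            class = "cut_plane")
}

#' @export
print.cut_plane <- function(x, ...) {
  cat(sprintf("cut_plane %s%s, depth %.1f mm\n", x$cut_kind,
              if (is.na(x$method)) "" else paste0(" (", x$method, ")"), x$depth))
  print(x$plane)
  invisible(x)
}

#' Distal femoral cut plane
#'
#' Perpendicular to the femoral mechanical axis, positioned `depth` mm
#' proximal to the most distal condylar point; the resected (positive) side
#' is distal.
#'
#' @param femur_surface A `bone_surface`.
#' @param frame An anatomical frame.
#' @param depth Resection depth (mm, default 9).
#' @return A `cut_plane`.
#' @export
build_distal_femoral_plane <- function(femur_surface, frame, depth = 9) {
  stopifnot(inherits(femur_surface, "bone_surface"),
            inherits(frame, "anatomical_frame"))
  if (nrow(femur_surface$vertices) == 0L) stop("empty femur surface", call. = FALSE)
  n <- -frame$z                       # points distal = resected side
  ext <- extreme_point(femur_surface$vertices, n)
  cut_plane(plane(ext - depth * n, n), "distal_femoral", depth = depth)
}

#' Proximal tibial cut plane
#'
#' Perpendicular to the tibial mechanical axis, `depth` mm distal to the most
#' proximal plateau point; the resected (positive) side is proximal.
#'
#' @param tibia_surface A `bone_surface`.
#' @param tib_axis Unit tibial mechanical axis pointing proximal.
#' @param depth Resection depth (mm, default 9).
#' @return A `cut_plane`.
#' @export
build_proximal_tibial_plane <- function(tibia_surface, tib_axis, depth = 9) {
  stopifnot(inherits(tibia_surface, "bone_surface"))
  check_vec3(tib_axis, "tib_axis")
  if (nrow(tibia_surface$vertices) == 0L) stop("empty tibia surface", call. = FALSE)
  n <- normalize(tib_axis)            # points proximal = resected side
  ext <- extreme_point(tibia_surface$vertices, n)
  cut_plane(plane(ext - depth * n, n), "proximal_tibial", depth = depth)
}

#' Posterior femoral cut plane for a reference axis
#'
#' Perpendicular to the distal femoral plane (i.e. containing the mechanical
#' axis direction) and parallel to the posterior reference axis, positioned
#' `depth` mm anterior to the globally most posterior condylar point along
#' the plane normal; the resected (positive) side is posterior.
#'
#' @param femur_surface A `bone_surface`.
#' @param frame An anatomical frame.
#' @param ref A `reference_axis`.
#' @param depth Resection depth (mm, default 9).
#' @return A `cut_plane` tagged with the reference method.
#' @export
build_posterior_femoral_plane <- function(femur_surface, frame, ref, depth = 9) {
  stopifnot(inherits(femur_surface, "bone_surface"),
            inherits(frame, "anatomical_frame"), inherits(ref, "reference_axis"))
  if (abs(sum(ref$direction * frame$z)) > 1e-6)
    stop("reference axis is not orthogonal to the mechanical axis", call. = FALSE)
  n <- normalize(cross3(frame$z, ref$direction))
  if (sum(n * frame$y) > 0) n <- -n   # resected side = posterior
  ext <- extreme_point(femur_surface$vertices, n)
  cut_plane(plane(ext - depth * n, n), "posterior_femoral",
            method = ref$method, depth = depth)
}

#' Per-compartment resected thickness
#'
#' Thickness of a compartment = the maximal signed distance of its surface
#' points to the cut plane, clamped at 0 (the extreme-point convention that
#' makes "9 mm from the most distal condyle" an exact identity for the
#' depth-defining compartment). Cartilage points are part of the surface.
#' A compartment entirely missed by the cut yields 0 with a warning.
#'
#' @param surface A `bone_surface` with medial/lateral labels.
#' @param cut A `cut_plane`.
#' @return Object of class `thickness_pair`: named numeric
#'   `c(medial=, lateral=)` in mm.
#' @export
resected_thickness <- function(surface, cut) {
  stopifnot(inherits(surface, "bone_surface"), inherits(cut, "cut_plane"))
  out <- c(medial = NA_real_, lateral = NA_real_)
  for (comp in c("medial", "lateral")) {
    pts <- compartment_points(surface, comp)
    if (nrow(pts) == 0L)
      stop(sprintf("empty %s compartment", comp), call. = FALSE)
    d <- max(signed_distance(cut$plane, pts))
    if (d <= 0)
      warning(sprintf("cut plane misses the %s compartment entirely", comp),
              call. = FALSE)
    out[comp] <- max(0, d)
  }
  structure(out, class = "thickness_pair")
}
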