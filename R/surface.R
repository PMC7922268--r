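# Labeled bone surfaces: vertex matrix + per-vertex compartment and region
# labels (+ optional triangle faces for mesh export).

#' Construct a labeled bone surface
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param compartment Character vector of length n with values `"medial"`,
#'   `"lateral"` or `"none"` (trochlea, shaft, ...).
#' @param region Character vector of length n; femoral surfaces use
#'   `"distal"`, `"posterior"`, `"trochlea"`; tibial surfaces use `"plateau"`.
#' @param faces Optional m x 3 integer matrix of 1-based triangle indices.
#' @return Object of class `bone_surface`.
#' @export
bone_surface <- function(vertices, compartment, region, faces = NULL) {
  if (!is.matrix(vertices) || ncol(vertices) != 3L)
    stop("vertices must be an n x 3 matrix", call. = FALSE)
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates", call. = FALSE)
  n <- nrow(vertices)
  compartment <- as.character(compartment)
  region <- as.character(region)
  if (length(compartment) != n || length(region) != n)
    stop("compartment and region labels must match the number of vertices",
         call. = FALSE)
  bad <- setdiff(unique(compartment), c("medial", "lateral", "none"))
  if (length(bad))
    stop(sprintf("unknown compartment label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (!is.null(faces)) {
    faces <- matrix(as.integer(faces), ncol = 3L)
    if (any(faces < 1L) || any(faces > n))
      stop("face indices out of range", call. = FALSE)
  }
  structure(list(vertices = vertices, compartment = compartment,
                 region = region, faces = faces),
            class = "bone_surface")
}

#' @export
print.bone_surface <- function(x, ...) {
  cat(sprintf("bone_surface: %d vertices (%d medial, %d lateral), %s faces\n",
              nrow(x$vertices), sum(x$compartment == "medial"),
              sum(x$compartment == "lateral"),
              if (is.null(x$faces)) "no" else nrow(x$faces)))
  invisible(x)
}

#' Construct a knee model
#'
#' Bundles the femoral and tibial articular surfaces, the landmark set and
#' (for synthetic knees) the generator's ground truth.
#'
#' @param femur,tibia `bone_surface` objects (articular cartilage included in
#'   the surface, as on MRI-derived models).
#' @param landmarks A [landmark_set()].
#' @param truth Optional list of generator ground-truth values.
#' @param id Optional knee identifier.
#' @return Object of class `knee_model`.
#' @export
knee_model <- function(femur, tibia, landmarks, truth = NULL, id = NA_character_) {
  stopifnot(inherits(femur, "bone_surface"), inherits(tibia, "bone_surface"),
            inherits(landmarks, "landmark_set"))
  structure(list(femur = femur, tibia = tibia, landmarks = landmarks,
                 truth = truth, id = id, side = landmarks$side),
            class = "knee_model")
}

#' @export
print.knee_model <- function(x, ...) {
  cat(sprintf("knee_model '%s' (%s): femur %d vertices, tibia %d vertices\n",
              x$id, x$side, nrow(x$femur$vertices), nrow(x$tibia$vertices)))
  invisible(x)
}
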