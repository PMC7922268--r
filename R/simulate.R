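# End-to-end per-knee simulation: frame, axes, cuts, thicknesses, gaps and
# imbalance records, and the cohort-level driver.

#' Simulate measured-resection TKA cuts on one knee
#'
#' Runs the full pipeline: builds the anatomical frame, computes HKA and the
#' requested posterior reference axes, performs the distal femoral, proximal
#' tibial and posterior femoral cuts at `depth` mm, and assembles gaps and
#' imbalances.
#'
#' @param knee A `knee_model`.
#' @param depth Resection depth in mm (default 9).
#' @param pca_rotation_deg External rotation added to the raw PCA (default 3).
#' @param methods Posterior reference methods to evaluate.
#' @return A data frame with one row per method and columns `knee_id`,
#'   `side`, `hka`, `group`, `method`, `ext_med`, `ext_lat`, `flex_med`,
#'   `flex_lat`, `mli_ext`, `mli_flex`, `fei_med`, `fei_lat` (mm; extension
#'   gaps are method-independent and repeated across rows).
#' @export
simulate_knee <- function(knee, depth = 9, pca_rotation_deg = 3,
                          methods = c("TEA", "WSL", "PCA", "FEA")) {
  stopifnot(inherits(knee, "knee_model"))
  frame <- build_frame(knee$landmarks)
  fem_ax <- femoral_mechanical_axis(knee$landmarks)
  tib_ax <- tibial_mechanical_axis(knee$landmarks)
  hka <- compute_hka(fem_ax, tib_ax, frame)
  group <- classify_alignment(hka)

  distal <- build_distal_femoral_plane(knee$femur, frame, depth = depth)
  tibial <- build_proximal_tibial_plane(knee$tibia, tib_ax, depth = depth)
  th_ext <- resected_thickness(knee$femur, distal)
  th_tib <- resected_thickness(knee$tibia, tibial)

  axes <- reference_axes(knee, frame, pca_rotation_deg = pca_rotation_deg,
                         methods = methods)
  rows <- lapply(methods, function(m) {
    post <- build_posterior_femoral_plane(knee$femur, frame, axes[[m]],
                                          depth = depth)
    th_flex <- resected_thickness(knee$femur, post)
    g <- gap_distances(th_ext, th_flex, th_tib, method = m)
    data.frame(knee_id = knee$id, side = knee$side, hka = hka, group = group,
               method = m,
               ext_med = g$ext_med, ext_lat = g$ext_lat,
               flex_med = g$flex_med, flex_lat = g$flex_lat,
               mli_ext = mli(g, "extension"), mli_flex = mli(g, "flexion"),
               fei_med = fei(g, "medial"), fei_lat = fei(g, "lateral"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a cohort of knees
#'
#' @param knees List of `knee_model` objects.
#' @param ... Passed to [simulate_knee()].
#' @return Row-bound data frame of imbalance records (knee x method).
#' @export
simulate_cohort <- function(knees, ...) {
  if (length(knees) == 0L) stop("empty cohort", call. = FALSE)
  do.call(rbind, lapply(knees, simulate_knee, ...))
}
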