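# Gap distances and imbalance metrics: extension/flexion gaps as sums of
# resected thicknesses, medio-lateral imbalance (MLI, lateral minus medial),
# flexion-extension imbalance (FEI, extension minus flexion), alignment
# grouping by HKA sign, and the simultaneous-balance predicate.

#' Assemble the four gap distances
#'
#' Each gap is the sum of the femoral (distal for extension, posterior for
#' flexion) and tibial resected thicknesses of the compartment.
#'
#' @param femoral_ext Distal femoral [resected_thickness()] pair.
#' @param femoral_flex Posterior femoral thickness pair for one reference
#'   method.
#' @param tibial Proximal tibial thickness pair.
#' @param method Posterior reference tag.
#' @return Object of class `gap_set`: list with `ext_med`, `ext_lat`,
#'   `flex_med`, `flex_lat` (mm) and `method`.
#' @export
gap_distances <- function(femoral_ext, femoral_flex, tibial,
                          method = NA_character_) {
  vals <- c(femoral_ext, femoral_flex, tibial)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("thicknesses must be finite and non-negative", call. = FALSE)
  structure(list(ext_med  = unname(femoral_ext["medial"]  + tibial["medial"]),
                 ext_lat  = unname(femoral_ext["lateral"] + tibial["lateral"]),
                 flex_med = unname(femoral_flex["medial"]  + tibial["medial"]),
                 flex_lat = unname(femoral_flex["lateral"] + tibial["lateral"]),
                 method = method),
            class = "gap_set")
}

#' @export
print.gap_set <- function(x, ...) {
  cat(sprintf("gap_set (%s): ext med/lat %.2f/%.2f, flex med/lat %.2f/%.2f mm\n",
              x$method, x$ext_med, x$ext_lat, x$flex_med, x$flex_lat))
  invisible(x)
}

#' Medio-lateral imbalance (lateral gap minus medial gap)
#'
#' @param gaps A [gap_distances()] result.
#' @param pose `"extension"` or `"flexion"` (90 degrees).
#' @return MLI in mm.
#' @export
mli <- function(gaps, pose = c("extension", "flexion")) {
  stopifnot(inherits(gaps, "gap_set"))
  pose <- match.arg(pose)
  if (pose == "extension") gaps$ext_lat - gaps$ext_med
  else gaps$flex_lat - gaps$flex_med
}

#' Flexion-extension imbalance (extension gap minus flexion gap)
#'
#' @param gaps A [gap_distances()] result.
#' @param compartment `"medial"` or `"lateral"`.
#' @return FEI in mm.
#' @export
fei <- function(gaps, compartment = c("medial", "lateral")) {
  stopifnot(inherits(gaps, "gap_set"))
  compartment <- match.arg(compartment)
  if (compartment == "medial") gaps$ext_med - gaps$flex_med
  else gaps$ext_lat - gaps$flex_lat
}

#' Classify coronal alignment from HKA
#'
#' HKA > 0 is varus; HKA <= 0 is valgus (the boundary belongs to the valgus
#' group; neutral is not a separate group).
#'
#' @param hka Numeric vector of HKA angles (degrees).
#' @return Character vector, `"varus"` or `"valgus"`.
#' @export
classify_alignment <- function(hka) {
  if (any(is.na(hka)) || any(!is.finite(hka)))
    stop("HKA must be finite", call. = FALSE)
  ifelse(hka > 0, "varus", "valgus")
}

#' Simultaneous medial and lateral flexion-extension balance
#'
#' TRUE when both |FEI medial| and |FEI lateral| are at or below the
#' threshold (the "no imbalance in either compartment" criterion, typically
#' evaluated at 1, 2 and 3 mm).
#'
#' @param fei_med,fei_lat Numeric vectors of FEI values (mm).
#' @param threshold Positive scalar threshold (mm).
#' @return Logical vector.
#' @export
balanced_both_compartments <- function(fei_med, fei_lat, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a positive scalar", call. = FALSE)
  abs(fei_med) <= threshold & abs(fei_lat) <= threshold
}
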