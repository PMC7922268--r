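# On-disk formats: ASCII STL meshes, the package's landmark JSON schema
# (versioned), per-vertex label CSVs (compartment/region do not survive STL),
# cohort truth tables and per-knee results CSVs, and run manifests.

.landmark_schema <- "kneegap-landmarks/1"

#' Write a triangle mesh as ASCII STL
#'
#' @param surface A `bone_surface` with faces, or a list with `vertices` and
#'   `faces`.
#' @param path Output file path.
#' @param name Solid name recorded in the file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(surface, path, name = "kneegap") {
  v <- surface$vertices; f <- surface$faces
  if (is.null(f)) stop("surface has no faces; cannot write STL", call. = FALSE)
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  # %.17g round-trips IEEE doubles exactly through the ASCII format
  fmt <- function(m) sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3])
  lines <- c(paste("solid", name),
             paste0("facet normal ", fmt(nrm), "\n",
                    "outer loop\n",
                    "vertex ", fmt(p1), "\n",
                    "vertex ", fmt(p2), "\n",
                    "vertex ", fmt(p3), "\n",
                    "endloop\nendfacet"),
             paste("endsolid", name))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ASCII STL file
#'
#' Vertices are de-duplicated on exact coordinate match so that meshes
#' written by [write_stl()] round-trip to the same vertex/face structure.
#'
#' @param path STL file path.
#' @return List with `vertices` (n x 3) and `faces` (m x 3, 1-based).
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex ", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("malformed ASCII STL: vertex count not a multiple of 3", call. = FALSE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  if (any(!is.finite(nums))) stop("malformed ASCII STL: bad coordinates",
                                  call. = FALSE)
  key <- apply(nums, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  verts <- nums[uniq, , drop = FALSE]
  idx <- match(key, key[uniq])
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

#' Write a landmark set as JSON
#'
#' Schema `kneegap-landmarks/1`: `{schema, side, landmarks: {name: [x,y,z]}}`
#' in mm; optional `files` entry naming the sibling mesh/label files.
#'
#' @param landmarks A [landmark_set()].
#' @param path Output path.
#' @param files Optional named list of sibling file names.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path, files = NULL) {
  stopifnot(inherits(landmarks, "landmark_set"))
  obj <- list(schema = .landmark_schema, side = landmarks$side,
              landmarks = landmarks[.landmark_names])
  if (!is.null(files)) obj$files <- files
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a landmark JSON file
#'
#' @param path Path to a `kneegap-landmarks/1` JSON file.
#' @return A [landmark_set()]; the raw parsed object is attached as
#'   attribute `"json"`.
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || obj$schema != .landmark_schema)
    stop(sprintf("unsupported landmark schema '%s' in %s",
                 if (is.null(obj$schema)) "<missing>" else obj$schema, path),
         call. = FALSE)
  missing <- setdiff(.landmark_names, names(obj$landmarks))
  if (length(missing))
    stop(sprintf("landmark file %s is missing: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  lm <- do.call(landmark_set,
                c(list(side = obj$side),
                  lapply(obj$landmarks[.landmark_names], as.numeric)))
  attr(lm, "json") <- obj
  lm
}

#' Write a knee model to a directory
#'
#' Emits `<id>_femur.stl`, `<id>_tibia.stl`, per-bone vertex label CSVs and
#' `<id>_landmarks.json` (which names the sibling files).
#'
#' @param knee A `knee_model`.
#' @param dir Output directory (created if needed).
#' @return The landmark file path, invisibly.
#' @export
write_knee <- function(knee, dir) {
  stopifnot(inherits(knee, "knee_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- knee$id
  files <- list(femur = sprintf("%s_femur.stl", id),
                tibia = sprintf("%s_tibia.stl", id),
                femur_labels = sprintf("%s_femur_labels.csv", id),
                tibia_labels = sprintf("%s_tibia_labels.csv", id))
  write_stl(knee$femur, file.path(dir, files$femur), name = paste0(id, "_femur"))
  write_stl(knee$tibia, file.path(dir, files$tibia), name = paste0(id, "_tibia"))
  for (bone in c("femur", "tibia")) {
    s <- knee[[bone]]
    utils::write.csv(data.frame(vertex = seq_len(nrow(s$vertices)),
                                compartment = s$compartment,
                                region = s$region),
                     file.path(dir, files[[paste0(bone, "_labels")]]),
                     row.names = FALSE)
  }
  lm_path <- file.path(dir, sprintf("%s_landmarks.json", id))
  write_landmarks(knee$landmarks, lm_path, files = files)
  invisible(lm_path)
}

#' Read a knee model written by [write_knee()]
#'
#' @param landmark_path Path to the knee's landmark JSON.
#' @return A `knee_model` (without generator truth).
#' @export
read_knee <- function(landmark_path) {
  lm <- read_landmarks(landmark_path)
  obj <- attr(lm, "json")
  if (is.null(obj$files))
    stop("landmark file does not reference mesh files", call. = FALSE)
  dir <- dirname(landmark_path)
  id <- sub("_landmarks\\.json$", "", basename(landmark_path))
  bones <- lapply(c(femur = "femur", tibia = "tibia"), function(bone) {
    mesh <- read_stl(file.path(dir, obj$files[[bone]]))
    lab <- utils::read.csv(file.path(dir, obj$files[[paste0(bone, "_labels")]]),
                           stringsAsFactors = FALSE)
    if (nrow(lab) != nrow(mesh$vertices))
      stop(sprintf("label/vertex count mismatch for %s of %s", bone, id),
           call. = FALSE)
    bone_surface(mesh$vertices, lab$compartment, lab$region, faces = mesh$faces)
  })
  attr(lm, "json") <- NULL
  knee_model(femur = bones$femur, tibia = bones$tibia, landmarks = lm, id = id)
}

#' Write per-knee imbalance records to CSV
#'
#' Stable column set: `knee_id, side, hka, group, method, ext_med, ext_lat,
#' flex_med, flex_lat, mli_ext, mli_flex, fei_med, fei_lat`.
#'
#' @param records Data frame from [simulate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  cols <- c("knee_id", "side", "hka", "group", "method", "ext_med", "ext_lat",
            "flex_med", "flex_lat", "mli_ext", "mli_flex", "fei_med", "fei_lat")
  missing <- setdiff(cols, names(records))
  if (length(missing))
    stop(sprintf("records are missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  utils::write.csv(records[cols], path, row.names = FALSE)
  invisible(path)
}

#' Read an imbalance records CSV, validating its schema
#'
#' @param path CSV path written by [write_records()].
#' @return Data frame of records.
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("knee_id", "side", "hka", "group", "method", "ext_med", "ext_lat",
            "flex_med", "flex_lat", "mli_ext", "mli_flex", "fei_med", "fei_lat")
  missing <- setdiff(cols, names(rec))
  if (length(missing))
    stop(sprintf("results CSV %s is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  num <- setdiff(cols, c("knee_id", "side", "group", "method"))
  for (cl in num)
    if (!is.numeric(rec[[cl]]))
      stop(sprintf("results column '%s' is not numeric", cl), call. = FALSE)
  if (nrow(rec) == 0L) stop("results CSV is empty", call. = FALSE)
  rec
}
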