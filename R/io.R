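#' Read and write MP exam files
#'
#' Exams are stored as UTF-8 tab-delimited text with header columns
#' `stimulus_id`, `x_deg`, `y_deg`, `sensitivity_db`, `raw_not_seen` (0/1),
#' one row per stimulus, decimal point `.`. Lines starting with `#` are
#' header comments and ignored on read; write-then-read round-trips
#' losslessly.
#'
#' @param path file path.
#' @param slo_frame the SLO [image_frame] to attach to the exam.
#' @param eye_id,visit identifiers attached on read.
#' @return `read_exam` returns an [mp_exam] (with a validation report in
#'   the `validation` attribute when the exam deviates from the canonical
#'   10-2 acquisition); `write_exam` returns `path` invisibly.
#' @export
read_exam <- function(path, slo_frame, eye_id = NA, visit = "baseline") {
  need <- c("stimulus_id", "x_deg", "y_deg", "sensitivity_db",
            "raw_not_seen")
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("exam file '%s' is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  for (col in c("x_deg", "y_deg", "sensitivity_db")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop(sprintf("exam file '%s': non-numeric '%s' at data row %d", path,
                   col, bad[1L]), call. = FALSE)
    df[[col]] <- as.numeric(df[[col]])
  }
  dup <- which(duplicated(df$stimulus_id))
  if (length(dup))
    stop(sprintf("exam file '%s': duplicate stimulus_id at data row %d",
                 path, dup[1L]), call. = FALSE)
  exam <- mp_exam(df, eye_id = eye_id, slo_frame = slo_frame, visit = visit)
  rep <- validate_exam(exam)
  if (nrow(rep)) {
    warning(sprintf("exam file '%s' deviates from the canonical 10-2 exam (%s)",
                    path, paste(unique(rep$check), collapse = ", ")),
            call. = FALSE)
    attr(exam, "validation") <- rep
  }
  exam
}

#' @param exam an [mp_exam].
#' @rdname read_exam
#' @export
write_exam <- function(exam, path) {
  stopifnot(inherits(exam, "mp_exam"))
  s <- exam$stimuli
  s$raw_not_seen <- as.integer(s$raw_not_seen)
  utils::write.table(s, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write fiducial correspondence files
#'
#' Tab-delimited text with columns `pair_id`, `src_x_px`, `src_y_px`,
#' `dst_x_px`, `dst_y_px`, `grader_id`, `eye_id`: one grader's paired
#' landmark picks (MP-SLO pixels -> FAF pixels).
#'
#' @param path file path.
#' @return `read_fiducials` returns a [fiducial_set]; `write_fiducials`
#'   returns `path` invisibly.
#' @export
read_fiducials <- function(path) {
  need <- c("pair_id", "src_x_px", "src_y_px", "dst_x_px", "dst_y_px",
            "grader_id", "eye_id")
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("fiducial file '%s' is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  fiducial_set(as.matrix(df[c("src_x_px", "src_y_px")]),
               as.matrix(df[c("dst_x_px", "dst_y_px")]),
               grader_id = df$grader_id[1L], eye_id = df$eye_id[1L])
}

#' @param fiducials a [fiducial_set].
#' @rdname read_fiducials
#' @export
write_fiducials <- function(fiducials, path) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  df <- data.frame(pair_id = seq_len(nrow(fiducials$src)),
                   src_x_px = fiducials$src[, 1L],
                   src_y_px = fiducials$src[, 2L],
                   dst_x_px = fiducials$dst[, 1L],
                   dst_y_px = fiducials$dst[, 2L],
                   grader_id = fiducials$grader_id,
                   eye_id = fiducials$eye_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write lesion tracing files (GeoJSON)
#'
#' Tracings are stored as a GeoJSON-style FeatureCollection of Polygon
#' features with coordinates in FAF pixels. Frame metadata
#' (`field_of_view_deg`, `pixel_dims`, `um_per_degree`) is required in the
#' collection-level `properties` and drives the internal conversion to
#' micrometers; `focus_id` sits in each feature's properties. Open rings,
#' rings with fewer than 3 distinct vertices, and self-intersecting rings
#' are rejected.
#'
#' @param path file path.
#' @return `read_tracing` returns a [lesion_tracing] in micrometers with
#'   the frame in the `frame` attribute; `write_tracing` returns `path`
#'   invisibly.
#' @export
read_tracing <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop(sprintf("tracing file '%s' is not a FeatureCollection", path),
         call. = FALSE)
  pr <- gj$properties
  if (is.null(pr$field_of_view_deg) || is.null(pr$pixel_dims) ||
      is.null(pr$um_per_degree))
    stop(sprintf("tracing file '%s' lacks frame metadata (field_of_view_deg, pixel_dims, um_per_degree)",
                 path), call. = FALSE)
  frame <- image_frame(pr$field_of_view_deg, pr$pixel_dims,
                       pr$um_per_degree)
  upp <- um_per_pixel(frame)
  foci <- lapply(gj$features, function(ft) {
    if (is.null(ft$geometry) || ft$geometry$type != "Polygon")
      stop(sprintf("tracing file '%s': features must be Polygons", path),
           call. = FALSE)
    ring <- ft$geometry$coordinates[[1L]]
    v <- do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
    if (nrow(v) < 4L || !all(v[1L, ] == v[nrow(v), ]))
      stop(sprintf("tracing file '%s': ring must be closed with >= 3 distinct vertices",
                   path), call. = FALSE)
    fid <- if (!is.null(ft$properties$focus_id)) ft$properties$focus_id
           else NA
    ga_focus(v[-nrow(v), , drop = FALSE] * upp, focus_id = fid)
  })
  min_area <- if (!is.null(pr$min_focus_area_mm2)) pr$min_focus_area_mm2
              else 0.05
  tr <- lesion_tracing(foci,
                       eye_id = if (!is.null(pr$eye_id)) pr$eye_id else NA,
                       min_focus_area_mm2 = min_area)
  attr(tr, "frame") <- frame
  tr
}

#' @param tracing a [lesion_tracing] in micrometers.
#' @param frame the FAF [image_frame] used to express coordinates in pixels.
#' @rdname read_tracing
#' @export
write_tracing <- function(tracing, path, frame) {
  stopifnot(inherits(tracing, "lesion_tracing"),
            inherits(frame, "image_frame"))
  upp <- um_per_pixel(frame)
  features <- lapply(tracing$foci, function(f) {
    v <- f$vertices / upp
    ring <- lapply(seq_len(nrow(v)), function(i) c(v[i, 1L], v[i, 2L]))
    ring[[length(ring) + 1L]] <- ring[[1L]]  # GeoJSON closed ring
    list(type = "Feature",
         properties = list(focus_id = f$focus_id),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  gj <- list(type = "FeatureCollection",
             properties = list(field_of_view_deg = frame$field_of_view_deg,
                               pixel_dims = frame$pixel_dims,
                               um_per_degree = frame$um_per_degree,
                               eye_id = tracing$eye_id,
                               min_focus_area_mm2 = tracing$min_focus_area_mm2),
             features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read and write a fitted similarity transform
#'
#' Structured JSON with `scale`, `rotation_rad`, `tx`, `ty`, optional
#' `rmse`, `n_pairs`, and free-form `source_frame`/`target_frame` labels.
#'
#' @param path file path.
#' @return `read_transform` returns a [similarity_transform];
#'   `write_transform` returns `path` invisibly.
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tf <- similarity_transform(x$scale, x$rotation_rad, c(x$tx, x$ty))
  tf$rmse <- x$rmse
  tf$n_pairs <- x$n_pairs
  tf
}

#' @param transform a [similarity_transform].
#' @param source_frame,target_frame free-form frame labels recorded in the
#'   file.
#' @rdname read_transform
#' @export
write_transform <- function(transform, path, source_frame = "mp_slo_px",
                            target_frame = "faf_px") {
  stopifnot(inherits(transform, "similarity_transform"))
  jsonlite::write_json(
    list(scale = transform$scale, rotation_rad = transform$rotation,
         tx = transform$translation[1L], ty = transform$translation[2L],
         source_frame = source_frame, target_frame = target_frame,
         rmse = transform$rmse, n_pairs = transform$n_pairs),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write or read a simulated study as a directory tree
#'
#' `write_study` lays a `ga_study` out on disk: per eye an exam file
#' (`eye<k>_exam.tsv`), a tracing (`eye<k>_tracing.geojson`) and two
#' fiducial files (`eye<k>_fiducials_grader<j>.tsv`), plus a `study.json`
#' manifest holding the frame metadata, seed and eye count. `read_study`
#' reconstructs the study from such a directory (ground truth is not
#' serialized; it lives only in the in-memory study object).
#'
#' @param study a `ga_study`.
#' @param dir directory path (created if needed).
#' @return `write_study` returns `dir` invisibly; `read_study` returns a
#'   `ga_study`-shaped list (without `truth` components).
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "ga_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- study$config
  manifest <- list(
    n_eyes = length(study$eyes), seed = cfg$seed,
    staircase = cfg$staircase,
    faf_frame = cfg$faf_frame[c("field_of_view_deg", "pixel_dims",
                                "um_per_degree")],
    slo_frame = cfg$slo_frame[c("field_of_view_deg", "pixel_dims",
                                "um_per_degree")])
  jsonlite::write_json(manifest, file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_along(study$eyes)) {
    eye <- study$eyes[[i]]
    write_exam(eye$exam, file.path(dir, sprintf("eye%d_exam.tsv", i)))
    write_tracing(eye$tracing,
                  file.path(dir, sprintf("eye%d_tracing.geojson", i)),
                  cfg$faf_frame)
    for (j in 1:2)
      write_fiducials(eye$fiducials[[j]],
                      file.path(dir,
                                sprintf("eye%d_fiducials_grader%d.tsv", i, j)))
  }
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "study.json"),
                                  simplifyVector = TRUE)
  faf <- image_frame(manifest$faf_frame$field_of_view_deg,
                     manifest$faf_frame$pixel_dims,
                     manifest$faf_frame$um_per_degree)
  slo <- image_frame(manifest$slo_frame$field_of_view_deg,
                     manifest$slo_frame$pixel_dims,
                     manifest$slo_frame$um_per_degree)
  eyes <- lapply(seq_len(manifest$n_eyes), function(i) {
    exam <- read_exam(file.path(dir, sprintf("eye%d_exam.tsv", i)),
                      slo_frame = slo, eye_id = i)
    tracing <- read_tracing(file.path(dir,
                                      sprintf("eye%d_tracing.geojson", i)))
    fids <- lapply(1:2, function(j)
      read_fiducials(file.path(dir,
                               sprintf("eye%d_fiducials_grader%d.tsv", i, j))))
    list(eye_id = i, exam = exam, tracing = tracing, fiducials = fids)
  })
  structure(list(config = list(faf_frame = faf, slo_frame = slo,
                               seed = manifest$seed,
                               staircase = manifest$staircase),
                 eyes = eyes),
            class = "ga_study")
}
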