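#' The rectilinear 10-2 microperimetry stimulus grid
#'
#' Generates the canonical fovea-centered 10-2 pattern: the lattice of points
#' with odd-integer degree coordinates (x, y in \{-9, -7, ..., 7, 9\})
#' retained when x^2 + y^2 <= 82. This is the unique symmetric radius cutoff
#' on the 2-degree-spaced odd lattice that yields the standard 68 stimulus
#' points. The grid is 4-fold symmetric, contains no point at the origin,
#' and is returned in a deterministic row-major order (top-left to
#' bottom-right, with y upward so the top row is y = +9).
#'
#' @return A data.frame with 68 rows and columns `stimulus_id` (1..68),
#'   `x_deg`, `y_deg`.
#' @examples
#' g <- mp_grid_10_2()
#' nrow(g)  # 68
#' @export
mp_grid_10_2 <- function() {
  odd <- seq(-9, 9, by = 2)
  pts <- expand.grid(x_deg = odd, y_deg = odd)
  pts <- pts[pts$x_deg^2 + pts$y_deg^2 <= 82, , drop = FALSE]
  pts <- pts[order(-pts$y_deg, pts$x_deg), , drop = FALSE]
  rownames(pts) <- NULL
  data.frame(stimulus_id = seq_len(nrow(pts)), pts)
}

#' Goldmann III stimulus diameter in degrees (metadata only; stimuli are
#' analysed as center points).
#' @export
GOLDMANN_III_DIAMETER_DEG <- 0.43

#' Construct a microperimetry exam
#'
#' An `mp_exam` holds one eye's MP acquisition: the per-stimulus grid
#' positions (fovea-centered degrees), measured sensitivities in dB, and the
#' raw not-seen flags. The device records -1 dB when the brightest stimulus
#' is not seen; `raw_not_seen` mirrors that sentinel.
#'
#' @param stimuli data.frame with columns `stimulus_id`, `x_deg`, `y_deg`,
#'   `sensitivity_db`, `raw_not_seen` (logical or 0/1).
#' @param eye_id eye identifier.
#' @param slo_frame the [image_frame] of the SLO image underlying the exam.
#' @param visit visit label.
#' @param stimulus_diameter_deg stimulus diameter metadata (degrees).
#' @return An object of class `mp_exam`.
#' @seealso [validate_exam()] for conformance checks against the canonical
#'   10-2 lattice.
#' @export
mp_exam <- function(stimuli, eye_id, slo_frame,
                    visit = "baseline",
                    stimulus_diameter_deg = GOLDMANN_III_DIAMETER_DEG) {
  stopifnot(inherits(slo_frame, "image_frame"))
  need <- c("stimulus_id", "x_deg", "y_deg", "sensitivity_db", "raw_not_seen")
  missing_cols <- setdiff(need, names(stimuli))
  if (length(missing_cols))
    stop("exam stimuli missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  stimuli <- as.data.frame(stimuli)[need]
  stimuli$raw_not_seen <- as.logical(stimuli$raw_not_seen)
  if (anyNA(stimuli$raw_not_seen))
    stop("'raw_not_seen' must be logical (or 0/1) without missing values",
         call. = FALSE)
  if (anyDuplicated(stimuli$stimulus_id))
    stop("duplicate stimulus_id values in exam", call. = FALSE)
  # device convention: a not-seen stimulus is recorded as -1 dB
  if (any(stimuli$raw_not_seen & stimuli$sensitivity_db != -1))
    stop("raw_not_seen stimuli must carry the -1 dB sentinel", call. = FALSE)
  structure(
    list(eye_id = eye_id, visit = visit, stimuli = stimuli,
         slo_frame = slo_frame,
         stimulus_diameter_deg = stimulus_diameter_deg),
    class = "mp_exam")
}

#' @export
print.mp_exam <- function(x, ...) {
  ns <- sum(classify_scotomatous(x$stimuli$sensitivity_db,
                                 x$stimuli$raw_not_seen))
  cat(sprintf("MP exam: eye %s, visit %s, %d stimuli (%d scotomatous)\n",
              x$eye_id, x$visit, nrow(x$stimuli), ns))
  invisible(x)
}

#' Validate an exam against the canonical 10-2 acquisition
#'
#' Report-only conformance check: flags a wrong stimulus count, duplicate
#' ids, positions off the canonical 10-2 lattice (beyond `position_tol_deg`),
#' and sensitivities outside the adopted device range of \[-1, 36\] dB.
#'
#' @param exam an [mp_exam].
#' @param position_tol_deg tolerance (degrees) for matching stimulus
#'   positions to the canonical lattice.
#' @return A data.frame with columns `check`, `detail`; zero rows when the
#'   exam is fully conformant.
#' @export
validate_exam <- function(exam, position_tol_deg = 0.01) {
  stopifnot(inherits(exam, "mp_exam"))
  s <- exam$stimuli
  issues <- list()
  flag <- function(check, detail)
    issues[[length(issues) + 1L]] <<- data.frame(check = check,
                                                 detail = detail)
  if (nrow(s) != 68L)
    flag("stimulus_count", sprintf("expected 68 stimuli, found %d", nrow(s)))
  dup <- unique(s$stimulus_id[duplicated(s$stimulus_id)])
  if (length(dup))
    flag("duplicate_ids", paste("duplicated stimulus_id:",
                                paste(dup, collapse = ", ")))
  g <- mp_grid_10_2()
  for (i in seq_len(nrow(s))) {
    d <- sqrt((g$x_deg - s$x_deg[i])^2 + (g$y_deg - s$y_deg[i])^2)
    if (min(d) > position_tol_deg)
      flag("off_lattice",
           sprintf("stimulus %s at (%g, %g) deg is %.3g deg from lattice",
                   s$stimulus_id[i], s$x_deg[i], s$y_deg[i], min(d)))
  }
  bad <- s$sensitivity_db < -1 | s$sensitivity_db > 36
  if (any(bad))
    flag("sensitivity_range",
         paste("sensitivity outside [-1, 36] dB for stimulus:",
               paste(s$stimulus_id[bad], collapse = ", ")))
  if (length(issues)) do.call(rbind, issues)
  else data.frame(check = character(), detail = character())
}
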