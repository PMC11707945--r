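#' A traced geographic-atrophy focus
#'
#' One GA focus traced on fundus autofluorescence, represented as a closed
#' simple polygon of 2-D vertices in FAF-frame micrometers (the closing edge
#' from the last vertex back to the first is implicit). Vertex order is
#' normalized to counterclockwise (positive shoelace signed area) on
#' construction; input orientation is accepted either way.
#'
#' @param vertices n x 2 matrix of vertex coordinates in micrometers
#'   (n >= 3; no repeated closing vertex).
#' @param focus_id identifier for the focus.
#' @return An object of class `ga_focus`.
#' @export
ga_focus <- function(vertices, focus_id = 1L) {
  v <- as_xy(vertices, "vertices")
  if (any(!is.finite(v)))
    stop("focus vertices must be finite", call. = FALSE)
  # drop an explicit closing vertex if present
  n <- nrow(v)
  if (n >= 2L && all(v[1L, ] == v[n, ])) v <- v[-n, , drop = FALSE]
  if (nrow(v) < 3L)
    stop("a GA focus needs at least 3 distinct vertices", call. = FALSE)
  a <- shoelace_signed_area(v)
  if (abs(a) == 0)
    stop("degenerate focus polygon: zero area", call. = FALSE)
  if (a < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  if (polygon_self_intersects(v))
    stop("focus polygon is self-intersecting", call. = FALSE)
  structure(list(vertices = v, focus_id = focus_id), class = "ga_focus")
}

shoelace_signed_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# Exact (tolerance-free) check that any two non-adjacent edges of the closed
# polygon cross or overlap.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(FALSE)
  a <- v
  b <- v[c(2:n, 1L), , drop = FALSE]
  idx <- utils::combn(n, 2L)
  i <- idx[1L, ]; j <- idx[2L, ]
  adjacent <- (j - i == 1L) | (i == 1L & j == n)
  i <- i[!adjacent]; j <- j[!adjacent]
  if (!length(i)) return(FALSE)
  segments_intersect(a[i, , drop = FALSE], b[i, , drop = FALSE],
                     a[j, , drop = FALSE], b[j, , drop = FALSE])
}

cross2 <- function(ox, oy, ax, ay, bx, by) {
  (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
}

# vectorized proper/improper intersection test for segment pairs
segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- cross2(p3[, 1L], p3[, 2L], p4[, 1L], p4[, 2L], p1[, 1L], p1[, 2L])
  d2 <- cross2(p3[, 1L], p3[, 2L], p4[, 1L], p4[, 2L], p2[, 1L], p2[, 2L])
  d3 <- cross2(p1[, 1L], p1[, 2L], p2[, 1L], p2[, 2L], p3[, 1L], p3[, 2L])
  d4 <- cross2(p1[, 1L], p1[, 2L], p2[, 1L], p2[, 2L], p4[, 1L], p4[, 2L])
  proper <- (sign(d1) * sign(d2) < 0) & (sign(d3) * sign(d4) < 0)
  on_seg <- function(px, py, ax, ay, bx, by, d) {
    d == 0 & px >= pmin(ax, bx) & px <= pmax(ax, bx) &
      py >= pmin(ay, by) & py <= pmax(ay, by)
  }
  touch <- on_seg(p1[, 1L], p1[, 2L], p3[, 1L], p3[, 2L], p4[, 1L], p4[, 2L], d1) |
    on_seg(p2[, 1L], p2[, 2L], p3[, 1L], p3[, 2L], p4[, 1L], p4[, 2L], d2) |
    on_seg(p3[, 1L], p3[, 2L], p1[, 1L], p1[, 2L], p2[, 1L], p2[, 2L], d3) |
    on_seg(p4[, 1L], p4[, 2L], p1[, 1L], p1[, 2L], p2[, 1L], p2[, 2L], d4)
  any(proper | touch)
}

#' Polygon area of a GA focus in square millimeters
#'
#' Shoelace area of the focus polygon, converted from square micrometers
#' (1 mm^2 = 1e6 um^2). Independent of vertex orientation.
#'
#' @param focus a [ga_focus].
#' @return Scalar area in mm^2.
#' @export
polygon_area <- function(focus) {
  stopifnot(inherits(focus, "ga_focus"))
  abs(shoelace_signed_area(focus$vertices)) / 1e6
}

#' A lesion tracing: the set of GA foci for one eye
#'
#' Bundles the traced foci of an eye with the minimum-lesion-size threshold
#' of the tracing protocol (default 0.05 mm^2). The constructor stores all
#' foci; [filter_min_area()] applies the threshold.
#'
#' @param foci a list of [ga_focus] objects (or a single focus).
#' @param eye_id eye identifier.
#' @param min_focus_area_mm2 minimum focus area retained by the tracing
#'   protocol, in mm^2.
#' @return An object of class `lesion_tracing`.
#' @export
lesion_tracing <- function(foci, eye_id = NA, min_focus_area_mm2 = 0.05) {
  if (inherits(foci, "ga_focus")) foci <- list(foci)
  if (!is.list(foci) || !all(vapply(foci, inherits, logical(1L), "ga_focus")))
    stop("'foci' must be a list of ga_focus objects", call. = FALSE)
  if (min_focus_area_mm2 < 0)
    stop("'min_focus_area_mm2' must be non-negative", call. = FALSE)
  structure(list(foci = foci, eye_id = eye_id,
                 min_focus_area_mm2 = min_focus_area_mm2),
            class = "lesion_tracing")
}

#' @export
print.lesion_tracing <- function(x, ...) {
  areas <- vapply(x$foci, polygon_area, numeric(1L))
  cat(sprintf("lesion tracing: eye %s, %d focus/foci, total area %.3f mm^2 (min size %.2g mm^2)\n",
              x$eye_id, length(x$foci), sum(areas), x$min_focus_area_mm2))
  invisible(x)
}

#' Apply the minimum-lesion-size filter to a tracing
#'
#' Retains foci with area >= `min_focus_area_mm2` and records dropped
#' focus ids in the `dropped_focus_ids` attribute. An empty result is valid:
#' downstream zones are then empty.
#'
#' @param tracing a [lesion_tracing].
#' @return The filtered `lesion_tracing`.
#' @export
filter_min_area <- function(tracing) {
  stopifnot(inherits(tracing, "lesion_tracing"))
  areas <- vapply(tracing$foci, polygon_area, numeric(1L))
  keep <- areas >= tracing$min_focus_area_mm2
  dropped <- vapply(tracing$foci[!keep], function(f) as.character(f$focus_id),
                    character(1L))
  out <- tracing
  out$foci <- tracing$foci[keep]
  attr(out, "dropped_focus_ids") <- dropped
  if (length(dropped))
    message(sprintf("filter_min_area: dropped %d focus/foci below %.2g mm^2 (%s)",
                    length(dropped), tracing$min_focus_area_mm2,
                    paste(dropped, collapse = ", ")))
  out
}

# min distance from each point (m x 2) to one polygon's boundary
point_to_ring_distance <- function(pts, v) {
  n <- nrow(v)
  ax <- v[, 1L]; ay <- v[, 2L]
  bx <- c(ax[-1L], ax[1L]); by <- c(ay[-1L], ay[1L])
  ex <- bx - ax; ey <- by - ay
  len2 <- ex^2 + ey^2
  len2[len2 == 0] <- 1  # degenerate edge collapses to its endpoint
  vapply(seq_len(nrow(pts)), function(i) {
    px <- pts[i, 1L]; py <- pts[i, 2L]
    t <- pmin(pmax(((px - ax) * ex + (py - ay) * ey) / len2, 0), 1)
    dx <- px - (ax + t * ex); dy <- py - (ay + t * ey)
    sqrt(min(dx^2 + dy^2))
  }, numeric(1L))
}

# even-odd (crossing-number) containment of each point in one ring
point_in_ring <- function(pts, v) {
  n <- nrow(v)
  ax <- v[, 1L]; ay <- v[, 2L]
  bx <- c(ax[-1L], ax[1L]); by <- c(ay[-1L], ay[1L])
  vapply(seq_len(nrow(pts)), function(i) {
    px <- pts[i, 1L]; py <- pts[i, 2L]
    crosses <- ((ay > py) != (by > py)) &
      (px < (bx - ax) * (py - ay) / (by - ay) + ax)
    sum(crosses) %% 2L == 1L
  }, logical(1L))
}

#' Signed distance from stimulus points to the GA lesion margin
#'
#' For each query point, the signed Euclidean (straight-line) distance to the
#' closest point on any retained focus boundary. Negative distances mark
#' points inside the atrophy, positive distances points outside; containment
#' over multifocal tracings uses the even-odd rule (a point inside an odd
#' number of foci is inside the lesion). A point exactly on a margin returns
#' distance 0 with non-negative sign. The minimum-lesion-size filter is
#' applied before distances are computed.
#'
#' @param xy n x 2 matrix (or length-2 vector) of query points in FAF-frame
#'   micrometers.
#' @param tracing a [lesion_tracing].
#' @param stimulus_id optional identifiers carried into the result.
#' @return A data.frame with columns `stimulus_id`, `distance_um` (signed),
#'   `nearest_focus_id`.
#' @examples
#' sq <- ga_focus(rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000)))
#' tr <- lesion_tracing(sq)
#' signed_distance(c(500, 500), tr)$distance_um   # -500 (inside)
#' signed_distance(c(1500, 500), tr)$distance_um  # +500 (outside)
#' @export
signed_distance <- function(xy, tracing, stimulus_id = NULL) {
  stopifnot(inherits(tracing, "lesion_tracing"))
  xy <- as_xy(xy)
  if (any(!is.finite(xy)))
    stop("query points must be finite", call. = FALSE)
  tracing <- suppressMessages(filter_min_area(tracing))
  if (!length(tracing$foci))
    stop("no lesion: tracing contains no focus at or above the minimum size",
         call. = FALSE)
  m <- nrow(xy)
  dmat <- vapply(tracing$foci,
                 function(f) point_to_ring_distance(xy, f$vertices),
                 numeric(m))
  dmat <- matrix(dmat, nrow = m)
  nearest <- max.col(-dmat, ties.method = "first")
  unsigned <- dmat[cbind(seq_len(m), nearest)]
  inmat <- vapply(tracing$foci, function(f) point_in_ring(xy, f$vertices),
                  logical(m))
  inmat <- matrix(inmat, nrow = m)
  inside <- (rowSums(inmat) %% 2L) == 1L
  d <- ifelse(unsigned == 0, 0, ifelse(inside, -unsigned, unsigned))
  ids <- vapply(tracing$foci, function(f) as.character(f$focus_id),
                character(1L))
  if (is.null(stimulus_id)) stimulus_id <- seq_len(m)
  data.frame(stimulus_id = stimulus_id,
             distance_um = d,
             nearest_focus_id = ids[nearest])
}

#' Analysis zone specification
#'
#' A zone is a band of signed stimulus-to-margin distances. The junctional
#' zone spans 250 um on both sides of the GA margin (-250 to +250 um); the
#' perilesional zone runs from the margin to 500 um beyond it (0 to
#' +500 um). Both bounds are inclusive.
#'
#' @param kind `"junctional"` or `"perilesional"`, or `"custom"` with
#'   explicit bounds.
#' @param inner_limit_um,outer_limit_um signed micrometre bounds; defaults
#'   follow `kind`.
#' @return An object of class `zone_spec`.
#' @export
zone_spec <- function(kind = c("junctional", "perilesional", "custom"),
                      inner_limit_um = NULL, outer_limit_um = NULL) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
                     junctional = c(-250, 250),
                     perilesional = c(0, 500),
                     custom = c(NA_real_, NA_real_))
  if (is.null(inner_limit_um)) inner_limit_um <- defaults[1L]
  if (is.null(outer_limit_um)) outer_limit_um <- defaults[2L]
  if (!is.finite(inner_limit_um) || !is.finite(outer_limit_um))
    stop("custom zones need explicit finite bounds", call. = FALSE)
  if (inner_limit_um >= outer_limit_um)
    stop("'inner_limit_um' must be below 'outer_limit_um'", call. = FALSE)
  structure(list(kind = kind,
                 inner_limit_um = as.numeric(inner_limit_um),
                 outer_limit_um = as.numeric(outer_limit_um)),
            class = "zone_spec")
}

#' @export
print.zone_spec <- function(x, ...) {
  cat(sprintf("%s zone: signed distance in [%g, %g] um\n",
              x$kind, x$inner_limit_um, x$outer_limit_um))
  invisible(x)
}

#' Zone membership of signed distances
#'
#' A stimulus belongs to the zone iff its signed stimulus-to-margin distance
#' lies within the zone's bounds, both bounds inclusive. A stimulus exactly
#' on the margin (distance 0) is in both the junctional and perilesional
#' zones.
#'
#' @param distance_um numeric vector of signed distances, or the data.frame
#'   returned by [signed_distance()].
#' @param zone a [zone_spec].
#' @return Logical vector.
#' @export
zone_membership <- function(distance_um, zone = zone_spec("junctional")) {
  stopifnot(inherits(zone, "zone_spec"))
  if (is.data.frame(distance_um)) distance_um <- distance_um$distance_um
  distance_um >= zone$inner_limit_um & distance_um <= zone$outer_limit_um
}
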