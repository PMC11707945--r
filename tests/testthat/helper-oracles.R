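# Independent oracles and fixture builders used across the suite.
# Oracles deliberately take a different computational route than the
# package implementation they check.

# --- geometry ---------------------------------------------------------------

square_focus <- function(side_um = 1000, origin = c(0, 0), focus_id = 1L) {
  ga_focus(rbind(origin,
                 origin + c(side_um, 0),
                 origin + c(side_um, side_um),
                 origin + c(0, side_um)),
           focus_id = focus_id)
}

random_star_polygon <- function(center = c(0, 0), radius = 300,
                                n_vertices = 24L, wobble = 0.35) {
  # jittered equal angular spacing keeps the star-shaped outline simple
  gap <- 2 * pi / n_vertices
  theta <- (seq_len(n_vertices) - 1L) * gap +
    stats::runif(n_vertices, 0.15, 0.85) * gap
  r <- radius * (1 + wobble * stats::runif(n_vertices, -1, 1))
  cbind(center[1] + r * cos(theta), center[2] + r * sin(theta))
}

# containment by signed angle sum (winding), independent of the package's
# crossing-number implementation
oracle_point_in_ring <- function(p, v) {
  dx <- v[, 1] - p[1]
  dy <- v[, 2] - p[2]
  if (any(dx == 0 & dy == 0)) return(TRUE)
  ang <- atan2(dy, dx)
  d <- diff(c(ang, ang[1]))
  d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
  abs(sum(d)) > pi  # ~2*pi inside, ~0 outside
}

# unsigned distance by dense boundary sampling at `step` micrometres
oracle_boundary_distance <- function(p, v, step = 0.1) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1), , drop = FALSE]
  best <- Inf
  for (e in seq_len(n)) {
    len <- sqrt(sum((b[e, ] - a[e, ])^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
    sx <- a[e, 1] + t * (b[e, 1] - a[e, 1])
    sy <- a[e, 2] + t * (b[e, 2] - a[e, 2])
    best <- min(best, sqrt(min((sx - p[1])^2 + (sy - p[2])^2)))
  }
  best
}

oracle_signed_distance <- function(p, rings, step = 0.1) {
  uns <- min(vapply(rings, function(v) oracle_boundary_distance(p, v, step),
                    numeric(1)))
  inside_count <- sum(vapply(rings, function(v) oracle_point_in_ring(p, v),
                             logical(1)))
  if (uns == 0) return(0)
  if (inside_count %% 2 == 1) -uns else uns
}

# --- registration -----------------------------------------------------------

random_similarity <- function() {
  similarity_transform(scale = exp(stats::runif(1, -0.5, 0.5)),
                       rotation = stats::runif(1, -pi, pi),
                       translation = stats::runif(2, -100, 100))
}

# sum of squared residuals of an arbitrary similarity on given pairs;
# written directly (no package code) so the optimizer stays independent
similarity_sse <- function(par, src, dst) {
  s <- exp(par[1])
  if (!is.finite(s)) return(1e300)
  R <- matrix(c(cos(par[2]), sin(par[2]), -sin(par[2]), cos(par[2])), 2, 2)
  pred <- s * (src %*% t(R))
  pred[, 1] <- pred[, 1] + par[3]
  pred[, 2] <- pred[, 2] + par[4]
  sum((pred - dst)^2)
}

# numeric-optimizer fit used as the least-squares oracle
oracle_fit_similarity_sse <- function(src, dst) {
  init <- c(0, 0, colMeans(dst) - colMeans(src))
  fit <- stats::optim(init, similarity_sse, src = src, dst = dst,
                      method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  fit$value
}

# --- deterministic staircase path enumeration -------------------------------

oracle_staircase_deterministic <- function(true_db, start = 25,
                                           range = c(0, 36)) {
  level <- start
  step <- 4
  reversals <- 0
  last_seen <- NA
  prev <- NA
  repeat {
    seen <- level <= true_db
    if (!seen && level <= range[1]) return(-1)
    if (seen) last_seen <- level
    if (!is.na(prev) && seen != prev) {
      reversals <- reversals + 1
      if (reversals == 1) step <- 2
      if (reversals == 2) break
    }
    prev <- seen
    nxt <- min(max(level + if (seen) step else -step, range[1]), range[2])
    if (nxt == level) break
    level <- nxt
  }
  if (is.na(last_seen)) -1 else last_seen
}
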