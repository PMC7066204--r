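#' A motile cell agent
#'
#' Cells are point agents that sense the attractant through saturable surface
#' receptors, steer with a persistent, locally biased random walk, move at
#' constant speed, and (optionally) degrade the attractant underneath them.
#' A cell interacts with every grid node within `overlap_radius` of its
#' centroid, and maintains a running average of its receptor occupancy over a
#' trailing one-minute window (a circular buffer of tick samples), which
#' drives both enzyme induction and the mitogenic response.
#'
#' @param position `c(x, y)` in um.
#' @param heading direction of motion, radians in (-pi, pi].
#' @param speed constant migration speed, um/min.
#' @param overlap_radius radius defining overlapped grid nodes, um.
#' @param kd receptor dissociation constant, nM.
#' @param vmax maximal degradation rate per cell, nM um^2 / min.
#' @param km Michaelis constant of the degrading activity, nM.
#' @param window_s trailing window of the occupancy average, s.
#' @param tick_s sampling interval of the occupancy window, s.
#' @return An object of class `cell_agent`.
#' @export
cell_agent <- function(position = c(0, 0), heading = 0, speed = 10,
                       overlap_radius = 6, kd = 12,
                       vmax = 6e6, km = 1500,
                       window_s = 60, tick_s = 1) {
  stopifnot(length(position) == 2, speed > 0, overlap_radius > 0,
            kd > 0, vmax > 0, km > 0, window_s > 0, tick_s > 0)
  W <- max(1L, as.integer(round(window_s / tick_s)))
  structure(list(
    position = as.numeric(position),
    heading = wrap_angle(heading),
    speed = speed,
    overlap_radius = overlap_radius,
    kd = kd, vmax = vmax, km = km,
    window_s = window_s, tick_s = tick_s,
    occ_buffer = numeric(W),
    buf_pos = 0L,
    primed = FALSE,     # buffer not yet filled by a first sense
    refractory = FALSE, # set after division, cleared once window refills
    samples_since_reset = W
  ), class = "cell_agent")
}

#' Motility parameters of the persistent biased random walk
#'
#' A new heading is proposed from a wrapped normal distribution centred on the
#' current heading (persistence), then a bias vector along the local
#' *occupancy* gradient direction is added. The bias magnitude is
#' `bias_strength * min(|grad y| / sensing_scale, 1)`: the steering response
#' saturates once the occupancy gradient across the cell is steep enough, and
#' fades linearly below `sensing_scale` (the receptor signal-to-steering gain).
#'
#' @param wrapped_normal_sigma dispersion of the heading proposal, radians.
#' @param bias_strength bias vector length at a fully legible gradient,
#'   relative to the unit persistence vector (dimensionless).
#' @param reorientation_interval time between direction updates, s.
#' @param sensing_scale occupancy-gradient magnitude (1/um) at which the
#'   steering bias saturates.
#' @param steering_floor minimum mean occupancy over the overlapped patch for
#'   any steering at all: with almost no bound receptors a cell has no
#'   directional information, however steep the relative gradient (the
#'   deterministic stand-in for receptor counting noise).
#' @return An object of class `motility_params`.
#' @export
motility_params <- function(wrapped_normal_sigma = 0.6, bias_strength = 3,
                            reorientation_interval = 5,
                            sensing_scale = 1e-3,
                            steering_floor = 0.005) {
  stopifnot(wrapped_normal_sigma > 0, bias_strength >= 0,
            reorientation_interval > 0, sensing_scale > 0,
            steering_floor >= 0, steering_floor < 1)
  structure(list(wrapped_normal_sigma = wrapped_normal_sigma,
                 bias_strength = bias_strength,
                 reorientation_interval = reorientation_interval,
                 sensing_scale = sensing_scale,
                 steering_floor = steering_floor),
            class = "motility_params")
}

#' Fractional receptor occupancy
#'
#' Single-site binding isotherm `y = c / (c + kd)`: the quantity cells
#' actually sense. Monotone in `c`, 1/2 at `c = kd`, saturating to 1.
#'
#' @param c attractant concentration, nM (vectorised).
#' @param kd receptor dissociation constant, nM.
#' @return Occupancy fraction in \[0, 1\].
#' @examples
#' receptor_occupancy(12, kd = 12)  # 0.5
#' @export
receptor_occupancy <- function(c, kd = 12) {
  if (any(c < 0)) stop("concentration must be non-negative")
  if (any(kd <= 0)) stop("kd must be positive")
  c / (c + kd)
}

#' Grid nodes overlapped by a cell
#'
#' All nodes whose centres lie within `overlap_radius` (Euclidean, inclusive)
#' of the cell centroid; never empty (falls back to the nearest node).
#'
#' @param cell a [cell_agent].
#' @param field an [attractant_field].
#' @return Integer matrix with columns `row`, `col` (1-based).
#' @export
overlapped_points <- function(cell, field) {
  stopifnot(inherits(cell, "cell_agent"), inherits(field, "attractant_field"))
  m <- cpp_overlap_nodes(cell$position[1], cell$position[2],
                         cell$overlap_radius, field$dx,
                         nrow(field$conc), ncol(field$conc))
  colnames(m) <- c("row", "col")
  m
}

#' Local concentration gradient seen by a cell
#'
#' Least-squares plane fit of concentration against position over the nodes
#' the cell overlaps; degenerate point sets (a single node, collinear nodes,
#' or a uniform field) give the zero vector.
#'
#' @param cell a [cell_agent].
#' @param field an [attractant_field].
#' @return `c(gx, gy)` in nM/um.
#' @export
local_gradient <- function(cell, field) {
  pts <- overlapped_points(cell, field)
  xs <- (pts[, "col"] - 1) * field$dx
  ys <- (pts[, "row"] - 1) * field$dx
  vs <- field$conc[pts]
  cpp_plane_gradient(xs, ys, vs)
}

#' Local receptor-occupancy gradient seen by a cell
#'
#' As [local_gradient()], but the plane is fitted to the receptor occupancy
#' `y(c) = c/(c + kd)` at each overlapped node. This is the signal that
#' actually steers cells: at saturating concentrations the occupancy gradient
#' collapses even when the concentration gradient is steep.
#'
#' @inheritParams local_gradient
#' @return `c(gx, gy)` in 1/um.
#' @export
occupancy_gradient <- function(cell, field) {
  pts <- overlapped_points(cell, field)
  xs <- (pts[, "col"] - 1) * field$dx
  ys <- (pts[, "row"] - 1) * field$dx
  vs <- receptor_occupancy(field$conc[pts], cell$kd)
  cpp_plane_gradient(xs, ys, vs)
}

#' Propose a new heading
#'
#' Draws a persistence direction from a wrapped normal centred on the current
#' heading, adds the saturating bias vector along the supplied occupancy
#' gradient, and returns the angle of the summed vector. A zero gradient
#' returns the pure persistence draw. Uses R's global RNG.
#'
#' @param cell a [cell_agent].
#' @param params a [motility_params].
#' @param gradient local occupancy gradient `c(gx, gy)`, 1/um (e.g. from
#'   [occupancy_gradient()]).
#' @param n number of independent proposals to draw.
#' @return `n` headings in radians.
#' @export
propose_heading <- function(cell, params, gradient = c(0, 0), n = 1) {
  stopifnot(inherits(cell, "cell_agent"), inherits(params, "motility_params"))
  gn <- sqrt(sum(gradient^2))
  b_eff <- if (gn > 0) {
    params$bias_strength * min(gn / params$sensing_scale, 1)
  } else 0
  cpp_propose_heading(as.integer(n), cell$heading,
                      params$wrapped_normal_sigma, b_eff,
                      gradient[1], gradient[2])
}

#' Move a cell at constant speed
#'
#' Advances the position by `speed * dt` along the current heading, reflecting
#' at the walkable-domain border (the normal heading component is inverted).
#'
#' @param cell a [cell_agent].
#' @param dt time step, s (>= 0).
#' @param extent walkable domain `c(Lx, Ly)` in um, e.g. [field_extent()].
#' @return The moved cell.
#' @export
move_cell <- function(cell, dt, extent) {
  stopifnot(inherits(cell, "cell_agent"), dt >= 0, length(extent) == 2)
  step <- cell$speed / 60 * dt
  x <- cell$position[1] + step * cos(cell$heading)
  y <- cell$position[2] + step * sin(cell$heading)
  h <- cell$heading
  if (x < 0)         { x <- -x;                h <- wrap_angle(pi - h) }
  if (x > extent[1]) { x <- 2 * extent[1] - x; h <- wrap_angle(pi - h) }
  if (y < 0)         { y <- -y;                h <- wrap_angle(-h) }
  if (y > extent[2]) { y <- 2 * extent[2] - y; h <- wrap_angle(-h) }
  cell$position <- c(x, y)
  cell$heading <- h
  cell
}

#' Update the trailing occupancy average
#'
#' Pushes an instantaneous occupancy sample into the cell's sliding one-minute
#' window (a circular buffer of `window_s / dt` samples). The first sample
#' primes the whole window (cells are assumed equilibrated to the field they
#' are placed in); after a mitotic reset the window refills sample by sample.
#'
#' @param cell a [cell_agent].
#' @param y_now instantaneous occupancy in \[0, 1\].
#' @param dt sample spacing, s; if it differs from the cell's configured tick
#'   the window is re-discretised to `round(window_s / dt)` slots.
#' @return The updated cell (see `occupancy_average()` for the average).
#' @export
update_occupancy_average <- function(cell, y_now, dt = cell$tick_s) {
  stopifnot(inherits(cell, "cell_agent"), y_now >= 0, y_now <= 1, dt > 0)
  W <- max(1L, as.integer(round(cell$window_s / dt)))
  if (W != length(cell$occ_buffer)) {
    cell$occ_buffer <- numeric(W)
    cell$buf_pos <- 0L
    cell$primed <- FALSE
    cell$tick_s <- dt
  }
  if (!cell$primed) {
    cell$occ_buffer[] <- y_now
    cell$buf_pos <- 0L
    cell$primed <- TRUE
    cell$samples_since_reset <- W
  } else {
    cell$occ_buffer[cell$buf_pos + 1L] <- y_now
    cell$buf_pos <- (cell$buf_pos + 1L) %% W
    cell$samples_since_reset <- cell$samples_since_reset + 1L
  }
  if (cell$refractory && cell$samples_since_reset >= W) cell$refractory <- FALSE
  cell
}

#' Trailing-window occupancy average of a cell
#'
#' @param cell a [cell_agent].
#' @return Mean occupancy over the trailing window, in \[0, 1\].
#' @export
occupancy_average <- function(cell) {
  if (!cell$primed) return(0)
  mean(cell$occ_buffer)
}

#' @export
print.cell_agent <- function(x, ...) {
  cat("<cell_agent> at (", format(x$position[1], digits = 5), ", ",
      format(x$position[2], digits = 5), ") um, heading ",
      format(x$heading, digits = 3), " rad\n", sep = "")
  cat("  speed ", x$speed, " um/min; Kd ", x$kd, " nM; Vmax ", x$vmax,
      " nM um^2/min; Km ", x$km, " nM\n", sep = "")
  cat("  occupancy average ", format(occupancy_average(x), digits = 4),
      if (x$refractory) " (refractory)" else "", "\n", sep = "")
  invisible(x)
}

wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  ifelse(a == -pi, pi, a)
}
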