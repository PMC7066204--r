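#' @title Assay scoring statistics
#' @description Pure functions of a tidy trajectory table (as produced by
#' [run_scenario()]): the same trajectory always gives the same score.
#' Bridge-axis distances are displacements along x from each cell's own start
#' position, which makes the scores robust to the width of the seeding region.
#' @name scoring
NULL

# rows of the latest recorded time <= t (error when t is beyond the run)
traj_at <- function(traj, t) {
  times <- unique(traj$time_s)
  if (t < 0 || t > max(times) + 1e-9)
    stop("time ", t, " s is beyond the recorded trajectory")
  tt <- max(times[times <= t + 1e-9])
  traj[traj$time_s == tt, , drop = FALSE]
}

# per-cell displacement along x from own first recorded position
axis_displacement <- function(traj, t) {
  first <- traj[!duplicated(traj$cell_id), , drop = FALSE]
  now <- traj_at(traj, t)
  now$x_um - first$x_um[match(now$cell_id, first$cell_id)]
}

#' Response score: fraction of cells passing a distance threshold
#'
#' The fraction of *initially seeded* cells whose displacement along the assay
#' axis from their own start exceeds `distance` at time `t` (cells born later
#' by mitosis are not counted in the denominator).
#'
#' @param traj trajectory tibble from [run_scenario()].
#' @param distance threshold, um.
#' @param t scoring time, s.
#' @return Fraction in \[0, 1\].
#' @export
score_response <- function(traj, distance = 400, t = 3600) {
  seeded <- traj$cell_id[traj$time_s == min(traj$time_s)]
  disp <- axis_displacement(traj, t)
  ids <- traj_at(traj, t)$cell_id
  mean(disp[ids %in% seeded] > distance)
}

#' Time for n cells to pass a distance
#'
#' First recorded time at which at least `n` distinct cells have reached axis
#' position `x` um (relative to `origin`); censored when that never happens
#' within the trajectory.
#'
#' @param traj trajectory tibble.
#' @param n number of cells required.
#' @param x axis position threshold, um.
#' @param origin axis origin, um (e.g. the bridge entrance).
#' @return `list(time_s, censored)`; `time_s` is `NA` when censored.
#' @export
time_to_pass <- function(traj, n = 100, x = 1000, origin = 0) {
  for (tt in sort(unique(traj$time_s))) {
    rows <- traj[traj$time_s == tt, , drop = FALSE]
    if (sum(rows$x_um - origin >= x) >= n)
      return(list(time_s = tt, censored = FALSE))
  }
  list(time_s = NA_real_, censored = TRUE)
}

#' Mean distance of the leading k cells
#'
#' @param traj trajectory tibble.
#' @param k number of front-most cells.
#' @param t scoring time, s.
#' @return Mean axis displacement of the k front-most cells, um.
#' @export
leading_distance <- function(traj, k = 10, t) {
  disp <- axis_displacement(traj, t)
  if (length(disp) < k) stop("fewer than k = ", k, " cells alive at t")
  mean(sort(disp, decreasing = TRUE)[seq_len(k)])
}

#' Mean radial distance of the leading k cells
#'
#' Radial displacement is each cell's distance from `center` at time `t`
#' minus its distance at first appearance.
#'
#' @param traj trajectory tibble.
#' @param k number of front-most cells.
#' @param t scoring time, s.
#' @param center `c(x, y)` of the well centre, um.
#' @return Mean radial displacement of the k front-most cells, um.
#' @export
radial_leading_distance <- function(traj, k = 10, t, center) {
  first <- traj[!duplicated(traj$cell_id), , drop = FALSE]
  now <- traj_at(traj, t)
  r0 <- sqrt((first$x_um - center[1])^2 + (first$y_um - center[2])^2)
  r1 <- sqrt((now$x_um - center[1])^2 + (now$y_um - center[2])^2)
  dr <- r1 - r0[match(now$cell_id, first$cell_id)]
  if (length(dr) < k) stop("fewer than k = ", k, " cells alive at t")
  mean(sort(dr, decreasing = TRUE)[seq_len(k)])
}

#' Two-spot positivity score
#'
#' Splits the scene by the line through the original cell-drop centre,
#' perpendicular to the spot-to-spot axis, and scores positive when at least
#' twice as many cells lie in the attractant-facing half as in the far half.
#'
#' @param traj trajectory tibble (or a two-column matrix of positions).
#' @param t scoring time, s (trajectory input only; default: end of record).
#' @param center `c(x, y)` of the original cell-drop centre, um.
#' @param direction unit vector from cell drop towards the attractant spot.
#' @return `list(positive, front, back)`.
#' @export
score_two_spot <- function(traj, t = NULL, center, direction = c(1, 0)) {
  if (is.matrix(traj)) {
    pos <- traj
  } else {
    if (is.null(t)) t <- max(traj$time_s)
    rows <- traj_at(traj, t)
    pos <- cbind(rows$x_um, rows$y_um)
  }
  u <- direction / sqrt(sum(direction^2))
  proj <- (pos[, 1] - center[1]) * u[1] + (pos[, 2] - center[2]) * u[2]
  front <- sum(proj > 0)
  back <- sum(proj < 0)
  list(positive = front >= 2 * back, front = front, back = back)
}

# assay-level statistics for a finished run, dispatched on geometry
score_scenario <- function(result) {
  spec <- result$spec
  traj <- result$trajectories
  g <- spec$geometry
  if (nrow(traj) == 0)
    return(structure(list(geometry = g$type), class = "score_result"))
  t_end <- max(traj$time_s)
  out <- list(geometry = g$type)
  if (g$type == "bridge") {
    out$response_score <- score_response(traj, distance = 400,
                                         t = min(3600, t_end))
    ttp <- time_to_pass(traj, n = min(100, spec$cells$n), x = g$length,
                        origin = bridge_x_start(spec))
    out$time_to_pass_s <- ttp$time_s
    out$time_to_pass_censored <- ttp$censored
    k <- min(10, spec$cells$n)
    disp <- axis_displacement(traj, t_end)
    out$leading_distances_um <- sort(disp, decreasing = TRUE)[seq_len(k)]
  } else if (g$type == "disc_well") {
    ctr <- c(g$arena / 2, g$arena / 2)
    out$radial_leading_um <- radial_leading_distance(
      traj, k = min(10, spec$cells$n), t = t_end, center = ctr)
  } else {
    ctr <- two_spot_centers(spec)
    ts <- score_two_spot(traj, t = t_end, center = ctr$cells)
    out$two_spot_positive <- ts$positive
    out$front_count <- ts$front
    out$back_count <- ts$back
  }
  structure(out, class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat("<score_result> (", x$geometry, ")\n", sep = "")
  if (!is.null(x$response_score))
    cat("  response score: ", format(x$response_score, digits = 4), "\n", sep = "")
  if (!is.null(x$time_to_pass_s))
    cat("  time to pass: ",
        if (x$time_to_pass_censored) "censored"
        else paste0(x$time_to_pass_s, " s"), "\n", sep = "")
  if (!is.null(x$leading_distances_um))
    cat("  leading cells, mean distance: ",
        format(mean(x$leading_distances_um), digits = 5), " um\n", sep = "")
  if (!is.null(x$radial_leading_um))
    cat("  radial leading distance: ", format(x$radial_leading_um, digits = 5),
        " um\n", sep = "")
  if (!is.null(x$two_spot_positive))
    cat("  two-spot: ", if (x$two_spot_positive) "POSITIVE" else "negative",
        " (front ", x$front_count, " / back ", x$back_count, ")\n", sep = "")
  invisible(x)
}
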