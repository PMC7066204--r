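#' Initialise a simulation state from a scenario
#'
#' Seeds the RNG from the scenario, builds the attractant field and the cell
#' population, bootstraps the two-level diffusion scheme, and returns the
#' opaque state advanced by [sim_advance()]. The field sub-step is chosen
#' automatically as the largest step with `D dt / dx^2 <= alpha_max` that
#' divides the agent tick evenly.
#'
#' @param spec a validated scenario (see [build_bridge()] and friends).
#' @return An object of class `sgg_state`.
#' @export
sim_state_init <- function(spec) {
  spec <- validate_scenario(spec)
  set.seed(spec$seed)
  fld <- scenario_field(spec)
  cells <- scenario_cells(spec)

  dt_max <- spec$alpha_max * spec$field$dx^2 / spec$field$D
  n_sub <- max(1L, as.integer(ceiling(spec$tick_s / dt_max)))

  # bootstrap: one FTCS block covering a single field sub-step
  dt_f <- spec$tick_s / n_sub
  fi <- fixed_indices0(fld)
  m <- max(1L, ceiling(dt_f / (0.25 * fld$dx^2 / fld$D)))
  cur <- fld$conc
  for (s in seq_len(m))
    cur <- cpp_ftcs_step(cur, fld$D, fld$dx, dt_f / m, fi, fld$fixed_values)
  prev <- fld$conc
  W <- max(1L, as.integer(round(60 / spec$tick_s)))
  n <- nrow(cells)

  state <- list(
    conc = cur, prev = prev, dx = fld$dx, D = fld$D,
    fixed_idx = fi, fixed_vals = fld$fixed_values,
    fixed_mask = fld$fixed_mask,
    cumulative_degraded = 0, clamped_mass = 0,
    time = 0, tick = 0L, next_id = n + 1L,
    cells = cells,
    occ_buf = matrix(0, W, n), buf_pos = integer(n),
    buf_primed = logical(n),
    n_sub = n_sub, window_ticks = W,
    spec = spec,
    initial_mass = sum(fld$conc) * fld$dx^2,
    start = cells[, 1:3, drop = FALSE],   # id, x0, y0
    traj = list(), divisions = list(), snapshots = list()
  )
  class(state) <- "sgg_state"
  state$snapshots[[1]] <- list(time = 0, conc = fld$conc)
  state
}

run_params <- function(state) {
  spec <- state$spec
  list(
    tick_s = spec$tick_s, n_sub = state$n_sub,
    speed_um_min = spec$cells$speed, sigma = spec$motility$wrapped_normal_sigma,
    bias_strength = spec$motility$bias_strength,
    sensing_scale = spec$motility$sensing_scale,
    steering_floor = spec$motility$steering_floor,
    reorient_ticks = max(1L, as.integer(round(
      spec$motility$reorientation_interval / spec$tick_s))),
    kd = spec$cells$kd, vmax = spec$cells$vmax, km = spec$cells$km,
    overlap_radius = spec$cells$overlap_radius,
    deg_mode = match(spec$logic$degradation,
                     c("none", "always_on", "induced")) - 1L,
    vb = spec$induction$vb, ki = spec$induction$ki, h = spec$induction$h,
    mitogen = isTRUE(spec$logic$mitogen),
    mitogen_floor = spec$mitogen$occupancy_floor,
    min_division_time_min = spec$mitogen$min_division_time,
    record_ticks = max(1L, as.integer(round(spec$record_every_s / spec$tick_s))),
    window_ticks = state$window_ticks,
    max_cells = spec$max_cells
  )
}

#' Advance a simulation state by whole agent ticks
#'
#' One tick is: (1) field diffusion sub-steps spanning the tick, (2) per cell,
#' in stable id order - sense and update the occupancy window, degrade (if
#' enabled), reorient (at the reorientation interval), move, maybe divide (if
#' the attractant is mitogenic), (3) record at the recording cadence.
#'
#' @param state an `sgg_state` from [sim_state_init()].
#' @param n_ticks number of agent ticks to advance.
#' @return The advanced state; recorded rows accumulate inside it.
#' @export
sim_advance <- function(state, n_ticks = 1L) {
  stopifnot(inherits(state, "sgg_state"), n_ticks >= 0)
  if (n_ticks == 0) return(state)
  out <- cpp_run(state, run_params(state), as.integer(n_ticks))
  for (nm in c("conc", "prev", "cumulative_degraded", "clamped_mass", "time",
               "tick", "next_id", "cells", "occ_buf", "buf_pos", "buf_primed"))
    state[[nm]] <- out[[nm]]
  if (nrow(out$traj) > 0) state$traj[[length(state$traj) + 1]] <- out$traj
  if (nrow(out$divisions) > 0)
    state$divisions[[length(state$divisions) + 1]] <- out$divisions
  state
}

#' Run a scenario end to end
#'
#' Initialises the state, advances it to the scenario duration (capturing
#' field snapshots at the snapshot cadence), assembles the tidy trajectory
#' table, and computes the scenario's scoring statistics.
#'
#' @param spec a scenario from one of the builders or [load_scenario()].
#' @param verbose emit a structured run log via `message()`: the resolved
#'   headline parameters, progress while the simulation advances, and the
#'   mass-balance check at the end.
#' @return An object of class `sgg_result`: a list with `trajectories`
#'   (tibble: time_s, cell_id, x_um, y_um, heading_rad, occupancy,
#'   occupancy_avg, event), `divisions` (tibble: time_s, mother, daughter),
#'   `field` (final [attractant_field]), `snapshots`, `score` (a
#'   `score_result`), `mass_balance`, and the echoed `spec`.
#' @examples
#' \donttest{
#' spec <- build_bridge(concentration = 300, mode = "self", n_cells = 20,
#'                      duration_s = 600, seed = 1)
#' res <- run_scenario(spec)
#' res$score$response_score
#' }
#' @export
run_scenario <- function(spec, verbose = FALSE) {
  spec <- validate_scenario(spec)
  state <- sim_state_init(spec)
  if (verbose)
    message(sprintf(
      "run: %s | %d cells | %g nM | degradation %s | mitogen %s | %g s | seed %d",
      spec$geometry$type, spec$cells$n,
      if (spec$field$mode == "uniform") spec$field$c0 else spec$field$c_high,
      spec$logic$degradation, spec$logic$mitogen, spec$duration_s, spec$seed))
  total_ticks <- as.integer(round(spec$duration_s / spec$tick_s))
  snap_ticks <- if (spec$snapshot_every_s > 0)
    max(1L, as.integer(round(spec$snapshot_every_s / spec$tick_s))) else total_ticks
  done <- 0L
  while (done < total_ticks) {
    chunk <- min(snap_ticks, total_ticks - done)
    state <- sim_advance(state, chunk)
    done <- done + chunk
    state$snapshots[[length(state$snapshots) + 1]] <-
      list(time = state$time, conc = state$conc)
    if (verbose)
      message(sprintf("  t = %6.0f s  cells %5d  degraded %.4g",
                      state$time, nrow(state$cells),
                      state$cumulative_degraded))
  }

  traj <- assemble_trajectories(state)
  divisions <- assemble_divisions(state)
  fld <- state_field(state)
  final_mass <- field_mass(fld)
  result <- structure(list(
    trajectories = traj,
    divisions = divisions,
    field = fld,
    snapshots = state$snapshots,
    spec = spec,
    n_cells_final = nrow(state$cells),
    mass_balance = list(
      initial = state$initial_mass, final = final_mass,
      degraded = state$cumulative_degraded,
      clamped = state$clamped_mass)
  ), class = "sgg_result")
  result$score <- score_scenario(result)
  if (verbose) {
    mb <- result$mass_balance
    message(sprintf(
      "mass balance: initial %.6g, final %.6g, degraded %.6g, clamped %.3g (residual %.3g)",
      mb$initial, mb$final, mb$degraded, mb$clamped,
      mb$initial - mb$final - mb$degraded + mb$clamped))
  }
  result
}

# rebuild an attractant_field object from the raw state
state_field <- function(state) {
  f <- structure(list(
    conc = state$conc, prev = state$prev, dx = state$dx, D = state$D,
    fixed_mask = state$fixed_mask,
    fixed_values = state$fixed_vals,
    cumulative_degraded = state$cumulative_degraded,
    clamped_mass = state$clamped_mass,
    bootstrapped = TRUE
  ), class = "attractant_field")
  f
}

assemble_trajectories <- function(state) {
  spec <- state$spec
  # t = 0 rows for the initial population
  n0 <- nrow(state$start)
  if (n0 == 0 && length(state$traj) == 0) {
    return(tibble::tibble(time_s = numeric(), cell_id = integer(),
                          x_um = numeric(), y_um = numeric(),
                          heading_rad = numeric(), occupancy = numeric(),
                          occupancy_avg = numeric(), event = character()))
  }
  j <- pmin(pmax(round(state$start[, 2] / state$dx), 0),
            ncol(state$snapshots[[1]]$conc) - 1) + 1
  i <- pmin(pmax(round(state$start[, 3] / state$dx), 0),
            nrow(state$snapshots[[1]]$conc) - 1) + 1
  occ0 <- receptor_occupancy(state$snapshots[[1]]$conc[cbind(i, j)],
                             spec$cells$kd)
  rows0 <- cbind(0, state$start[, 1], state$start[, 2], state$start[, 3],
                 0, occ0, occ0, 0)
  m <- do.call(rbind, c(list(rows0), state$traj))
  tibble::tibble(
    time_s = m[, 1],
    cell_id = as.integer(m[, 2]),
    x_um = m[, 3],
    y_um = m[, 4],
    heading_rad = m[, 5],
    occupancy = m[, 6],
    occupancy_avg = m[, 7],
    event = ifelse(m[, 8] > 0, "division", "none")
  )
}

assemble_divisions <- function(state) {
  if (length(state$divisions) == 0)
    return(tibble::tibble(time_s = numeric(), mother = integer(),
                          daughter = integer()))
  m <- do.call(rbind, state$divisions)
  tibble::tibble(time_s = m[, 1], mother = as.integer(m[, 2]),
                 daughter = as.integer(m[, 3]))
}

#' @export
print.sgg_result <- function(x, ...) {
  cat("<sgg_result> ", x$spec$geometry$type, " scenario, seed ", x$spec$seed,
      ", ", x$spec$duration_s, " s\n", sep = "")
  cat("  cells: ", length(unique(x$trajectories$cell_id)), " total (",
      nrow(x$divisions), " divisions)\n", sep = "")
  mb <- x$mass_balance
  cat("  attractant mass: ", format(mb$initial, digits = 6), " -> ",
      format(mb$final, digits = 6), " (degraded ",
      format(mb$degraded, digits = 6), ")\n", sep = "")
  print(x$score)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
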