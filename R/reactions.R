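#' Michaelis-Menten degradation rate
#'
#' The rate at which a cell's surface enzymes (or internalising receptors; the
#' two are formally equivalent) remove attractant:
#' `r = vmax * c / (c + km)`.
#'
#' @param c local attractant concentration, nM (vectorised).
#' @param vmax maximal degradation rate, nM um^2 / min.
#' @param km Michaelis constant, nM.
#' @return Degradation rate in the units of `vmax`.
#' @examples
#' mm_rate(500, vmax = 1e6, km = 500)  # half-saturation: vmax / 2
#' @export
mm_rate <- function(c, vmax, km) {
  if (any(c < 0)) stop("concentration must be non-negative")
  stopifnot(all(km > 0), all(vmax >= 0))
  vmax * c / (c + km)
}

#' Parameters of occupancy-induced enzyme expression
#'
#' When degradation is inducible, the effective Vmax is multiplied by a Hill
#' factor of the trailing-minute receptor occupancy:
#' `vb + (1 - vb) * y^h / (ki^h + y^h)` - basal activity `vb` at rest,
#' switch-like induction around occupancy `ki` with steepness `h`.
#'
#' @param enabled logical; `FALSE` means constitutive (factor identically 1).
#' @param vb basal activity fraction.
#' @param ki occupancy of half-activity.
#' @param h Hill coefficient.
#' @return An object of class `induction_params`.
#' @export
induction_params <- function(enabled = TRUE, vb = 0.05, ki = 0.4, h = 2) {
  stopifnot(is.logical(enabled), vb >= 0, vb <= 1, ki > 0, ki < 1, h >= 1)
  structure(list(enabled = enabled, vb = vb, ki = ki, h = h),
            class = "induction_params")
}

#' Induced-activity factor
#'
#' @param y_avg trailing-average receptor occupancy in \[0, 1\] (vectorised).
#' @param params an [induction_params].
#' @return Multiplier on Vmax: 1 when induction is disabled, otherwise the
#'   Hill factor, bounded in `[vb, 1)` and non-decreasing in `y_avg`.
#' @examples
#' induction_factor(0.4, induction_params())  # vb + (1 - vb)/2 = 0.525
#' @export
induction_factor <- function(y_avg, params = induction_params()) {
  stopifnot(inherits(params, "induction_params"),
            all(y_avg >= 0), all(y_avg <= 1))
  if (!params$enabled) return(rep(1, length(y_avg)))
  with(params, vb + (1 - vb) * y_avg^h / (ki^h + y_avg^h))
}

#' Degrade attractant under a cell for one tick
#'
#' Computes the cell-level Michaelis-Menten rate from the mean concentration
#' over the overlapped nodes (scaled by the induction factor of the cell's
#' running-average occupancy when induction is enabled) and removes the mass
#' `r * dt` split evenly across those nodes. Each node is clamped at zero and
#' only the mass actually removed is added to the field's
#' `cumulative_degraded` tally. Both time levels of the field are decremented
#' identically so the leapfrog scheme sees a consistent sink.
#'
#' @param cell a [cell_agent].
#' @param field an [attractant_field].
#' @param induction an [induction_params]; pass `induction_params(enabled =
#'   FALSE)` for constitutive degradation.
#' @param dt tick length, s.
#' @return The field after removal.
#' @export
degrade_step <- function(cell, field, induction = induction_params(enabled = FALSE),
                         dt = 1) {
  stopifnot(inherits(cell, "cell_agent"), inherits(field, "attractant_field"),
            dt > 0)
  pts <- overlapped_points(cell, field)
  idx <- cbind(pts[, "row"], pts[, "col"])
  c_local <- mean(field$conc[idx])
  if (c_local <= 0) return(field)
  veff <- cell$vmax * induction_factor(occupancy_average(cell), induction)
  r <- mm_rate(c_local, veff, cell$km)            # nM um^2 / min
  np <- nrow(idx)
  dconc <- r * (dt / 60) / (np * field$dx^2)      # per-node decrement, nM
  avail <- pmax(pmin(field$conc[idx], field$prev[idx]), 0)
  d <- pmin(dconc, avail)
  field$conc[idx] <- field$conc[idx] - d
  field$prev[idx] <- field$prev[idx] - d
  field$cumulative_degraded <- field$cumulative_degraded + sum(d) * field$dx^2
  field
}

#' Parameters of the mitogenic response
#'
#' When the attractant is also a mitogen, well-fed cells divide: the expected
#' time to the next mitosis interpolates from infinite at a minimum trailing
#' occupancy (`occupancy_floor`) down to `min_division_time` at full occupancy.
#'
#' @param enabled logical.
#' @param occupancy_floor minimum average occupancy for any division.
#' @param min_division_time expected division time at occupancy 1, minutes.
#' @return An object of class `mitogen_params`.
#' @export
mitogen_params <- function(enabled = TRUE, occupancy_floor = 0.35,
                           min_division_time = 1) {
  stopifnot(is.logical(enabled), occupancy_floor > 0, occupancy_floor < 1,
            min_division_time > 0)
  structure(list(enabled = enabled, occupancy_floor = occupancy_floor,
                 min_division_time = min_division_time),
            class = "mitogen_params")
}

#' Division rate at a given trailing occupancy
#'
#' The division *rate* is interpolated linearly: zero at the occupancy floor,
#' `1 / min_division_time` at occupancy 1 (so the expected waiting time is
#' exactly infinite at the floor and exactly `min_division_time` at full
#' occupancy, with no extra parameters).
#'
#' @param y_avg trailing-average occupancy in \[0, 1\] (vectorised).
#' @param params a [mitogen_params].
#' @return Division rate, per minute.
#' @examples
#' 1 / division_rate(0.675, mitogen_params())  # expected time 2 min
#' @export
division_rate <- function(y_avg, params = mitogen_params()) {
  stopifnot(inherits(params, "mitogen_params"), all(y_avg >= 0), all(y_avg <= 1))
  pmax(0, (y_avg - params$occupancy_floor) / (1 - params$occupancy_floor)) /
    params$min_division_time
}

#' Stochastic division of a cell in one tick
#'
#' Division fires as a Poisson event with probability `1 - exp(-lambda * dt)`.
#' On division the daughter appears at the mother's position with an
#' independently drawn uniform heading, and *both* cells have their occupancy
#' window reset to zero - the refractory period emerges because a zeroed
#' window keeps the division rate at zero until it refills above the floor.
#' Uses R's global RNG.
#'
#' @param cell a [cell_agent].
#' @param params a [mitogen_params].
#' @param dt tick length, s.
#' @return `list(cell = mother, daughter = <cell_agent> or NULL)`.
#' @export
maybe_divide <- function(cell, params = mitogen_params(), dt = 1) {
  stopifnot(inherits(cell, "cell_agent"), inherits(params, "mitogen_params"),
            dt > 0)
  if (!params$enabled) return(list(cell = cell, daughter = NULL))
  lambda <- division_rate(occupancy_average(cell), params)
  if (lambda <= 0 || stats::runif(1) >= 1 - exp(-lambda * dt / 60))
    return(list(cell = cell, daughter = NULL))
  daughter <- cell
  daughter$heading <- wrap_angle(stats::runif(1, -pi, pi))
  reset <- function(cl) {
    cl$occ_buffer[] <- 0
    cl$buf_pos <- 0L
    cl$primed <- TRUE
    cl$refractory <- TRUE
    cl$samples_since_reset <- 0L
    cl
  }
  list(cell = reset(cell), daughter = reset(daughter))
}
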