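#' @title Scenario objects
#' @description A scenario is a complete declarative description of one
#' in-silico assay: geometry, initial attractant field, cell population and
#' kinetics, motility, degradation/mitogen logic, duration, seed and
#' recording cadence. Scenarios are built with [build_bridge()],
#' [build_disc_well()], [build_two_spot()] or [build_population_scan()], or
#' loaded from YAML with [load_scenario()].
#' @name scenario
NULL

scenario_defaults <- function() {
  list(
    field = list(dx = 4, D = 150, mode = "uniform", c0 = 300,
                 c_low = 0, c_high = 300, prefill = "steady"),
    cells = list(n = 100L, speed = 10, overlap_radius = 6, kd = 12,
                 vmax = 6e6, km = 1500, seed_depth = 40),
    motility = list(wrapped_normal_sigma = 0.6, bias_strength = 3,
                    reorientation_interval = 5, sensing_scale = 1e-3,
                    steering_floor = 0.005),
    logic = list(degradation = "none", mitogen = FALSE),
    induction = list(vb = 0.05, ki = 0.4, h = 2),
    mitogen = list(occupancy_floor = 0.35, min_division_time = 1),
    duration_s = 3600, seed = 1L,
    record_every_s = 60, snapshot_every_s = 0,
    tick_s = 1, alpha_max = 0.75, max_cells = 20000L,
    derived = NULL
  )
}

# geometry keys are type-specific; each type has its own default block
geometry_defaults <- function(type) {
  switch(as.character(type),
    bridge = list(type = "bridge", length = 1000, width = 200,
                  reservoir_length = 1000, strip_width = 40),
    disc_well = list(type = "disc_well", well_radius = 1000, arena = 4000),
    two_spot = list(type = "two_spot", spot_radius = 400, separation = 1000,
                    arena = c(3200, 1600)),
    stop("invalid scenario: geometry$type must be bridge, disc_well or two_spot",
         call. = FALSE))
}

# deep-merge user values into defaults, rejecting unknown keys
merge_spec <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("unknown scenario field(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  for (nm in names(user)) {
    if (is.null(user[[nm]])) next   # NULL would delete the slot, not set it
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_spec(defaults[[nm]], as.list(user[[nm]]),
                                   paste0(path, nm, "$"))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

new_scenario <- function(...) {
  user <- list(...)
  geom_user <- as.list(user$geometry)
  user$geometry <- NULL
  spec <- merge_spec(scenario_defaults(), user)
  gdef <- geometry_defaults(geom_user$type %||% "bridge")
  unknown <- setdiff(names(geom_user), names(gdef))
  if (length(unknown) > 0)
    stop("unknown scenario field(s): ",
         paste0("geometry$", unknown, collapse = ", "), call. = FALSE)
  spec$geometry <- utils::modifyList(gdef, geom_user)
  class(spec) <- "sgg_scenario"
  validate_scenario(spec)
}

#' Validate a scenario
#'
#' Checks geometry dimensions, concentrations, kinetic and motility
#' parameters, logic flags and run controls; errors name the offending field.
#'
#' @param spec a scenario list.
#' @return The validated scenario (invisibly usable downstream).
#' @export
validate_scenario <- function(spec) {
  fail <- function(field, msg) stop("invalid scenario: ", field, " ", msg,
                                    call. = FALSE)
  g <- spec$geometry
  if (!g$type %in% c("bridge", "disc_well", "two_spot"))
    fail("geometry$type", "must be bridge, disc_well or two_spot")
  num_pos <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0
  if (g$type == "bridge") {
    for (f in c("length", "width", "reservoir_length", "strip_width"))
      if (!num_pos(g[[f]])) fail(paste0("geometry$", f), "must be positive")
  } else if (g$type == "disc_well") {
    if (!num_pos(g$well_radius)) fail("geometry$well_radius", "must be positive")
    if (!num_pos(g$arena)) fail("geometry$arena", "must be positive")
    if (g$arena <= 2 * g$well_radius)
      fail("geometry$arena", "must exceed the well diameter")
  } else {
    for (f in c("spot_radius", "separation"))
      if (!num_pos(g[[f]])) fail(paste0("geometry$", f), "must be positive")
    if (g$spot_radius >= g$separation)
      fail("geometry$spot_radius", "must be smaller than the separation")
    if (!is.numeric(g$arena) || length(g$arena) != 2 || any(g$arena <= 0))
      fail("geometry$arena", "must be c(Lx, Ly) > 0")
  }
  fl <- spec$field
  if (!fl$mode %in% c("uniform", "imposed"))
    fail("field$mode", "must be uniform or imposed")
  if (!num_pos(fl$dx)) fail("field$dx", "must be positive")
  if (!num_pos(fl$D)) fail("field$D", "must be positive")
  if (fl$mode == "uniform") {
    if (!is.numeric(fl$c0) || fl$c0 < 0) fail("field$c0", "must be >= 0")
  } else {
    if (!is.numeric(fl$c_low) || fl$c_low < 0) fail("field$c_low", "must be >= 0")
    if (!is.numeric(fl$c_high) || fl$c_high < fl$c_low)
      fail("field$c_high", "must be >= c_low")
    if (!fl$prefill %in% c("steady", "empty"))
      fail("field$prefill", "must be steady or empty")
  }
  cl <- spec$cells
  # n = 0 is allowed for pure-diffusion runs
  if (!is.numeric(cl$n) || cl$n < 0) fail("cells$n", "must be >= 0")
  for (f in c("speed", "overlap_radius", "kd", "vmax", "km"))
    if (!num_pos(cl[[f]])) fail(paste0("cells$", f), "must be positive")
  mo <- spec$motility
  if (!num_pos(mo$wrapped_normal_sigma))
    fail("motility$wrapped_normal_sigma", "must be positive")
  if (!is.numeric(mo$bias_strength) || mo$bias_strength < 0)
    fail("motility$bias_strength", "must be >= 0")
  if (!num_pos(mo$reorientation_interval))
    fail("motility$reorientation_interval", "must be positive")
  if (!num_pos(mo$sensing_scale)) fail("motility$sensing_scale", "must be positive")
  if (!is.numeric(mo$steering_floor) || mo$steering_floor < 0 ||
      mo$steering_floor >= 1)
    fail("motility$steering_floor", "must be in [0, 1)")
  if (!spec$logic$degradation %in% c("none", "always_on", "induced"))
    fail("logic$degradation", "must be none, always_on or induced")
  if (!is.logical(spec$logic$mitogen))
    fail("logic$mitogen", "must be logical")
  ind <- spec$induction
  if (ind$vb < 0 || ind$vb > 1) fail("induction$vb", "must be in [0, 1]")
  if (ind$ki <= 0 || ind$ki >= 1) fail("induction$ki", "must be in (0, 1)")
  if (ind$h < 1) fail("induction$h", "must be >= 1")
  mi <- spec$mitogen
  if (mi$occupancy_floor <= 0 || mi$occupancy_floor >= 1)
    fail("mitogen$occupancy_floor", "must be in (0, 1)")
  if (!num_pos(mi$min_division_time))
    fail("mitogen$min_division_time", "must be positive")
  if (!is.numeric(spec$duration_s) || spec$duration_s < 0)
    fail("duration_s", "must be >= 0")
  if (!num_pos(spec$record_every_s)) fail("record_every_s", "must be positive")
  if (!num_pos(spec$tick_s)) fail("tick_s", "must be positive")
  spec$seed <- as.integer(spec$seed)
  spec$cells$n <- as.integer(spec$cells$n)
  spec$max_cells <- as.integer(spec$max_cells)
  spec
}

# lattice dimensions for a physical extent (nodes at 0, dx, ..., ~L)
lat_dim <- function(L, dx) as.integer(round(L / dx)) + 1L

#' @rdname scenario
#' @param spec a scenario.
#' @export
scenario_field <- function(spec) {
  g <- spec$geometry; fl <- spec$field
  if (g$type == "bridge") {
    pad <- if (fl$mode == "imposed") g$strip_width else g$reservoir_length
    nc <- lat_dim(g$length + 2 * pad, fl$dx)
    nr <- lat_dim(g$width, fl$dx)
    xs <- (seq_len(nc) - 1) * fl$dx
    if (fl$mode == "uniform") {
      attractant_field(c(nr, nc), fl$dx, fl$D, conc = fl$c0)
    } else {
      x0 <- g$strip_width; x1 <- g$strip_width + g$length
      ramp <- fl$c_low + (fl$c_high - fl$c_low) *
        pmin(pmax((xs - x0) / (x1 - x0), 0), 1)
      if (fl$prefill == "empty")
        ramp <- ifelse(xs > x1, fl$c_high, fl$c_low)
      conc <- matrix(rep(ramp, each = nr), nr, nc)
      mask <- matrix(rep(xs < x0 | xs > x1, each = nr), nr, nc)
      attractant_field(c(nr, nc), fl$dx, fl$D, conc = conc, fixed_mask = mask)
    }
  } else if (g$type == "disc_well") {
    n <- lat_dim(g$arena, fl$dx)
    attractant_field(c(n, n), fl$dx, fl$D, conc = fl$c0)
  } else {  # two_spot
    nc <- lat_dim(g$arena[1], fl$dx); nr <- lat_dim(g$arena[2], fl$dx)
    ctr <- two_spot_centers(spec)
    xs <- (seq_len(nc) - 1) * fl$dx
    ys <- (seq_len(nr) - 1) * fl$dx
    d2 <- outer(ys - ctr$attractant[2], xs - ctr$attractant[1],
                function(a, b) a^2 + b^2)
    conc <- matrix(0, nr, nc)
    conc[d2 <= g$spot_radius^2] <- fl$c0
    attractant_field(c(nr, nc), fl$dx, fl$D, conc = conc)
  }
}

two_spot_centers <- function(spec) {
  g <- spec$geometry
  cx <- (g$arena[1] - g$separation) / 2
  cy <- g$arena[2] / 2
  list(cells = c(cx, cy), attractant = c(cx + g$separation, cy))
}

bridge_x_start <- function(spec) {
  g <- spec$geometry
  if (spec$field$mode == "imposed") g$strip_width else g$reservoir_length
}

# initial cell placement; uses the (already seeded) global RNG
scenario_cells <- function(spec) {
  g <- spec$geometry; n <- spec$cells$n
  if (g$type == "bridge") {
    x0 <- bridge_x_start(spec)
    x <- stats::runif(n, x0, x0 + spec$cells$seed_depth)
    y <- stats::runif(n, 0, g$width)
  } else {
    ctr <- if (g$type == "disc_well") {
      list(c(g$arena / 2, g$arena / 2), g$well_radius)
    } else {
      list(two_spot_centers(spec)$cells, g$spot_radius)
    }
    r <- ctr[[2]] * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    x <- ctr[[1]][1] + r * cos(th)
    y <- ctr[[1]][2] + r * sin(th)
  }
  heading <- stats::runif(n, -pi, pi)
  cbind(id = seq_len(n), x = x, y = y, heading = heading)
}

#' Bridge (gradient-chamber) scenario
#'
#' A straight channel of the given length between two regions. In
#' `mode = "imposed"` the channel ends are pinned strips - an infinite sink at
#' the cell end (`c_low`, default 0) and an infinite reservoir at the far end
#' (`c_high = concentration`) - so a linear gradient spans the bridge and the
#' responding cells cannot change it. In `mode = "self"` the whole domain,
#' including a finite reservoir region on each side, starts uniform at
#' `concentration`, and any gradient must be generated by the cells' own
#' degradation (enable it via `degradation`). Cells are seeded at the left
#' end of the bridge.
#'
#' @param length bridge length, um.
#' @param concentration `c_high` of the imposed gradient, or the uniform
#'   starting concentration, nM.
#' @param mode `"self"` or `"imposed"`.
#' @param width channel width, um.
#' @param reservoir_length finite-reservoir length on each side (self mode), um.
#' @param n_cells number of cells seeded.
#' @param degradation one of `"none"`, `"always_on"`, `"induced"`.
#' @param mitogen logical; is the attractant also a mitogen?
#' @param duration_s run length, s.
#' @param seed RNG seed.
#' @param ... further scenario fields (e.g. `cells = list(vmax = ...)`).
#' @return A scenario object.
#' @export
build_bridge <- function(length = 1000, concentration = 300,
                         mode = c("self", "imposed"),
                         width = 200, reservoir_length = 1000,
                         n_cells = 100,
                         degradation = if (mode == "self") "always_on" else "none",
                         mitogen = FALSE,
                         duration_s = 3600, seed = 1, ...) {
  mode <- match.arg(mode)
  fld <- if (mode == "imposed") {
    list(mode = "imposed", c_low = 0, c_high = concentration)
  } else {
    list(mode = "uniform", c0 = concentration)
  }
  args <- list(
    geometry = list(type = "bridge", length = length, width = width,
                    reservoir_length = reservoir_length, strip_width = 40),
    field = fld,
    cells = list(n = n_cells),
    logic = list(degradation = degradation, mitogen = mitogen),
    duration_s = duration_s, seed = seed)
  do.call(new_scenario, utils::modifyList(args, list(...)))
}

#' Radial disc-well scenario
#'
#' Cells are seeded uniformly in a central disc ("well") inside a square arena
#' filled with a uniform attractant background; with degradation on, a
#' ring-shaped wave of cells emerges and travels radially outward.
#'
#' @param radius well radius, um.
#' @param background uniform attractant background, nM.
#' @param arena arena side length, um (defaults to well diameter + 2 mm).
#' @inheritParams build_bridge
#' @return A scenario object.
#' @export
build_disc_well <- function(radius = 1000, background = 10000,
                            arena = 2 * radius + 2000,
                            n_cells = 100, degradation = "always_on",
                            mitogen = FALSE, duration_s = 3600 * 4,
                            seed = 1, ...) {
  args <- list(
    geometry = list(type = "disc_well", well_radius = radius, arena = arena),
    field = list(mode = "uniform", c0 = background, dx = 6),
    cells = list(n = n_cells),
    logic = list(degradation = degradation, mitogen = mitogen),
    duration_s = duration_s, seed = seed)
  do.call(new_scenario, utils::modifyList(args, list(...)))
}

#' Two-spot assay scenario
#'
#' A disc of cells on an empty arena, with an equal-sized disc of attractant
#' loaded a fixed centre-to-centre distance away (no pinned nodes - the spot
#' is finite and free to diffuse). The assay emulates placing a ~500 nl drop
#' of cells about 500 um from a similar drop of attractant on agar; the 3D
#' drop maps to a 2D disc of 500 um radius.
#'
#' @param spot_concentration initial attractant concentration in the
#'   attractant disc, nM.
#' @param spot_radius disc radius (both discs), um.
#' @param separation centre-to-centre distance, um.
#' @param arena `c(Lx, Ly)` arena extent, um.
#' @inheritParams build_bridge
#' @return A scenario object.
#' @export
build_two_spot <- function(spot_concentration, spot_radius = 400,
                           separation = 1000, arena = c(3200, 1600),
                           n_cells = 100, degradation = "none",
                           mitogen = FALSE, duration_s = 7200,
                           seed = 1, ...) {
  args <- list(
    geometry = list(type = "two_spot", spot_radius = spot_radius,
                    separation = separation, arena = arena),
    field = list(mode = "uniform", c0 = spot_concentration, dx = 6, D = 100),
    motility = list(sensing_scale = 5e-4, steering_floor = 0.15),
    cells = list(n = n_cells),
    logic = list(degradation = degradation, mitogen = mitogen),
    duration_s = duration_s, seed = seed)
  do.call(new_scenario, utils::modifyList(args, list(...)))
}

#' Population-scan scenario series
#'
#' One self-generated bridge scenario per population size, everything else
#' held fixed, with systematically varied seeds. Each scenario carries the
#' derived quantity `derived$total_vmax = n_cells * vmax` (the key control
#' parameter of collective degradation).
#'
#' @param background uniform attractant background, nM.
#' @param populations vector of cell counts (non-empty).
#' @param seed_base first seed; scenario i uses `seed_base + i - 1`.
#' @param ... passed on to [build_bridge()].
#' @return A list of scenario objects.
#' @export
build_population_scan <- function(background, populations, seed_base = 1, ...) {
  if (length(populations) < 1) stop("populations must be non-empty")
  lapply(seq_along(populations), function(i) {
    spec <- build_bridge(concentration = background, mode = "self",
                         n_cells = populations[i],
                         seed = seed_base + i - 1, ...)
    spec$derived <- list(total_vmax = populations[i] * spec$cells$vmax)
    spec
  })
}

#' @export
print.sgg_scenario <- function(x, ...) {
  g <- x$geometry
  dims <- switch(g$type,
    bridge = paste0(g$length, " x ", g$width, " um bridge (", x$field$mode, ")"),
    disc_well = paste0(g$well_radius, " um well in ", g$arena, " um arena"),
    two_spot = paste0(g$spot_radius, " um spots, ", g$separation, " um apart"))
  cat("<sgg_scenario> ", g$type, ": ", dims, "\n", sep = "")
  conc <- if (x$field$mode == "uniform") paste0(x$field$c0, " nM uniform")
          else paste0(x$field$c_low, "-", x$field$c_high, " nM imposed")
  cat("  attractant: ", conc, "; degradation ", x$logic$degradation,
      "; mitogen ", x$logic$mitogen, "\n", sep = "")
  cat("  ", x$cells$n, " cells; ", x$duration_s, " s; seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}
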