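#' Attractant concentration field on a 2D lattice
#'
#' Creates the reaction-diffusion substrate of the simulation: a square-cell
#' lattice of attractant concentrations (nM) that diffuses with coefficient
#' `D` under no-flux borders, with optional fixed-concentration nodes that act
#' as infinite reservoirs or sinks. The field keeps two time levels because
#' the DuFort-Frankel scheme is a two-level leapfrog; a forward-Euler (FTCS)
#' bootstrap supplies the second level on the first step.
#'
#' Mass bookkeeping: the "mass" of a node is `concentration * dx^2`
#' (nM um^2); a nominal unit depth is absorbed into the cells' Vmax units.
#' Attractant removed by cells accumulates in `cumulative_degraded`, and any
#' (tiny) negative undershoot clamped by the solver near sharp features is
#' tracked in `clamped_mass`.
#'
#' @param dim lattice dimensions `c(nrow, ncol)`; node `(i, j)` sits at
#'   physical position `x = (j-1)*dx`, `y = (i-1)*dx` (um, origin lower-left).
#' @param dx grid spacing, um.
#' @param D diffusion coefficient, um^2/s.
#' @param conc initial concentration, nM: a scalar or an `nrow x ncol` matrix.
#' @param fixed_mask optional logical matrix, same shape; `TRUE` nodes are
#'   held at their *initial* concentration forever (reservoir/sink nodes).
#' @return An object of class `attractant_field`.
#' @examples
#' f <- attractant_field(c(21, 21), dx = 4, conc = 300)
#' field_mass(f)
#' @export
attractant_field <- function(dim, dx = 4, D = 150, conc = 0, fixed_mask = NULL) {
  stopifnot(length(dim) == 2, all(dim >= 3), dx > 0, D > 0)
  nr <- as.integer(dim[1]); nc <- as.integer(dim[2])
  if (is.matrix(conc)) {
    if (!all(dim(conc) == c(nr, nc))) stop("conc matrix shape does not match dim")
    m <- conc
  } else {
    m <- matrix(as.numeric(conc), nr, nc)
  }
  if (any(m < 0)) stop("initial concentrations must be non-negative")
  if (is.null(fixed_mask)) {
    fixed_mask <- matrix(FALSE, nr, nc)
  } else {
    stopifnot(is.logical(fixed_mask), all(dim(fixed_mask) == c(nr, nc)))
  }
  structure(list(
    conc = m,
    prev = m,
    dx = dx,
    D = D,
    fixed_mask = fixed_mask,
    fixed_values = m[fixed_mask],
    cumulative_degraded = 0,
    clamped_mass = 0,
    bootstrapped = FALSE
  ), class = "attractant_field")
}

# 0-based linear indices of pinned nodes (what the C++ kernels expect)
fixed_indices0 <- function(field) which(field$fixed_mask) - 1L

#' Advance the field one diffusion step
#'
#' Integrates the 2D heat equation `dc/dt = D lap(c)` by one step of the
#' DuFort-Frankel leapfrog scheme with no-flux (reflecting) outer borders.
#' Fixed-mask nodes are re-pinned to their initial values after the step. The
#' first call bootstraps the two-level scheme with forward-Euler sub-steps at
#' or below the FTCS stability limit (`D dt / dx^2 <= 1/4`).
#'
#' @param field an [attractant_field].
#' @param dt time step, s (> 0).
#' @return The advanced field.
#' @export
diffusion_step <- function(field, dt) {
  stopifnot(inherits(field, "attractant_field"))
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a positive number")
  if (!all(dim(field$prev) == dim(field$conc)))
    stop("lattice shape mismatch between time levels")
  fi <- fixed_indices0(field)
  fv <- field$fixed_values
  if (!field$bootstrapped) {
    dt_stab <- 0.25 * field$dx^2 / field$D
    m <- max(1L, ceiling(dt / dt_stab))
    cur <- field$conc
    for (s in seq_len(m)) cur <- cpp_ftcs_step(cur, field$D, field$dx, dt / m, fi, fv)
    field$prev <- field$conc
    field$conc <- cur
    field$bootstrapped <- TRUE
  } else {
    res <- cpp_df_step(field$conc, field$prev, field$D, field$dx, dt, fi, fv)
    field$prev <- res$prev
    field$conc <- res$conc
    field$clamped_mass <- field$clamped_mass + res$clamped_mass
  }
  field
}

#' Re-pin reservoir and sink nodes
#'
#' Sets every fixed-mask node (both time levels) back to its pinned value and
#' leaves all other nodes untouched. Idempotent; called automatically after
#' every diffusion step, exposed for direct manipulation of fields.
#'
#' @param field an [attractant_field].
#' @return The field with pinned nodes restored.
#' @export
apply_fixed_points <- function(field) {
  stopifnot(inherits(field, "attractant_field"))
  field$conc[field$fixed_mask] <- field$fixed_values
  field$prev[field$fixed_mask] <- field$fixed_values
  field
}

#' Concentration at a physical position
#'
#' Nearest-node lookup: agents interact with discrete grid nodes (the overlap
#' rule), so the sampling convention is the value of the closest node, not an
#' interpolation.
#'
#' @param field an [attractant_field].
#' @param position `c(x, y)` in um.
#' @return Concentration, nM.
#' @export
sample_concentration <- function(field, position) {
  stopifnot(inherits(field, "attractant_field"), length(position) == 2)
  ext <- field_extent(field)
  x <- position[1]; y <- position[2]
  if (x < 0 || x > ext[1] || y < 0 || y > ext[2])
    stop("position outside field domain")
  j <- round(x / field$dx) + 1
  i <- round(y / field$dx) + 1
  field$conc[i, j]
}

#' Total attractant mass on the lattice
#'
#' @param field an [attractant_field].
#' @return `sum(conc) * dx^2`, nM um^2.
#' @export
field_mass <- function(field) sum(field$conc) * field$dx^2

#' Physical extent of the field domain
#'
#' @param field an [attractant_field].
#' @return `c(Lx, Ly)` in um.
#' @export
field_extent <- function(field) {
  c((ncol(field$conc) - 1) * field$dx, (nrow(field$conc) - 1) * field$dx)
}

#' @export
print.attractant_field <- function(x, ...) {
  ext <- field_extent(x)
  cat("<attractant_field> ", nrow(x$conc), "x", ncol(x$conc),
      " nodes (", ext[1], " x ", ext[2], " um, dx = ", x$dx, " um)\n", sep = "")
  cat("  D = ", x$D, " um^2/s; conc range [",
      format(min(x$conc), digits = 4), ", ", format(max(x$conc), digits = 4),
      "] nM; ", sum(x$fixed_mask), " pinned nodes\n", sep = "")
  cat("  mass = ", format(field_mass(x), digits = 6),
      " nM um^2; degraded so far = ", format(x$cumulative_degraded, digits = 6),
      "\n", sep = "")
  invisible(x)
}
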