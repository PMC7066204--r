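# Independent oracles used across the suite.

# 2D heat kernel: concentration at radius r, time t, for a point mass M
# (closed-form solution of dc/dt = D lap(c) on the infinite plane)
heat_kernel_2d <- function(M, D, r, t) {
  M / (4 * pi * D * t) * exp(-r^2 / (4 * D * t))
}

# evolve a field by repeated diffusion steps
evolve <- function(field, dt, n) {
  for (i in seq_len(n)) field <- diffusion_step(field, dt)
  field
}

# node coordinate grids for a field (um)
node_xy <- function(field) {
  list(x = (seq_len(ncol(field$conc)) - 1) * field$dx,
       y = (seq_len(nrow(field$conc)) - 1) * field$dx)
}

# circular mean of angles
circ_mean <- function(theta) atan2(mean(sin(theta)), mean(cos(theta)))

# smallest signed angular difference a - b
ang_diff <- function(a, b) atan2(sin(a - b), cos(a - b))

# hand-built trajectory tibble: one row per cell per time
make_traj <- function(times, positions) {
  # positions: list of matrices (n_cells x 2), one per time
  n <- nrow(positions[[1]])
  do.call(rbind, lapply(seq_along(times), function(i) {
    tibble::tibble(time_s = times[i], cell_id = seq_len(n),
                   x_um = positions[[i]][, 1], y_um = positions[[i]][, 2],
                   heading_rad = 0, occupancy = 0, occupancy_avg = 0,
                   event = "none")
  }))
}
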