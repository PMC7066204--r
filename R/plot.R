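#' Quick-look plot of a field snapshot with cells overlaid
#'
#' @param result an `sgg_result` (or an [attractant_field]).
#' @param snapshot index into `result$snapshots` (default: final).
#' @return A ggplot object.
#' @export
plot_field <- function(result, snapshot = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_field needs the ggplot2 package")
  if (inherits(result, "attractant_field")) {
    conc <- result$conc; dx <- result$dx; cells <- NULL; t <- NA
  } else {
    if (is.null(snapshot)) snapshot <- length(result$snapshots)
    snap <- result$snapshots[[snapshot]]
    conc <- snap$conc; dx <- result$field$dx; t <- snap$time
    traj <- result$trajectories
    rows <- traj[traj$time_s == max(traj$time_s[traj$time_s <= t]), ]
    cells <- data.frame(x = rows$x_um, y = rows$y_um)
  }
  df <- expand.grid(y = (seq_len(nrow(conc)) - 1) * dx,
                    x = (seq_len(ncol(conc)) - 1) * dx)
  df$conc <- as.vector(conc)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = conc)) +
    ggplot2::scale_fill_viridis_c(name = "attractant (nM)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)",
                  title = if (is.na(t)) NULL else paste0("t = ", t, " s"))
  if (!is.null(cells) && nrow(cells) > 0)
    p <- p + ggplot2::geom_point(data = cells, colour = "white", size = 0.8)
  p
}
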