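# Optional figures (ggplot2 is suggested, not required).

#' Plot cluster-mean learning curves
#'
#' One panel per cluster, one line per limb role, baseline ratio at 1 Hz.
#'
#' @param model A `cluster_model` fitted on a four-role feature matrix.
#' @param t_grid The 1 Hz grid used to build the features.
#' @return A ggplot object.
#' @export
plot_cluster_centres <- function(model, t_grid = 0:719) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    mk_error("ggplot2 is not installed", "mobilekin_invalid_spec")
  Tn <- length(t_grid)
  d <- do.call(rbind, lapply(seq_len(model$k), function(i) {
    do.call(rbind, lapply(seq_along(LIMB_ROLES), function(r) {
      data.frame(cluster = paste0("cluster ", i), limb = LIMB_ROLES[r],
                 t = t_grid,
                 ratio = model$centres[i, (r - 1) * Tn + seq_len(Tn)])
    }))
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = t, y = ratio, colour = limb)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 120, linetype = "dashed") +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "time (s)", y = "baseline ratio")
}

#' Plot simulated cluster learning curves
#'
#' Ensemble members in grey, ensemble mean in red.
#'
#' @param sim Output of [simulate_cluster()].
#' @return A ggplot object.
#' @export
plot_simulated_cluster <- function(sim) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    mk_error("ggplot2 is not installed", "mobilekin_invalid_spec")
  t <- sim$mean_curve$t
  members <- do.call(rbind, lapply(seq_len(nrow(sim$curves)), function(i)
    data.frame(run = i, t = t, ratio = sim$curves[i, ])))
  ggplot2::ggplot() +
    ggplot2::geom_line(data = members,
                       ggplot2::aes(x = t, y = ratio, group = run),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_line(data = sim$mean_curve,
                       ggplot2::aes(x = t, y = ratio), colour = "red") +
    ggplot2::geom_vline(xintercept = 120, linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "simulated ConA baseline ratio")
}
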