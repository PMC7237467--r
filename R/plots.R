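# Base-graphics views of the metric objects. Plots are side artifacts; all
# quantitative results come from the numeric outputs.

#' @export
plot.ng_metrics <- function(x, which = c("correlation", "es_profile"), ...) {
  which <- match.arg(which)
  if (which == "correlation") {
    M <- x$correlation
    np <- nrow(M)
    image(seq_len(np), seq_len(np), t(M[np:1, ]),
          col = hcl.colors(64, "Blue-Red 3"),
          xlab = "player (direction rank)", ylab = "player (direction rank)",
          main = sprintf("Action-time correlation (%s)", x$model),
          axes = FALSE)
    axis(1, seq_len(np)); axis(2, seq_len(np), labels = np:1)
  } else {
    p <- x$es_profile
    if (is.null(p)) stop("metrics were computed with es = FALSE")
    plot(p$distance, p$mean_es, type = "b", pch = 16,
         xlab = "circular distance between directions (rad)",
         ylab = "mean event synchronization",
         main = sprintf("Synchronization by distance (%s)", x$model))
  }
  invisible(x)
}

#' @export
plot.ng_learning <- function(x, ...) {
  d <- x$durations[!x$censored & !is.na(x$durations)]
  if (length(d) == 0) stop("no uncensored learning durations")
  k <- seq_len(max(d))
  Fhat <- vapply(k, function(kk) mean(d <= kk), 0)
  plot(k, Fhat, type = "s", xlab = "spike count k",
       ylab = "fraction of unit-batches with T* <= k",
       main = sprintf("Learning durations (%s)", x$model), ylim = c(0, 1))
  if (is.finite(x$learning_rate))
    lines(k, 1 - exp(-x$learning_rate * k), col = 2, lwd = 2)
  legend("bottomright", c("empirical", "cumulative exponential fit"),
         col = c(1, 2), lty = 1, bty = "n")
  invisible(x)
}

#' @export
plot.ng_session <- function(x, batch = 1, trial = 1, ...) {
  b <- x$batches[[batch]]
  rows <- which(b$trial == trial)
  tr <- b$trials[trial, ]
  plot(b$pos[rows, 1], b$pos[rows, 2], type = "l",
       xlab = "x (px)", ylab = "y (px)",
       main = sprintf("%s model: batch %d, trial %d", x$model, batch, trial))
  points(tr$start_x, tr$start_y, pch = 16, col = "darkgreen", cex = 1.4)
  points(tr$target_x, tr$target_y, pch = 16, col = "red", cex = 1.4)
  invisible(x)
}
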