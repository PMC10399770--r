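## base-graphics plot methods

#' @export
plot.recording <- function(x, downsample = 10L, ...) {
  idx <- seq(1L, length(x$samples), by = max(1L, downsample))
  graphics::plot(idx / x$sample_rate, x$samples[idx], type = "l",
                 xlab = "time (s)", ylab = "amplitude",
                 main = x$label, ...)
  invisible(x)
}

#' @export
plot.correlation_trace <- function(x, downsample = 10L, ...) {
  idx <- seq(1L, length(x$values), by = max(1L, downsample))
  graphics::plot((idx - 1L) / x$sample_rate + x$alignment, x$values[idx],
                 type = "l", xlab = "time (s)",
                 ylab = "normalized correlation", ylim = c(-1, 1), ...)
  invisible(x)
}

ellipse_points <- function(center, covariance, confidence, n = 120L) {
  r <- sqrt(stats::qchisq(confidence, df = 2))
  theta <- seq(0, 2 * pi, length.out = n)
  circ <- r * cbind(cos(theta), sin(theta))
  ev <- eigen(covariance, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  pts <- circ %*% diag(sqrt(lam)) %*% t(ev$vectors)
  sweep(pts, 2L, center, `+`)
}

#' Acoustic-space scatter with group confidence ellipses
#'
#' @param x an `acoustic_space`.
#' @param axes which two axes to draw.
#' @param col colors, one per group.
#' @param ... passed to [graphics::plot()].
#' @export
plot.acoustic_space <- function(x, axes = c(1L, 2L), col = NULL, ...) {
  g <- x$groups
  if (is.null(col)) col <- grDevices::hcl.colors(nlevels(g), "Dark 3")
  s <- x$scores[, axes, drop = FALSE]
  graphics::plot(s, col = col[as.integer(g)], pch = 16,
                 xlab = sprintf("PC%d (%.1f%%)", axes[1L],
                                100 * x$explained_variance[axes[1L]]),
                 ylab = sprintf("PC%d (%.1f%%)", axes[2L],
                                100 * x$explained_variance[axes[2L]]),
                 ...)
  if (identical(sort(axes), c(1L, 2L))) {
    for (k in seq_along(x$ellipses)) {
      e <- x$ellipses[[k]]
      if (all(is.finite(e$covariance)) && any(e$covariance != 0))
        graphics::lines(ellipse_points(e$center, e$covariance,
                                       e$confidence), col = col[k])
    }
  }
  graphics::legend("topright", legend = levels(g), col = col, pch = 16,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Null distribution of the permuted DFA
#'
#' @param x a `pdfa` object.
#' @param ... passed to [graphics::hist()].
#' @export
plot.pdfa <- function(x, ...) {
  graphics::hist(x$null_distribution, breaks = 30,
                 xlim = range(c(x$null_distribution,
                                x$overall_reclassification)),
                 xlab = "overall reclassification rate",
                 main = sprintf("pDFA null (p = %.3g)", x$p_value), ...)
  graphics::abline(v = x$overall_reclassification, col = "red", lwd = 2)
  invisible(x)
}

#' Hierarchical clustering tree projected on geographic coordinates
#'
#' Leaves are drawn at each group's (lon, lat); cluster merges are drawn
#' as segments joining the (coordinate-averaged) positions of the merged
#' clusters, annotated with merge heights.
#'
#' @param x a `geo_clustering`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.geo_clustering <- function(x, ...) {
  co <- x$coordinates
  graphics::plot(co$lon, co$lat, pch = 16, xlab = "longitude",
                 ylab = "latitude", ...)
  graphics::text(co$lon, co$lat, co$group, pos = 3, cex = 0.8)
  hc <- x$hclust
  pos <- cbind(co$lon, co$lat)        # leaf positions, hclust label order
  pos <- pos[match(hc$labels, co$group), , drop = FALSE]
  node_pos <- matrix(NA_real_, nrow(hc$merge), 2L)
  get_pos <- function(id)
    if (id < 0) pos[-id, ] else node_pos[id, ]
  for (m in seq_len(nrow(hc$merge))) {
    a <- get_pos(hc$merge[m, 1L])
    b <- get_pos(hc$merge[m, 2L])
    graphics::segments(a[1L], a[2L], b[1L], b[2L], col = "grey40")
    node_pos[m, ] <- (a + b) / 2
    graphics::text(node_pos[m, 1L], node_pos[m, 2L],
                   sprintf("%.2f", hc$height[m]), cex = 0.6, col = "grey30")
  }
  invisible(x)
}

#' @export
plot.tuned_detector <- function(x, ...) {
  sw <- x$sweep[order(x$sweep$threshold), ]
  graphics::plot(sw$threshold, sw$precision, type = "l", ylim = c(0, 1),
                 xlab = "threshold", ylab = "metric", ...)
  graphics::lines(sw$threshold, sw$recall, lty = 2)
  graphics::abline(v = x$threshold, col = "red")
  graphics::abline(h = x$target, col = "grey60", lty = 3)
  graphics::legend("bottomleft", legend = c("precision", "recall"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
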