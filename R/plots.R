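#' Copy-number heatmap of a bin table
#'
#' Samples as rows, genome position as columns, fill by gain/loss state
#' relative to each sample's baseline ploidy (red gains, blue losses) or by
#' integer copy number.
#'
#' @param x Wide bin table of integer copy numbers.
#' @param fill `"state"` (default) or `"cn"`.
#' @param baseline As in [pga()].
#' @return A ggplot object.
#' @export
plot_cn_heatmap <- function(x, fill = c("state", "cn"), baseline = NULL) {
  fill <- match.arg(fill)
  m <- cn_matrix(x)
  long <- tibble::tibble(
    bin = rep(seq_len(nrow(m)), ncol(m)),
    chrom = rep(x$chrom, ncol(m)),
    sample_id = rep(colnames(m), each = nrow(m)),
    cn = as.vector(m)
  )
  if (fill == "state") {
    s <- state_matrix(m, resolve_baseline(m, baseline))
    long$state <- factor(c("loss", "baseline", "gain")[as.vector(s) + 2L],
                         levels = c("loss", "baseline", "gain"))
    p <- ggplot2::ggplot(long, ggplot2::aes(.data$bin, .data$sample_id,
                                            fill = .data$state)) +
      ggplot2::scale_fill_manual(values = c(loss = "#3B6FB6",
                                            baseline = "grey95",
                                            gain = "#C0392B"),
                                 drop = FALSE)
  } else {
    p <- ggplot2::ggplot(long, ggplot2::aes(.data$bin, .data$sample_id,
                                            fill = .data$cn)) +
      ggplot2::scale_fill_gradient2(midpoint = 2, low = "#3B6FB6",
                                    mid = "grey95", high = "#C0392B")
  }
  brk <- cumsum(rle(x$chrom)$lengths)
  p + ggplot2::geom_tile() +
    ggplot2::geom_vline(xintercept = brk + 0.5, linewidth = 0.2,
                        colour = "grey60") +
    ggplot2::labs(x = "genomic bin", y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-ploidy score profile of a ploidy fit
#'
#' @param fit A `"ploidy_fit"`.
#' @return A ggplot object showing the scaled within-sample fit error, the
#'   scaled cross-sample distance and the combined score over the ploidy
#'   grid, with the rank-1 solution marked.
#' @export
plot_ploidy_scores <- function(fit) {
  tab <- tidy(fit)
  long <- tidyr::pivot_longer(tab, c("scaled_fit", "scaled_distance",
                                     "score"),
                              names_to = "measure")
  best <- tab$psi[tab$rank == 1]
  ggplot2::ggplot(long, ggplot2::aes(.data$psi, .data$value,
                                     colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = best, linetype = 2) +
    ggplot2::labs(x = "ploidy", y = "scaled score") +
    ggplot2::theme_minimal()
}

#' Accepted ABC draws in the (mu, alpha) plane
#'
#' @param fit An `"abc_fit"` (selection model).
#' @return A ggplot object; the joint posterior typically shows the
#'   positive mu-alpha ridge reflecting their non-identifiability from
#'   end-point karyotypes.
#' @export
plot_abc_posterior <- function(fit) {
  acc <- tidy(fit)
  ggplot2::ggplot(acc, ggplot2::aes(.data$mu, .data$alpha)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "CNA rate mu", y = "selection strength alpha") +
    ggplot2::theme_minimal()
}

#' Autoplot a simulation as a gland heatmap
#'
#' @param object A `"cin_sim"`.
#' @param n_glands Glands to sample for display.
#' @param seed Seed for the display sample.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cin_sim
#' @export
autoplot.cin_sim <- function(object, n_glands = min(40, object$population),
                             seed = 1, ...) {
  g <- sample_glands(object, n_glands, seed = seed)
  plot_cn_heatmap(g, fill = "cn")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
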