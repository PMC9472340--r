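#' Density plot of homoeolog expression bias per group
#'
#' Mirrors the standard presentation of bias distributions: one log2(R/C)
#' density per group with dotted lines at the group means.
#'
#' @param ratios Ratio records from [homoeolog_ratios()] (any number of
#'   groups).
#'
#' @return A ggplot object.
#' @export
plot_heb_density <- function(ratios) {
  d <- ratios[is.finite(ratios$log2rc), ]
  means <- d |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(m = mean(.data$log2rc), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2rc, colour = .data$group)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = .data$m,
                                     colour = .data$group),
                        linetype = "dotted") +
    ggplot2::labs(x = expression(log[2](R/C)), y = "density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Copy-ratio track along a chromosome pair
#'
#' Scatter of per-gene log10 depth ratios in map order with the decision
#' thresholds at +/- log10(2) and detected segments shaded.
#'
#' @param records Copy-ratio records ([copy_ratio_records()]).
#' @param segments Optional segments from [detect_segments()].
#' @param config An [hs_config()].
#'
#' @return A ggplot object.
#' @export
plot_copy_ratio <- function(records, segments = NULL,
                            config = hs_config()) {
  d <- records[is.finite(records$log10_ratio), ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$order_index,
                                       y = .data$log10_ratio)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$state), size = 0.8) +
    ggplot2::geom_hline(yintercept = c(-1, 0, 1) * config$copy_log10_threshold,
                        linetype = c("dashed", "solid", "dashed"),
                        colour = c("black", "red", "black")) +
    ggplot2::facet_wrap(~chrom_pair, scales = "free_x") +
    ggplot2::labs(x = "gene order along chromosome pair",
                  y = expression(log[10](R/C~depth))) +
    ggplot2::theme_minimal()
  if (!is.null(segments) && nrow(segments)) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(segments),
      ggplot2::aes(xmin = .data$start_index - 0.5,
                   xmax = .data$end_index + 0.5),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "orange",
      inherit.aes = FALSE)
  }
  p
}

#' Window methylation profile plot
#'
#' @param profile Output of [region_profile()] (or a list of them).
#' @return A ggplot object.
#' @export
plot_region_profile <- function(profile) {
  if (!is.null(profile$gene_id)) profile <- list(profile)
  d <- dplyr::bind_rows(lapply(profile, function(pr)
    tibble(gene_id = pr$gene_id, region = pr$region,
           window = seq_along(pr$window_ml), ml = pr$window_ml)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$window, y = .data$ml,
                                  colour = .data$gene_id)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~region) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "window (5' to 3')", y = "methylation level",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' TE density versus SV count scatter
#'
#' @param track Window tibble with `te_density` and `sv_count`.
#' @return A ggplot object.
#' @export
plot_sv_te <- function(track) {
  ggplot2::ggplot(track, ggplot2::aes(x = .data$te_density,
                                      y = .data$sv_count)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red") +
    ggplot2::labs(x = "TE density per window", y = "SV count per window") +
    ggplot2::theme_minimal()
}

#' @rdname plot_heb_density
#' @param object Ratio records.
#' @param ... Ignored.
#' @method autoplot hs_cistrans
#' @export
autoplot.hs_cistrans <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$P, y = .data$H,
                                  colour = .data$category7)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "parental log2(R/C)  (P)",
                  y = "hybrid log2(R/C)  (H)", colour = NULL) +
    ggplot2::theme_minimal()
}
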