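# Optional ggplot2 figures mirroring the study's displays. ggplot2 is a
# suggested dependency; each function checks for it at call time.

.needGgplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop(.err("mitocomp_missing_dependency",
              "ggplot2 is required for plotting"))
}

#' Scatter plot of AT skew against GC skew
#'
#' @param skew a skew table (see [skewTable()]).
#' @param group optional vector (e.g. subfamily) used for point colour.
#' @return a ggplot object.
#' @export
plotSkew <- function(skew, group = NULL) {
  .needGgplot()
  df <- skew
  df$group <- if (is.null(group)) "all" else group
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gc_skew, y = .data$at_skew,
                                   colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "GC skew", y = "AT skew") +
    ggplot2::theme_minimal()
}

#' Sliding-window CAI profiles per gene
#'
#' @param profiles long-format profile table (`genome_id`, `gene`,
#'   `window_start`, `cai`), as written by [runPipeline()].
#' @return a ggplot object faceted by gene.
#' @export
plotCAIProfiles <- function(profiles) {
  .needGgplot()
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$window_start, y = .data$cai,
                               colour = .data$genome_id)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~gene, scales = "free_x") +
    ggplot2::labs(x = "window start (codon)", y = "CAI") +
    ggplot2::theme_minimal()
}

#' Neutrality plot (GC12 against GC3) with the fitted line
#'
#' @param gc3,gc12 per-species positional GC values.
#' @param fit optional `NeutralityFit` row used for the line; computed
#'   from the points when omitted.
#' @return a ggplot object.
#' @export
plotNeutrality <- function(gc3, gc12, fit = NULL) {
  .needGgplot()
  if (is.null(fit)) fit <- neutralityFit(gc3, gc12)
  ggplot2::ggplot(data.frame(gc3 = gc3, gc12 = gc12),
                  ggplot2::aes(x = .data$gc3, y = .data$gc12)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept) +
    ggplot2::labs(x = "GC3", y = "GC12") +
    ggplot2::theme_minimal()
}
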