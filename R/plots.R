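# ggplot2 visualisations for the main result types.

#' @describeIn hk_scan Plot LRS (and the additive coefficient) along the
#'   genome, faceted by chromosome.
#' @param object,x A `scan_result`.
#' @param ... Unused.
#' @param significance LRS line drawn as the genome-wide significance level
#'   (default 18, the conventional level for a BXD-scale panel).
#' @export
autoplot.scan_result <- function(object, ..., significance = 18) {
  lv <- chrom_levels(object$chromosome)
  df <- dplyr::mutate(object, chromosome = chrom_factor(.data$chromosome, lv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mb)) +
    ggplot2::geom_hline(yintercept = significance, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$lrs), colour = "#2c6fbb") +
    ggplot2::geom_line(ggplot2::aes(y = .data$additive * 10), colour = "#2e8b57",
                       alpha = 0.7, na.rm = TRUE) +
    ggplot2::facet_grid(. ~ chromosome, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "LRS",
                  title = attr(object, "trait_id"),
                  subtitle = "green: additive coefficient x10 (positive = D allele increases trait)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing = ggplot2::unit(0.1, "lines"),
                   axis.text.x = ggplot2::element_blank())
}

#' @export
plot.scan_result <- function(x, ...) print(autoplot(x, ...))

#' @describeIn transcriptome_scan Transcript-position versus peak-position
#'   scatter (cis peaks fall on the diagonal), coloured by class.
#' @param object A `peak_catalog`.
#' @param min_lrs Only peaks at or above this LRS are drawn (default 12).
#' @param ... Unused.
#' @export
autoplot.peak_catalog <- function(object, min_lrs = 12, ...) {
  df <- dplyr::filter(object, .data$lrs >= min_lrs, .data$class != "unclassified")
  lv <- chrom_levels(c(df$peak_chr, df$probe_chr))
  off <- cumulative_mb_offset(df, lv)
  df <- df |>
    dplyr::mutate(
      gx = .data$peak_mb + off[as.character(.data$peak_chr)],
      gy = .data$probe_mb + off[as.character(.data$probe_chr)]
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gx, y = .data$gy,
                                   colour = .data$class, size = .data$lrs)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_size_continuous(range = c(0.5, 3)) +
    ggplot2::labs(x = "eQTL peak position (genome Mb)",
                  y = "transcript position (genome Mb)",
                  colour = "class", size = "LRS") +
    ggplot2::theme_minimal()
}

cumulative_mb_offset <- function(df, lv) {
  spans <- vapply(lv, function(ch) {
    max(c(df$peak_mb[df$peak_chr == ch], df$probe_mb[df$probe_chr == ch], 0),
        na.rm = TRUE)
  }, numeric(1))
  setNames(c(0, cumsum(spans + 5))[seq_along(lv)], lv)
}

#' @describeIn permutation_null Histogram of the permutation genome-wide
#'   maxima with the 5% genome-wide threshold marked.
#' @param object A `null_distribution`.
#' @param ... Unused.
#' @export
autoplot.null_distribution <- function(object, ...) {
  thr <- genomewide_threshold(object, 0.05)
  ggplot2::ggplot(tibble(max_lrs = object$max_lrs),
                  ggplot2::aes(x = .data$max_lrs)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = thr, colour = "#b2182b", linetype = "dashed") +
    ggplot2::annotate("text", x = thr, y = Inf, hjust = -0.1, vjust = 1.5,
                      label = sprintf("LRS %.1f (p = 0.05)", thr), colour = "#b2182b") +
    ggplot2::labs(x = "genome-wide maximum LRS per permutation", y = "count") +
    ggplot2::theme_minimal()
}

#' @describeIn pc_signature Bar chart of member correlations with the seed
#'   PC1.
#' @param object A `pc_signature`.
#' @param ... Unused.
#' @export
autoplot.pc_signature <- function(object, ...) {
  df <- dplyr::mutate(object$members,
                      probe_id = factor(.data$probe_id, levels = rev(.data$probe_id)),
                      seed = .data$probe_id %in% object$seeds$probe_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$probe_id,
                                   fill = .data$seed)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "#2c6fbb")) +
    ggplot2::labs(x = "correlation with seed PC1", y = NULL, fill = "seed") +
    ggplot2::theme_minimal()
}

#' @describeIn fold_range_histogram Bar chart of the fold-range distribution.
#' @param x The tibble returned by `fold_range_histogram()`.
#' @param ... Unused.
#' @export
plot_fold_range <- function(x, ...) {
  df <- dplyr::mutate(x, fold_range = factor(.data$fold_range, levels = .data$fold_range))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_range, y = .data$n_probes)) +
    ggplot2::geom_col(fill = "grey60", colour = "grey30") +
    ggplot2::labs(x = "expression range (fold)", y = "probe sets") +
    ggplot2::theme_minimal()
}
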