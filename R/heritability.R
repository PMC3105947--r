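#' Per-transcript heritability by one-way ANOVA
#'
#' Heritability of an expression trait is estimated from replicate arrays by a
#' one-way ANOVA with mouse strain as the single factor: the between-strain
#' mean square divided by the sum of the between-strain and within-strain mean
#' squares,
#'
#' \deqn{h^2 = MS_{between} / (MS_{between} + MS_{within}).}
#'
#' Both mean squares are non-negative, so `h2` lies in `[0, 1]`; when all
#' values are identical (both mean squares zero) `h2 = 0` by convention. Note
#' this mean-square ratio is upwardly biased relative to the intraclass
#' correlation \eqn{\sigma_b^2/(\sigma_b^2+\sigma_e^2)}: with `n` replicates
#' per strain its expectation is
#' \eqn{(\sigma_e^2 + n\sigma_b^2)/(2\sigma_e^2 + n\sigma_b^2)}. It is the
#' estimator as defined, implemented verbatim; no REML refinement is applied.
#'
#' F1 arrays are excluded by default. Unbalanced designs use the standard
#' one-way decomposition with \eqn{\sum_i (n_i - 1)} within-strain degrees of
#' freedom.
#'
#' @param norm A `norm_panel` with at least two strains and at least one
#'   strain with replicate arrays (otherwise the within-strain mean square is
#'   undefined).
#' @param probe_id A single probe id present in the panel.
#' @param exclude_f1 Drop F1 arrays before the ANOVA (default TRUE).
#' @return A one-row tibble: `probe_id`, `h2`, `between_ms`, `within_ms`,
#'   `n_strains`, `n_arrays`.
#' @export
anova_heritability <- function(norm, probe_id, exclude_f1 = TRUE) {
  if (!inherits(norm, "norm_panel")) abort("`norm` must be a normalized panel.")
  if (!probe_id %in% colnames(norm$signals)) {
    abort(sprintf("probe %s not in panel.", probe_id))
  }
  heritability_table(norm, probes = probe_id, exclude_f1 = exclude_f1, sort = FALSE)
}

#' Heritability table for all probes
#'
#' Runs the one-way ANOVA heritability estimator of [anova_heritability()]
#' across probes and returns records sorted by decreasing `h2` (ties broken by
#' probe id).
#'
#' @param norm A `norm_panel`.
#' @param probes Optional subset of probe ids (default: all).
#' @param exclude_f1 Drop F1 arrays (default TRUE).
#' @param sort Sort descending by `h2` (default TRUE).
#' @return A tibble with one row per probe, columns as in
#'   [anova_heritability()].
#' @export
heritability_table <- function(norm, probes = NULL, exclude_f1 = TRUE, sort = TRUE) {
  if (!inherits(norm, "norm_panel")) abort("`norm` must be a normalized panel.")
  probes <- probes %||% colnames(norm$signals)
  keep <- if (exclude_f1) !norm$samples$is_f1 else rep(TRUE, nrow(norm$samples))
  y <- norm$signals[keep, probes, drop = FALSE]
  strain <- norm$samples$strain_id[keep]

  n_i <- as.vector(table(strain))
  k <- length(n_i)
  n <- length(strain)
  if (k < 2) abort("need >= 2 strains for heritability.")
  if (all(n_i < 2)) abort("within-strain variance undefined: no strain has replicate arrays.")

  # one-way decomposition via group sums, vectorized across probes
  grp_sum <- rowsum(y, strain)
  grp_n <- as.vector(table(strain)[rownames(grp_sum)])
  grand_mean <- colMeans(y)
  ss_between <- colSums(grp_sum^2 / grp_n) - n * grand_mean^2
  ss_total <- colSums(y^2) - n * grand_mean^2
  ss_within <- pmax(ss_total - ss_between, 0)
  ss_between <- pmax(ss_between, 0)
  between_ms <- ss_between / (k - 1)
  within_ms <- ss_within / (n - k)
  denom <- between_ms + within_ms
  h2 <- ifelse(denom == 0, 0, between_ms / denom)

  out <- tibble(
    probe_id = probes, h2 = unname(h2),
    between_ms = unname(between_ms), within_ms = unname(within_ms),
    n_strains = k, n_arrays = n
  )
  if (sort) out <- dplyr::arrange(out, dplyr::desc(.data$h2), .data$probe_id)
  out
}
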