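#' Build a synthetic marker map for an RI panel
#'
#' Creates an ordered marker map (genetic and physical positions) emulating the
#' dense SNP/microsatellite maps used to genotype recombinant inbred panels.
#' Markers are laid out at regular genetic intervals per chromosome, optionally
#' jittered, and physical positions follow the genetic positions at a fixed
#' Mb/cM ratio (defaults to 2 Mb per cM, the coarse mouse genome-wide average).
#'
#' When `n_chromosomes >= 2` the last chromosome is labelled `"X"`; sex
#' chromosomes beyond X (Y) and the mitochondrial genome are never generated,
#' matching the scan's exclusion of those from interval mapping.
#'
#' @param n_chromosomes Number of chromosomes (autosomes plus one X).
#' @param chrom_length_cm Genetic length of each chromosome in centimorgans.
#' @param marker_spacing_cm Target spacing between adjacent markers (cM).
#' @param mb_per_cm Physical-to-genetic ratio (megabases per centimorgan).
#' @param jitter_cm Half-width of the uniform jitter applied to interior marker
#'   positions; must be less than half the spacing so order is preserved.
#' @param seed Integer seed; identical seeds give identical maps.
#'
#' @return A tibble with columns `marker`, `chromosome`, `cm`, `mb`, ordered by
#'   chromosome then genetic position.
#' @examples
#' make_marker_map(1, 100, 10, mb_per_cm = 0.5, seed = 1)
#' @export
make_marker_map <- function(n_chromosomes, chrom_length_cm = 80,
                            marker_spacing_cm = 1, mb_per_cm = 2,
                            jitter_cm = 0, seed = 1L) {
  assert_scalar_number(n_chromosomes, "n_chromosomes", min = 1)
  assert_scalar_number(chrom_length_cm, "chrom_length_cm", min = 0, strict_min = TRUE)
  assert_scalar_number(marker_spacing_cm, "marker_spacing_cm", min = 0, strict_min = TRUE)
  assert_scalar_number(mb_per_cm, "mb_per_cm", min = 0, strict_min = TRUE)
  assert_scalar_number(jitter_cm, "jitter_cm", min = 0)
  if (jitter_cm >= marker_spacing_cm / 2) {
    abort("`jitter_cm` must be < marker_spacing_cm / 2 to keep positions increasing.")
  }

  labels <- if (n_chromosomes >= 2) c(as.character(seq_len(n_chromosomes - 1)), "X")
            else "1"
  withr::with_seed(as.integer(seed), {
    purrr::map_dfr(labels, function(chr) {
      cm <- seq(0, chrom_length_cm, by = marker_spacing_cm)
      if (jitter_cm > 0 && length(cm) > 2) {
        mid <- seq_along(cm)[-c(1, length(cm))]
        cm[mid] <- cm[mid] + runif(length(mid), -jitter_cm, jitter_cm)
      }
      tibble(
        marker = sprintf("chr%s_m%03d", chr, seq_along(cm)),
        chromosome = chr,
        cm = cm,
        mb = cm * mb_per_cm
      )
    })
  })
}

validate_marker_map <- function(map) {
  req <- c("marker", "chromosome", "cm", "mb")
  if (!all(req %in% names(map))) {
    abort(sprintf("marker map must have columns %s.", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(map$marker)) abort("duplicate marker ids in map.")
  if (any(map$cm < 0) || any(map$mb < 0)) abort("marker positions must be >= 0.")
  bad <- map |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(
      ok = all(diff(.data$cm) > 0) && all(diff(.data$mb) > 0),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(sprintf("non-monotone marker positions on chromosome(s): %s",
                  paste(bad$chromosome, collapse = ", ")))
  }
  invisible(map)
}
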