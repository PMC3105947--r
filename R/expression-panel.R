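#' Construct an expression panel
#'
#' Container for probe-set level array data: a samples x probes signal matrix
#' plus sample metadata (strain, sex, F1 flag) and probe annotation (symbol and
#' genomic position). Raw panels hold non-negative intensities;
#' [normalize_panel()] returns the same structure on the normalized scale
#' (class `norm_panel`), where one unit is approximately a two-fold difference
#' in expression.
#'
#' @param signals Arrays x probes numeric matrix, rownames = array ids,
#'   colnames = probe ids; values must be non-negative for raw panels.
#' @param samples Tibble with columns `array_id`, `strain_id`, `sex`
#'   (`"F"`/`"M"`), `is_f1` (logical).
#' @param probes Tibble with columns `probe_id`, `symbol`, `chromosome`
#'   (chromosome label or `"unmapped"`), `mb` (position in megabases; NA when
#'   unmapped).
#' @param normalized Internal flag; set by [normalize_panel()].
#' @return An `expr_panel` (or `norm_panel`) object.
#' @export
expression_panel <- function(signals, samples, probes, normalized = FALSE) {
  samples <- as_tibble(samples)
  probes <- as_tibble(probes)
  req_s <- c("array_id", "strain_id", "sex", "is_f1")
  req_p <- c("probe_id", "symbol", "chromosome", "mb")
  if (!all(req_s %in% names(samples))) {
    abort(sprintf("sample sheet needs columns %s.", paste(req_s, collapse = ", ")))
  }
  if (!all(req_p %in% names(probes))) {
    abort(sprintf("probe sheet needs columns %s.", paste(req_p, collapse = ", ")))
  }
  if (is.null(rownames(signals)) || is.null(colnames(signals))) {
    abort("`signals` must have array rownames and probe colnames.")
  }
  missing_meta <- setdiff(rownames(signals), samples$array_id)
  if (length(missing_meta) > 0) {
    abort(sprintf("array(s) without sample metadata: %s",
                  paste(missing_meta, collapse = ", ")))
  }
  missing_ann <- setdiff(colnames(signals), probes$probe_id)
  if (length(missing_ann) > 0) {
    abort(sprintf("probe(s) without annotation: %s",
                  paste(head(missing_ann, 5), collapse = ", ")))
  }
  if (!normalized && any(signals < 0)) abort("raw signals must be >= 0.")
  samples <- samples[match(rownames(signals), samples$array_id), ]
  probes <- probes[match(colnames(signals), probes$probe_id), ]
  structure(
    list(signals = signals, samples = samples, probes = probes),
    class = c(if (normalized) "norm_panel", "expr_panel")
  )
}

#' @export
print.expr_panel <- function(x, ...) {
  cat(sprintf("<%s> %d arrays x %d probes (%d strains%s)\n",
              if (inherits(x, "norm_panel")) "norm_panel" else "expr_panel",
              nrow(x$signals), ncol(x$signals),
              dplyr::n_distinct(x$samples$strain_id),
              if (any(x$samples$is_f1)) sprintf(", %d F1 arrays", sum(x$samples$is_f1)) else ""))
  invisible(x)
}

#' Tidy an expression panel into long format
#'
#' @param x An `expr_panel`.
#' @param ... Unused.
#' @return A tibble with one row per (array, probe) cell, carrying sample
#'   metadata and the signal value.
#' @export
tidy.expr_panel <- function(x, ...) {
  as_tibble(x$signals, rownames = "array_id") |>
    tidyr::pivot_longer(-"array_id", names_to = "probe_id", values_to = "value") |>
    dplyr::left_join(x$samples, by = "array_id")
}
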