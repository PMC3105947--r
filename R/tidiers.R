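# broom-style tidiers for result objects. scan_result and peak_catalog are
# already tibbles; their tidy() methods strip the subclass, and glance() gives
# the one-row peak/run summary.

#' @export
tidy.scan_result <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.scan_result <- function(x, ...) {
  j <- which.max(x$lrs)
  tibble(
    trait_id = attr(x, "trait_id") %||% "trait",
    n_strains = attr(x, "n_strains"),
    peak_chr = x$chromosome[j], peak_cm = x$cm[j], peak_mb = x$mb[j],
    peak_lrs = x$lrs[j], peak_lod = lrs_to_lod(x$lrs[j]),
    additive = x$additive[j], saturated = x$saturated[j]
  )
}

#' @export
tidy.peak_catalog <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.peak_catalog <- function(x, ...) {
  tibble(
    n_probes = nrow(x),
    n_cis = sum(x$class == "cis"),
    n_trans = sum(x$class == "trans"),
    n_unclassified = sum(x$class == "unclassified"),
    cis_window_mb = attr(x, "cis_window_mb"),
    max_lrs = if (nrow(x)) max(x$lrs) else NA_real_
  )
}

#' @export
tidy.null_distribution <- function(x, ...) {
  tibble(permutation = seq_len(x$n_perm), max_lrs = x$max_lrs)
}

#' @export
glance.null_distribution <- function(x, ...) {
  tibble(
    n_perm = x$n_perm, seed = x$seed,
    lrs_threshold_05 = genomewide_threshold(x, 0.05),
    lrs_threshold_01 = genomewide_threshold(x, 0.01)
  )
}

#' @export
tidy.strain_summary <- function(x, ...) {
  as_tibble(x$values, rownames = "strain") |>
    tidyr::pivot_longer(-"strain", names_to = "probe_id", values_to = "value")
}

#' @export
tidy.geno_panel <- function(x, ...) {
  as_tibble(x$calls, rownames = "strain") |>
    tidyr::pivot_longer(-"strain", names_to = "marker", values_to = "call") |>
    dplyr::left_join(x$map, by = "marker")
}
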