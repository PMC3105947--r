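# Small in-code fixtures shared across test files.

# A compact RI panel: 5 chromosomes x 60 cM, 2 cM marker spacing, 30 strains.
small_panel <- function(n_strains = 30, n_chromosomes = 5, length_cm = 60,
                        spacing_cm = 2, seed = 11) {
  map <- make_marker_map(n_chromosomes, length_cm, spacing_cm, mb_per_cm = 2,
                         seed = seed)
  simulate_ri_genotypes(map, n_strains, seed = seed + 1)
}

# Raw expression panel built by hand from an explicit signal matrix.
toy_panel <- function(signals, sex = NULL, is_f1 = NULL, chromosome = NULL,
                      mb = NULL, strain = NULL, normalized = FALSE) {
  n_arr <- nrow(signals)
  n_pr <- ncol(signals)
  if (is.null(rownames(signals))) rownames(signals) <- sprintf("arr%02d", seq_len(n_arr))
  if (is.null(colnames(signals))) colnames(signals) <- sprintf("p%03d", seq_len(n_pr))
  expression_panel(
    signals,
    samples = tibble::tibble(
      array_id = rownames(signals),
      strain_id = strain %||% rownames(signals),
      sex = sex %||% rep("F", n_arr),
      is_f1 = is_f1 %||% rep(FALSE, n_arr)
    ),
    probes = tibble::tibble(
      probe_id = colnames(signals),
      symbol = toupper(colnames(signals)),
      chromosome = chromosome %||% rep("1", n_pr),
      mb = mb %||% seq_len(n_pr)
    ),
    normalized = normalized
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wrap a matrix of per-strain values as a strain_summary.
as_summary <- function(values, chromosome = NULL, mb = NULL) {
  structure(
    list(
      values = values,
      n_reps = stats::setNames(rep(1L, nrow(values)), rownames(values)),
      probes = tibble::tibble(
        probe_id = colnames(values),
        symbol = toupper(colnames(values)),
        chromosome = chromosome %||% rep("1", ncol(values)),
        mb = mb %||% seq_len(ncol(values))
      )
    ),
    class = "strain_summary"
  )
}
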