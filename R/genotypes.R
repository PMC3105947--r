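#' RI-scale recombination fraction between two map positions
#'
#' Converts a genetic distance in centimorgans to the expected discordance
#' frequency between the fixed genotypes of two loci in a sib-mated recombinant
#' inbred line: the meiotic recombination fraction under the Haldane map
#' function, `r = (1 - exp(-2 d / 100)) / 2`, expanded to the RI scale by the
#' Haldane-Waterman formula `R = 4 r / (1 + 6 r)`.
#'
#' @param distance_cm Genetic distance(s) in centimorgans; non-negative.
#' @return Recombination fraction(s) on the RI scale, in `[0, 0.5)` (0.5 in the
#'   limit of unlinked loci).
#' @examples
#' ri_recombination_fraction(c(0, 25, 1e6))
#' @export
ri_recombination_fraction <- function(distance_cm) {
  if (!is.numeric(distance_cm) || any(is.na(distance_cm))) {
    abort("`distance_cm` must be numeric and non-missing.")
  }
  if (any(distance_cm < 0)) abort("`distance_cm` must be >= 0.")
  r <- (1 - exp(-2 * distance_cm / 100)) / 2
  4 * r / (1 + 6 * r)
}

#' Simulate genotypes for a panel of recombinant inbred strains
#'
#' Each strain is an independent homozygous mosaic of the two parental genomes
#' (coded B = -1, D = +1). Within a chromosome, genotypes follow a Markov chain:
#' the first marker is B or D with probability 1/2, and each subsequent marker
#' switches parental origin with the RI-scale recombination fraction of the
#' inter-marker distance ([ri_recombination_fraction()]). Residual
#' heterozygosity is not modelled.
#'
#' @param map Marker map from [make_marker_map()] or [read_genotypes()].
#' @param n_strains Number of RI strains (>= 2).
#' @param seed Integer seed.
#' @return A `geno_panel` object: list with `strains` (character), `calls`
#'   (strains x markers matrix of -1/+1, NA for missing) and `map`.
#' @examples
#' g <- simulate_ri_genotypes(make_marker_map(2, 50, 5), n_strains = 10, seed = 1)
#' dim(g$calls)
#' @export
simulate_ri_genotypes <- function(map, n_strains, seed = 1L) {
  validate_marker_map(map)
  if (nrow(map) == 0) abort("marker map is empty.")
  assert_scalar_number(n_strains, "n_strains", min = 2)
  n_strains <- as.integer(n_strains)

  strains <- sprintf("RI%03d", seq_len(n_strains))
  calls <- matrix(NA_real_, n_strains, nrow(map),
                  dimnames = list(strains, map$marker))
  withr::with_seed(as.integer(seed), {
    for (chr in chrom_levels(map$chromosome)) {
      idx <- which(map$chromosome == chr)
      R <- ri_recombination_fraction(diff(map$cm[idx]))
      g <- matrix(0, n_strains, length(idx))
      g[, 1] <- sample(c(-1, 1), n_strains, replace = TRUE)
      if (length(idx) > 1) {
        for (j in seq_along(R)) {
          flip <- rbinom(n_strains, 1L, R[j]) == 1L
          g[, j + 1] <- ifelse(flip, -g[, j], g[, j])
        }
      }
      calls[, idx] <- g
    }
  })
  geno_panel(calls, map)
}

#' Construct a genotype panel object
#'
#' @param calls Strains x markers numeric matrix with values -1 (B allele),
#'   +1 (D allele) or NA (missing); rownames are strain ids, colnames marker ids.
#' @param map Marker map tibble matching the columns of `calls`.
#' @return A validated `geno_panel`.
#' @export
geno_panel <- function(calls, map) {
  validate_marker_map(map)
  if (is.null(rownames(calls))) abort("`calls` must have strain rownames.")
  if (!identical(colnames(calls), map$marker)) {
    abort("columns of `calls` must match map$marker in order.")
  }
  vals <- calls[!is.na(calls)]
  if (!all(vals %in% c(-1, 1))) {
    abort("genotype calls must be -1 (B), +1 (D) or NA (RI strains are homozygous).")
  }
  structure(
    list(strains = rownames(calls), calls = calls, map = as_tibble(map)),
    class = "geno_panel"
  )
}

#' @export
print.geno_panel <- function(x, ...) {
  cat(sprintf("<geno_panel> %d strains x %d markers on %d chromosome(s)\n",
              length(x$strains), nrow(x$map),
              length(chrom_levels(x$map$chromosome))))
  invisible(x)
}
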