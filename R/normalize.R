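#' Quantile-normalize a log2 signal matrix across arrays
#'
#' Replaces each array's values with the mean, over arrays, of the values at
#' the same rank (the distribution-matching step of the RMA transform). Tied
#' values within an array all receive the mean of the rank-mean reference
#' values over the ranks the tie occupies, so the output is invariant to how
#' ties are ordered. After the transform every array has an identical sorted
#' value vector, and within-array rank order is preserved.
#'
#' @param mat Arrays x probes numeric matrix (>= 2 arrays).
#' @return Matrix of the same shape and dimnames.
#' @examples
#' quantile_normalize(rbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantile_normalize <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) abort("`mat` must be a numeric matrix.")
  if (nrow(mat) < 2) abort("quantile normalization needs >= 2 arrays.")
  ref <- colMeans(t(apply(mat, 1, sort)))
  out <- t(apply(mat, 1, function(x) {
    v <- ref[rank(x, ties.method = "first")]
    stats::ave(v, x, FUN = mean)   # ties share the mean reference over their ranks
  }))
  dimnames(out) <- dimnames(mat)
  out
}

#' Normalize a raw expression panel
#'
#' Applies the full normalization chain, in order: add an offset of 1 to each
#' signal (so all logs are positive), take log2, quantile-normalize across the
#' full set of arrays, compute per-array Z scores, then rescale as `2 Z + 8`.
#' On the resulting scale every array has mean 8 and (population) standard
#' deviation 2, all values are positive in practice, and one unit corresponds
#' to approximately a two-fold difference in expression.
#'
#' @param raw An `expr_panel` with non-negative signals, >= 2 arrays and
#'   >= 2 probes.
#' @return A `norm_panel` (same structure, normalized values).
#' @export
normalize_panel <- function(raw) {
  if (!inherits(raw, "expr_panel")) abort("`raw` must be an expr_panel.")
  sig <- raw$signals
  if (nrow(sig) < 2 || ncol(sig) < 2) abort("need >= 2 arrays and >= 2 probes.")
  if (any(sig < 0)) abort("raw signals must be >= 0.")
  qn <- quantile_normalize(log2(sig + 1))
  sds <- apply(qn, 1, pop_sd)
  if (any(sds == 0)) {
    abort(sprintf("array(s) with zero variance after quantile normalization: %s",
                  paste(rownames(qn)[sds == 0], collapse = ", ")))
  }
  z <- (qn - rowMeans(qn)) / sds
  expression_panel(2 * z + 8, raw$samples, raw$probes, normalized = TRUE)
}

#' Summarize a normalized panel to one value per strain
#'
#' Mapping consumes one phenotype value per strain; replicate arrays are
#' averaged (arithmetic mean) and F1-hybrid arrays are excluded, since F1s
#' carry no fixed recombinant genotype.
#'
#' @param norm A `norm_panel`.
#' @return A `strain_summary`: list with `values` (strains x probes matrix of
#'   per-strain means), `n_reps` (named replicate counts) and `probes`
#'   annotation.
#' @export
summarize_by_strain <- function(norm) {
  if (!inherits(norm, "norm_panel")) abort("`norm` must be a normalized panel.")
  keep <- !norm$samples$is_f1
  sig <- norm$signals[keep, , drop = FALSE]
  strain <- norm$samples$strain_id[keep]
  vals <- rowsum(sig, strain)
  cnt <- as.vector(table(strain)[rownames(vals)])
  vals <- vals / cnt
  structure(
    list(values = vals,
         n_reps = setNames(cnt, rownames(vals)),
         probes = norm$probes),
    class = "strain_summary"
  )
}

#' @export
print.strain_summary <- function(x, ...) {
  cat(sprintf("<strain_summary> %d strains x %d probes (replicates %s)\n",
              nrow(x$values), ncol(x$values),
              paste(range(x$n_reps), collapse = "-")))
  invisible(x)
}

#' Histogram of per-probe expression ranges
#'
#' For each probe, the range is the difference between the highest and lowest
#' expression across strains (or arrays), in normalized units where one unit is
#' about a two-fold change. Probes are binned into left-closed, right-open
#' log2-range bins 0-1, 1-2, ..., 6+ (fold ranges 1-2x, 2-4x, ..., >64x).
#'
#' @param x A `norm_panel` or `strain_summary`.
#' @return A tibble with columns `fold_range`, `log2_range` and `n_probes`;
#'   counts sum to the number of probes.
#' @export
fold_range_histogram <- function(x) {
  vals <- if (inherits(x, "strain_summary")) x$values
          else if (inherits(x, "norm_panel")) x$signals
          else abort("`x` must be a norm_panel or strain_summary.")
  if (ncol(vals) < 1) abort("need >= 1 probe.")
  rng <- apply(vals, 2, function(v) max(v) - min(v))
  edges <- c(0:6, Inf)
  fold_lab <- c("1-2", "2-4", "4-8", "8-16", "16-32", "32-64", "64-inf")
  log2_lab <- c("0-1", "1-2", "2-3", "3-4", "4-5", "5-6", "6-inf")
  bin <- cut(rng, breaks = edges, right = FALSE, include.lowest = TRUE,
             labels = log2_lab)
  tibble(
    fold_range = fold_lab,
    log2_range = log2_lab,
    n_probes = as.integer(table(factor(bin, levels = log2_lab)))
  )
}
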