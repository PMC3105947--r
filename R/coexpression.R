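#' Two-sided p-value for a correlation coefficient
#'
#' Exact under bivariate normality: `t = r sqrt(n-2) / sqrt(1-r^2)` referred
#' to a t distribution with `n - 2` degrees of freedom. The same transform is
#' applied to Spearman's rho where used (a documented approximation). For
#' `|r| = 1` the p-value is 0 and the result carries an `underflow` attribute.
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @param n Number of paired observations (>= 4).
#' @return Two-sided p-value(s), vectorized over `r`.
#' @examples
#' correlation_test(0.8, 57)   # < 1e-12
#' @export
correlation_test <- function(r, n) {
  if (any(abs(r) > 1, na.rm = TRUE)) abort("`r` must lie in [-1, 1].")
  assert_scalar_number(n, "n", min = 4)
  p <- rep(NA_real_, length(r))
  lim <- !is.na(r) & abs(r) == 1
  ok <- !is.na(r) & !lim
  p[lim] <- 0
  tt <- r[ok] * sqrt(n - 2) / sqrt(1 - r[ok]^2)
  p[ok] <- 2 * pt(-abs(tt), df = n - 2)
  if (any(lim)) attr(p, "underflow") <- TRUE
  p
}

#' Correlated probe pairs across strains
#'
#' Computes Pearson and Spearman correlations between all probe pairs of a
#' strain summary and returns the unordered pairs whose chosen statistic
#' exceeds `threshold` in absolute value. Constant probes are excluded with a
#' warning. Each pair is listed once with `probe_a < probe_b`; both statistics
#' and the t-based p-value of the chosen one are reported.
#'
#' @param summary A `strain_summary` with >= 4 strains.
#' @param method `"pearson"` (default) or `"spearman"`: which statistic the
#'   threshold applies to.
#' @param threshold Absolute correlation threshold in `(0, 1]`.
#' @return A tibble `probe_a`, `probe_b`, `pearson_r`, `spearman_rho`, `n`,
#'   `p`, sorted by decreasing absolute chosen statistic then pair ids.
#' @export
correlation_pairs <- function(summary, method = c("pearson", "spearman"),
                              threshold = 0.8) {
  if (!inherits(summary, "strain_summary")) abort("`summary` must be a strain_summary.")
  method <- match.arg(method)
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1].")
  vals <- summary$values
  n <- nrow(vals)
  if (n < 4) abort("need >= 4 strains for correlation analysis.")
  constant <- apply(vals, 2, stats::sd) == 0
  if (any(constant)) {
    warn(sprintf("%d constant probe(s) excluded from pairing.", sum(constant)))
    vals <- vals[, !constant, drop = FALSE]
  }
  if (ncol(vals) < 2) return(tibble(
    probe_a = character(), probe_b = character(), pearson_r = numeric(),
    spearman_rho = numeric(), n = integer(), p = numeric()
  ))
  rp <- cor(vals, method = "pearson")
  rs <- cor(vals, method = "spearman")
  chosen <- if (method == "pearson") rp else rs
  # tiny slack so exact duplicates (cor = 1 up to rounding) pass threshold = 1
  idx <- which(upper.tri(chosen) & abs(chosen) >= threshold - 1e-12, arr.ind = TRUE)
  pvals <- as.numeric(correlation_test(chosen[idx], n))
  out <- tibble(
    probe_a = colnames(vals)[idx[, 1]],
    probe_b = colnames(vals)[idx[, 2]],
    pearson_r = rp[idx],
    spearman_rho = rs[idx],
    n = n,
    p = pvals
  )
  stat <- if (method == "pearson") out$pearson_r else out$spearman_rho
  out[order(-abs(stat), out$probe_a, out$probe_b), ]
}

#' Seed-gene principal-component signature
#'
#' Extracts a cell-type style expression signature: the first principal
#' component of a set of seed marker probes (computed on strain-standardized
#' seed vectors, i.e. correlation-matrix PCA; orientation fixed so the mean
#' seed loading is positive), then every probe whose correlation with the PC1
#' strain scores clears a threshold. Gating can be on the absolute correlation
#' (`threshold`) or on its t-based p-value (`p_threshold`); members are capped
#' at `max_members` by descending absolute correlation. Seed probes are always
#' recorded, member or not.
#'
#' @param summary A `strain_summary` with >= 4 strains.
#' @param seed_probes Two or more probe ids present in the summary; zero-
#'   variance seeds are dropped with a warning.
#' @param threshold Absolute correlation threshold for membership (default
#'   0.8); ignored when `p_threshold` is given.
#' @param p_threshold Optional p-value gate replacing the correlation gate.
#' @param max_members Cap on the member list (default unlimited).
#' @return A `pc_signature`: list with `seeds`, `scores` (tibble strain,
#'   pc1), `members` (tibble probe_id, symbol, r, p), `threshold` and
#'   `var_explained`.
#' @export
pc_signature <- function(summary, seed_probes, threshold = 0.8,
                         p_threshold = NULL, max_members = Inf) {
  if (!inherits(summary, "strain_summary")) abort("`summary` must be a strain_summary.")
  if (length(seed_probes) < 2) abort("need >= 2 seed probes.")
  vals <- summary$values
  if (nrow(vals) < 4) abort("need >= 4 strains.")
  missing <- setdiff(seed_probes, colnames(vals))
  if (length(missing) > 0) {
    abort(sprintf("seed probe(s) absent from summary: %s",
                  paste(missing, collapse = ", ")))
  }
  seeds <- vals[, seed_probes, drop = FALSE]
  zv <- apply(seeds, 2, stats::sd) == 0
  if (any(zv)) {
    warn(sprintf("zero-variance seed(s) excluded: %s",
                 paste(colnames(seeds)[zv], collapse = ", ")))
    seeds <- seeds[, !zv, drop = FALSE]
  }
  if (ncol(seeds) < 1) abort("no usable seed probes (all zero variance).")

  pca <- prcomp(seeds, center = TRUE, scale. = TRUE)
  flip <- if (mean(pca$rotation[, 1]) < 0) -1 else 1
  scores <- flip * pca$x[, 1]

  r <- as.vector(suppressWarnings(cor(scores, vals)))
  p <- as.numeric(correlation_test(r, nrow(vals)))
  cand <- tibble(
    probe_id = colnames(vals),
    symbol = summary$probes$symbol[match(colnames(vals), summary$probes$probe_id)],
    r = r, p = p
  )
  keep <- if (!is.null(p_threshold)) !is.na(cand$p) & cand$p <= p_threshold
          else !is.na(cand$r) & abs(cand$r) >= threshold
  members <- cand[keep, ] |> dplyr::arrange(dplyr::desc(abs(.data$r)))
  if (is.finite(max_members)) members <- head(members, max_members)

  structure(
    list(
      seeds = cand[cand$probe_id %in% colnames(seeds), ],
      scores = tibble(strain = rownames(vals), pc1 = unname(scores)),
      members = members,
      threshold = if (!is.null(p_threshold)) p_threshold else threshold,
      gate = if (!is.null(p_threshold)) "p" else "r",
      var_explained = unname(pca$sdev[1]^2 / sum(pca$sdev^2))
    ),
    class = "pc_signature"
  )
}

#' @export
print.pc_signature <- function(x, ...) {
  cat(sprintf("<pc_signature> %d seeds, %d members at %s %s %.3g (PC1 %.0f%% of seed variance)\n",
              nrow(x$seeds), nrow(x$members),
              if (x$gate == "p") "p <=" else "|r| >=",
              "", x$threshold, 100 * x$var_explained))
  invisible(x)
}

#' @export
tidy.pc_signature <- function(x, ...) x$members

#' @export
glance.pc_signature <- function(x, ...) {
  tibble(n_seeds = nrow(x$seeds), n_members = nrow(x$members),
         gate = x$gate, threshold = x$threshold,
         var_explained = x$var_explained)
}
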