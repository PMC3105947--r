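# Array-identity quality control: sex inference from sex-marker transcripts
# (Xist-like female markers, Y-linked male markers) and strain verification
# from Mendelian bimodal transcripts whose expression tracks the genotype at
# their cognate locus.

# Deterministic 1-D 2-means split: centers seeded at the range extremes.
# Returns cluster labels (1 = low, 2 = high) or NULL when the values carry no
# spread to split on.
split_two_means <- function(x, tol = 1e-8) {
  if (diff(range(x)) < tol) return(NULL)
  km <- stats::kmeans(x, centers = matrix(c(min(x), max(x)), 2, 1))
  if (km$centers[1] <= km$centers[2]) km$cluster else 3L - km$cluster
}

# Mean silhouette width of a 1-D two-cluster split; gauges bimodality.
silhouette_1d <- function(x, cluster) {
  if (length(unique(cluster)) < 2) return(0)
  s <- vapply(seq_along(x), function(i) {
    own <- x[cluster == cluster[i]]
    oth <- x[cluster != cluster[i]]
    a <- if (length(own) > 1) sum(abs(x[i] - own)) / (length(own) - 1) else 0
    b <- mean(abs(x[i] - oth))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Check declared sex of each array against sex-marker expression
#'
#' Computes, per array, a sex score = mean expression of female-marker probes
#' minus mean expression of male-marker probes, splits arrays by 2-means, and
#' calls the high cluster female. Arrays whose inferred sex disagrees with the
#' declared sex are flagged. When the score carries no usable separation
#' (spread below `min_gap`) every call is `"indeterminate"` and every array is
#' flagged.
#'
#' @param norm A `norm_panel`.
#' @param female_marker_probes,male_marker_probes Probe ids of transcripts
#'   expressed at high level in one sex only (e.g. an Xist-type probe for
#'   females; Y-linked transcripts for males). At least one marker probe in
#'   total is required.
#' @param min_gap Minimum between-cluster center separation (normalized units)
#'   below which calls are indeterminate.
#' @return A tibble with one row per array: `array_id`, `declared_sex`,
#'   `inferred_sex`, `flag`.
#' @export
sex_check <- function(norm, female_marker_probes = character(),
                      male_marker_probes = character(), min_gap = 1) {
  if (!inherits(norm, "norm_panel")) abort("`norm` must be a normalized panel.")
  markers <- c(female_marker_probes, male_marker_probes)
  if (length(markers) == 0) abort("at least one sex-marker probe is required.")
  missing <- setdiff(markers, colnames(norm$signals))
  if (length(missing) > 0) {
    abort(sprintf("sex-marker probe(s) absent from panel: %s",
                  paste(missing, collapse = ", ")))
  }
  score <- numeric(nrow(norm$signals))
  if (length(female_marker_probes) > 0) {
    score <- score + rowMeans(norm$signals[, female_marker_probes, drop = FALSE])
  }
  if (length(male_marker_probes) > 0) {
    score <- score - rowMeans(norm$signals[, male_marker_probes, drop = FALSE])
  }
  cl <- split_two_means(score)
  if (is.null(cl) || abs(diff(range(tapply(score, cl, mean)))) < min_gap) {
    inferred <- rep("indeterminate", length(score))
  } else {
    inferred <- unname(ifelse(cl == 2L, "F", "M"))
  }
  tibble(
    array_id = norm$samples$array_id,
    declared_sex = norm$samples$sex,
    inferred_sex = inferred,
    flag = inferred == "indeterminate" | inferred != norm$samples$sex
  )
}

#' Verify strain identity of each array from Mendelian bimodal transcripts
#'
#' Each Mendelian transcript's expression is driven by the genotype at its
#' cognate locus, so the low/high expression class of an array must match its
#' declared strain's genotype at the marker nearest the probe. For each probe,
#' arrays are split by 2-means; probes whose split is not convincingly bimodal
#' (mean silhouette below `min_silhouette`) are excluded with a warning. The
#' high class is oriented to the allele that maximizes overall concordance.
#' Arrays are flagged when their concordance over usable probes falls below
#' `min_concordance`. F1 arrays (heterozygous, intermediate expression) are
#' reported with `NA` concordance and never flagged.
#'
#' @param norm A `norm_panel`.
#' @param genotypes A `geno_panel` covering the panel's strains.
#' @param mendelian_probes Probe ids of bimodal Mendelian transcripts (>= 1).
#' @param min_concordance Flagging threshold on per-array concordance.
#' @param min_silhouette Bimodality threshold for including a probe.
#' @return A tibble with one row per array: `array_id`, `strain_id`,
#'   `concordance`, `n_probes_used`, `flag`.
#' @export
strain_identity_check <- function(norm, genotypes, mendelian_probes,
                                  min_concordance = 0.8, min_silhouette = 0.65) {
  if (!inherits(norm, "norm_panel")) abort("`norm` must be a normalized panel.")
  if (!inherits(genotypes, "geno_panel")) abort("`genotypes` must be a geno_panel.")
  if (length(mendelian_probes) == 0) abort("at least one Mendelian probe is required.")
  missing <- setdiff(mendelian_probes, colnames(norm$signals))
  if (length(missing) > 0) {
    abort(sprintf("Mendelian probe(s) absent from panel: %s",
                  paste(missing, collapse = ", ")))
  }
  map <- genotypes$map
  samples <- norm$samples
  n_arr <- nrow(samples)
  match_mat <- matrix(NA, n_arr, length(mendelian_probes))
  used <- logical(length(mendelian_probes))

  for (k in seq_along(mendelian_probes)) {
    p <- mendelian_probes[k]
    ann <- norm$probes[norm$probes$probe_id == p, ]
    near <- which(map$chromosome == ann$chromosome)
    if (length(near) == 0) {
      warn(sprintf("probe %s: no markers on chromosome %s; skipped.", p, ann$chromosome))
      next
    }
    marker <- map$marker[near[which.min(abs(map$mb[near] - ann$mb))]]
    x <- norm$signals[, p]
    cl <- split_two_means(x)
    if (is.null(cl) || silhouette_1d(x, cl) < min_silhouette) {
      warn(sprintf("probe %s: expression not bimodal; excluded from strain check.", p))
      next
    }
    geno <- genotypes$calls[match(samples$strain_id, genotypes$strains), marker]
    obs_high <- cl == 2L
    exp_d <- geno == 1
    agree <- mean(obs_high == exp_d, na.rm = TRUE)
    if (is.nan(agree)) next
    # orient the high class to whichever allele fits the panel better
    match_mat[, k] <- if (agree >= 0.5) obs_high == exp_d else obs_high != exp_d
    used[k] <- TRUE
  }
  if (!any(used)) abort("no usable Mendelian probes (all excluded).")

  conc <- rowMeans(match_mat[, used, drop = FALSE], na.rm = TRUE)
  n_used <- rowSums(!is.na(match_mat[, used, drop = FALSE]))
  conc[samples$is_f1 | n_used == 0] <- NA_real_
  tibble(
    array_id = samples$array_id,
    strain_id = samples$strain_id,
    concordance = conc,
    n_probes_used = as.integer(n_used),
    flag = !is.na(conc) & conc < min_concordance
  )
}
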