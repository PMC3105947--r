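#' Expected allele dosage on a pseudomarker grid
#'
#' Builds the interval-mapping substrate: a grid of positions at `step_cm`
#' intervals along every chromosome (observed marker positions always
#' included), with, for each strain, the conditional expectation of the allele
#' dosage `P(D) - P(B)` in `[-1, 1]` given the nearest non-missing flanking
#' marker genotypes. Transitions between positions follow a Markov model with
#' RI-scale recombination fractions ([ri_recombination_fraction()]) of the cM
#' separations. At an observed, non-missing marker the dosage equals the
#' observed code. Physical positions are interpolated linearly in cM between
#' flanking markers.
#'
#' @param genotypes A `geno_panel`.
#' @param step_cm Grid step in centimorgans (default 1).
#' @return A `position_grid`: list with `positions` (tibble: `chromosome`,
#'   `cm`, `mb`, `left_marker`, `right_marker`), `dosage` (strains x positions
#'   matrix) and `strains`.
#' @export
expected_dosage <- function(genotypes, step_cm = 1) {
  if (!inherits(genotypes, "geno_panel")) abort("`genotypes` must be a geno_panel.")
  assert_scalar_number(step_cm, "step_cm", min = 0, strict_min = TRUE)
  map <- genotypes$map
  calls <- genotypes$calls
  S <- nrow(calls)

  pos_list <- list()
  dos_list <- list()
  for (chr in chrom_levels(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    if (length(idx) == 0) {
      warn(sprintf("chromosome %s has no markers; skipped.", chr))
      next
    }
    mcm <- map$cm[idx]
    mmb <- map$mb[idx]
    g <- calls[, idx, drop = FALSE]

    cm <- sort(unique(c(seq(min(mcm), max(mcm), by = step_cm), mcm)))
    P <- length(cm)
    # flanking marker indices within the chromosome
    li <- findInterval(cm, mcm)
    at_marker <- cm %in% mcm
    ri <- ifelse(at_marker, li, pmin(li + 1L, length(idx)))

    mb <- ifelse(at_marker, mmb[li],
                 mmb[li] + (cm - mcm[li]) / (mcm[ri] - mcm[li]) * (mmb[ri] - mmb[li]))

    rL <- ri_recombination_fraction(cm - mcm[li])
    rR <- ri_recombination_fraction(mcm[ri] - cm)
    gL <- g[, li, drop = FALSE]
    gR <- g[, ri, drop = FALSE]
    rLm <- matrix(rL, S, P, byrow = TRUE)
    rRm <- matrix(rR, S, P, byrow = TRUE)

    # P(flank -> D) under the RI-scale Markov chain, then condition on both flanks
    tLD <- ifelse(gL == 1, 1 - rLm, rLm)
    tRD <- ifelse(gR == 1, 1 - rRm, rRm)
    numD <- tLD * tRD
    numB <- (1 - tLD) * (1 - tRD)
    dos <- (numD - numB) / (numD + numB)

    # missing flanks: fall back to the nearest non-missing marker on each side
    na_cells <- which(is.na(dos), arr.ind = TRUE)
    if (nrow(na_cells) > 0) {
      for (rw in seq_len(nrow(na_cells))) {
        s <- na_cells[rw, 1]; j <- na_cells[rw, 2]
        obs <- which(!is.na(g[s, ]))
        lf <- obs[obs <= li[j]]
        rf <- obs[obs >= ri[j]]
        lf <- if (length(lf)) max(lf) else NA_integer_
        rf <- if (length(rf)) min(rf) else NA_integer_
        if (is.na(lf) && is.na(rf)) { dos[s, j] <- NA_real_; next }
        if (is.na(lf) || is.na(rf)) {
          k <- if (is.na(lf)) rf else lf
          R1 <- ri_recombination_fraction(abs(cm[j] - mcm[k]))
          dos[s, j] <- (1 - 2 * R1) * g[s, k]
        } else {
          RL <- ri_recombination_fraction(cm[j] - mcm[lf])
          RR <- ri_recombination_fraction(mcm[rf] - cm[j])
          tld <- if (g[s, lf] == 1) 1 - RL else RL
          trd <- if (g[s, rf] == 1) 1 - RR else RR
          nd <- tld * trd; nb <- (1 - tld) * (1 - trd)
          dos[s, j] <- (nd - nb) / (nd + nb)
        }
      }
    }
    pos_list[[chr]] <- tibble(
      chromosome = chr, cm = cm, mb = mb,
      left_marker = map$marker[idx][li], right_marker = map$marker[idx][ri]
    )
    dos_list[[chr]] <- dos
  }
  positions <- dplyr::bind_rows(pos_list)
  dosage <- do.call(cbind, dos_list)
  rownames(dosage) <- rownames(calls)
  structure(list(positions = positions, dosage = dosage, strains = rownames(calls)),
            class = "position_grid")
}

#' @export
print.position_grid <- function(x, ...) {
  cat(sprintf("<position_grid> %d positions on %d chromosome(s), %d strains\n",
              nrow(x$positions), length(chrom_levels(x$positions$chromosome)),
              length(x$strains)))
  invisible(x)
}

# Vectorized Haley-Knott engine. X: n x P dosage (complete), Y: n x Q centered
# traits. Returns list(lrs = P x Q, additive = P x Q, saturated = P x Q logical).
# Uses the simple-regression identity RSS1 = RSS0 (1 - r^2), so
# LRS = n log(RSS0 / RSS1) = -n log(1 - r^2).
hk_engine <- function(X, Y, sat_eps = 1e-12) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  sxx <- colSums(Xc^2)
  syy <- colSums(Yc^2)
  sxy <- crossprod(Xc, Yc)                       # P x Q
  ok <- sxx > 0
  r2 <- matrix(0, ncol(X), ncol(Y))
  r2[ok, ] <- sxy[ok, , drop = FALSE]^2 /
    (sxx[ok] * matrix(syy, sum(ok), ncol(Y), byrow = TRUE))
  r2 <- pmin(r2, 1)
  saturated <- (1 - r2) < sat_eps
  lrs <- -n * log(pmax(1 - r2, sat_eps))
  additive <- sweep(sxy, 1, ifelse(ok, sxx, NA_real_), "/")
  additive[!ok, ] <- NA_real_
  lrs[!ok, ] <- 0
  list(lrs = lrs, additive = additive, saturated = saturated)
}

#' Haley-Knott regression scan of one trait
#'
#' At every grid position, fits the least-squares regression of the per-strain
#' trait on the expected allele dosage (intercept plus slope) and reports the
#' likelihood ratio statistic `LRS = n ln(RSS0 / RSS1)` (RSS0 from the
#' intercept-only model) and the additive coefficient (slope; positive values
#' mean the D allele increases the trait). Strains with a missing trait value
#' are dropped; strains with missing dosage at a position are dropped pairwise
#' for that position. A position fitting the trait essentially perfectly
#' (`RSS1 < 1e-12 RSS0`) has its LRS capped at `n ln(1e12)` and is flagged
#' `saturated`.
#'
#' @param trait Named numeric vector of per-strain values, or a two-column
#'   (strain, value) data frame. Needs >= 8 strains with data and non-zero
#'   variance.
#' @param grid A `position_grid` from [expected_dosage()].
#' @return A `scan_result` tibble: `chromosome`, `cm`, `mb`, `lrs`,
#'   `additive`, `saturated`, with attributes `n_strains` and `trait_id`.
#' @export
hk_scan <- function(trait, grid) {
  if (!inherits(grid, "position_grid")) abort("`grid` must be a position_grid.")
  y <- as_strain_values(trait)
  trait_id <- attr(trait, "trait_id") %||% "trait"
  common <- intersect(names(y)[!is.na(y)], grid$strains)
  if (length(common) < 8) abort("need >= 8 strains with trait and genotype data.")
  y <- y[common]
  if (stats::sd(y) == 0) abort("constant trait: variance is zero.")
  X <- grid$dosage[common, , drop = FALSE]

  if (!anyNA(X)) {
    eng <- hk_engine(X, matrix(y, ncol = 1))
    lrs <- unname(eng$lrs[, 1]); addv <- unname(eng$additive[, 1])
    sat <- unname(eng$saturated[, 1])
  } else {
    P <- ncol(X)
    lrs <- numeric(P); addv <- rep(NA_real_, P); sat <- logical(P)
    for (j in seq_len(P)) {
      use <- !is.na(X[, j])
      if (sum(use) < 8 || stats::sd(y[use]) == 0) next
      eng <- hk_engine(X[use, j, drop = FALSE], matrix(y[use], ncol = 1))
      lrs[j] <- eng$lrs[1, 1]; addv[j] <- eng$additive[1, 1]; sat[j] <- eng$saturated[1, 1]
    }
  }
  out <- dplyr::bind_cols(grid$positions,
                          tibble(lrs = lrs, additive = addv, saturated = sat))
  class(out) <- c("scan_result", class(out))
  attr(out, "n_strains") <- length(common)
  attr(out, "trait_id") <- trait_id
  out
}

#' Permutation null distribution of the genome-wide maximum LRS
#'
#' Permutes trait values over strain labels (dosages fixed), rescans the whole
#' genome per permutation, and records the genome-wide maximum LRS. The
#' resulting sample defines genome-wide empirical p-values
#' ([empirical_p()]) and significance thresholds ([genomewide_threshold()]).
#'
#' @param trait As in [hk_scan()].
#' @param grid A `position_grid`.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; results are reproducible bit-exactly.
#' @return A `null_distribution`: list with `max_lrs` (length `n_perm`),
#'   `n_perm` and `seed`.
#' @export
permutation_null <- function(trait, grid, n_perm = 1000, seed = 1L) {
  if (!inherits(grid, "position_grid")) abort("`grid` must be a position_grid.")
  assert_scalar_number(n_perm, "n_perm", min = 100)
  y <- as_strain_values(trait)
  common <- intersect(names(y)[!is.na(y)], grid$strains)
  if (length(common) < 8) abort("need >= 8 strains with trait and genotype data.")
  y <- y[common]
  if (stats::sd(y) == 0) abort("constant trait: variance is zero.")
  X <- grid$dosage[common, , drop = FALSE]
  n <- length(y)
  n_perm <- as.integer(n_perm)

  Yp <- withr::with_seed(as.integer(seed),
    vapply(seq_len(n_perm), function(i) y[sample.int(n)], numeric(n)))

  if (!anyNA(X)) {
    eng <- hk_engine(X, Yp)
    max_lrs <- apply(eng$lrs, 2, max)
  } else {
    max_lrs <- vapply(seq_len(n_perm), function(i) {
      yi <- setNames(Yp[, i], common)
      max(hk_scan(yi, grid_subset(grid, common))$lrs)
    }, numeric(1))
  }
  structure(list(max_lrs = max_lrs, n_perm = n_perm, seed = as.integer(seed)),
            class = "null_distribution")
}

grid_subset <- function(grid, strains) {
  structure(list(positions = grid$positions,
                 dosage = grid$dosage[strains, , drop = FALSE],
                 strains = strains),
            class = "position_grid")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d permutations; LRS 95th percentile %.2f\n",
              x$n_perm, genomewide_threshold(x, 0.05)))
  invisible(x)
}

#' Genome-wide empirical p-value of an observed maximum LRS
#'
#' Uses the plus-one estimator `p = (#\{null >= observed\} + 1) / (n_perm + 1)`,
#' which never returns exactly zero.
#'
#' @param observed_max Observed genome-wide maximum LRS.
#' @param null A `null_distribution`.
#' @return A probability in `(0, 1]`.
#' @export
empirical_p <- function(observed_max, null) {
  if (!inherits(null, "null_distribution")) abort("`null` must be a null_distribution.")
  if (length(null$max_lrs) == 0) abort("empty null distribution.")
  (sum(null$max_lrs >= observed_max) + 1) / (null$n_perm + 1)
}

#' Genome-wide LRS significance threshold
#'
#' @param null A `null_distribution`.
#' @param alpha Genome-wide type-I error rate (default 0.05).
#' @return The `1 - alpha` quantile of the permutation maxima.
#' @export
genomewide_threshold <- function(null, alpha = 0.05) {
  if (!inherits(null, "null_distribution")) abort("`null` must be a null_distribution.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  unname(quantile(null$max_lrs, 1 - alpha))
}

#' Convert between LRS and LOD
#'
#' `LOD = LRS / (2 ln 10)`; the two scales describe the same likelihood ratio.
#'
#' @param value Non-negative statistic value(s).
#' @return The converted value(s).
#' @examples
#' lod_to_lrs(50)   # 230.2585
#' @export
lrs_to_lod <- function(value) {
  if (any(value < 0)) abort("LRS must be >= 0.")
  value / (2 * log(10))
}

#' @rdname lrs_to_lod
#' @export
lod_to_lrs <- function(value) {
  if (any(value < 0)) abort("LOD must be >= 0.")
  value * 2 * log(10)
}
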