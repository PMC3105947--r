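#' Classify an eQTL peak as cis or trans
#'
#' A peak is *cis* when it lies on the transcript's own chromosome within a
#' 10 Mb window (inclusive) of the transcript's annotated position, *trans*
#' otherwise, and *unclassified* when the transcript is unmapped.
#'
#' @param probe_chr,probe_mb Transcript chromosome label and position (Mb);
#'   `"unmapped"` or `NA` gives `"unclassified"`.
#' @param peak_chr,peak_mb Peak chromosome and position (Mb).
#' @param cis_window_mb Window half-width in Mb (default 10, boundary
#'   inclusive).
#' @return Character vector in `{"cis", "trans", "unclassified"}`; vectorized
#'   over its arguments.
#' @examples
#' classify_eqtl("9", 30, "12", 50)          # trans
#' classify_eqtl("14", 51.7, "14", 52)       # cis
#' @export
classify_eqtl <- function(probe_chr, probe_mb, peak_chr, peak_mb,
                          cis_window_mb = 10) {
  unmapped <- is.na(probe_chr) | probe_chr == "unmapped" | is.na(probe_mb)
  cis <- !unmapped & as.character(probe_chr) == as.character(peak_chr) &
    abs(probe_mb - peak_mb) <= cis_window_mb
  dplyr::case_when(unmapped ~ "unclassified", cis ~ "cis", TRUE ~ "trans")
}

#' Transcriptome-wide eQTL scan
#'
#' Runs a Haley-Knott scan ([hk_scan()]) for every probe of a strain summary
#' over a pseudomarker grid, records each probe's peak (maximum-LRS position;
#' ties broken by lowest chromosome then lowest position), classifies it
#' cis/trans ([classify_eqtl()]), and returns a peak catalog. Probes with
#' variance below `min_variance` are skipped and reported in a message.
#' Optionally computes a genome-wide empirical p-value per probe by
#' permutation.
#'
#' @param summary A `strain_summary`.
#' @param grid A `position_grid` over the same strains.
#' @param min_variance Minimum per-probe variance across strains (default 0:
#'   only strictly constant probes are skipped).
#' @param cis_window_mb Cis window (Mb, inclusive).
#' @param n_perm Permutations per probe for empirical p-values; `NULL` (the
#'   default) skips them, as transcriptome-scale permutation cost grows with
#'   the probe count.
#' @param seed Seed for the per-probe permutations.
#' @param chunk_size Probes scanned per matrix block (memory control).
#' @return A `peak_catalog` tibble: `probe_id`, `symbol`, `probe_chr`,
#'   `probe_mb`, `peak_chr`, `peak_mb`, `peak_cm`, `lrs`, `lod`, `additive`,
#'   `mean_expr`, `p` (NA unless `n_perm` given), `class`; ordered by
#'   `probe_id`.
#' @export
transcriptome_scan <- function(summary, grid, min_variance = 0,
                               cis_window_mb = 10, n_perm = NULL, seed = 1L,
                               chunk_size = 2000L) {
  if (!inherits(summary, "strain_summary")) abort("`summary` must be a strain_summary.")
  if (!inherits(grid, "position_grid")) abort("`grid` must be a position_grid.")
  common <- intersect(rownames(summary$values), grid$strains)
  if (length(common) < 8) abort("need >= 8 strains shared by summary and grid.")
  vals <- summary$values[common, , drop = FALSE]
  X <- grid$dosage[common, , drop = FALSE]
  pos <- grid$positions
  n <- length(common)

  v <- apply(vals, 2, stats::var)
  skip <- v <= min_variance | v == 0
  if (any(skip)) {
    inform(sprintf("%d probe(s) below the variance filter; skipped.", sum(skip)))
  }
  probes <- colnames(vals)[!skip]
  if (length(probes) == 0) {
    return(empty_peak_catalog(cis_window_mb))
  }

  complete <- !anyNA(X)
  res <- purrr::map_dfr(split(probes, ceiling(seq_along(probes) / chunk_size)),
    function(pb) {
      Y <- vals[, pb, drop = FALSE]
      if (complete) {
        eng <- hk_engine(X, Y)
        peak_j <- apply(eng$lrs, 2, which.max)   # first max = lowest chr, then pos
        tibble(
          probe_id = pb,
          peak_chr = pos$chromosome[peak_j],
          peak_mb = pos$mb[peak_j],
          peak_cm = pos$cm[peak_j],
          lrs = eng$lrs[cbind(peak_j, seq_along(pb))],
          additive = eng$additive[cbind(peak_j, seq_along(pb))]
        )
      } else {
        purrr::map_dfr(pb, function(p) {
          sc <- hk_scan(setNames(Y[, p], rownames(Y)), grid_subset(grid, common))
          j <- which.max(sc$lrs)
          tibble(probe_id = p, peak_chr = sc$chromosome[j], peak_mb = sc$mb[j],
                 peak_cm = sc$cm[j], lrs = sc$lrs[j], additive = sc$additive[j])
        })
      }
    })

  ann <- summary$probes[match(res$probe_id, summary$probes$probe_id), ]
  res <- res |>
    dplyr::mutate(
      symbol = ann$symbol,
      probe_chr = ann$chromosome,
      probe_mb = ann$mb,
      lod = lrs_to_lod(.data$lrs),
      mean_expr = colMeans(vals)[.data$probe_id],
      p = NA_real_,
      class = classify_eqtl(.data$probe_chr, .data$probe_mb,
                            .data$peak_chr, .data$peak_mb, cis_window_mb)
    )

  if (!is.null(n_perm)) {
    res$p <- purrr::map2_dbl(res$probe_id, seq_len(nrow(res)), function(p, i) {
      y <- setNames(vals[, p], rownames(vals))
      null <- permutation_null(y, grid_subset(grid, common), n_perm = n_perm,
                               seed = derive_seed(seed, p))
      empirical_p(res$lrs[i], null)
    })
  }

  out <- res |>
    dplyr::select("probe_id", "symbol", "probe_chr", "probe_mb", "peak_chr",
                  "peak_mb", "peak_cm", "lrs", "lod", "additive", "mean_expr",
                  "p", "class") |>
    dplyr::arrange(.data$probe_id)
  class(out) <- c("peak_catalog", class(out))
  attr(out, "cis_window_mb") <- cis_window_mb
  attr(out, "n_strains") <- n
  out
}

empty_peak_catalog <- function(cis_window_mb) {
  out <- tibble(
    probe_id = character(), symbol = character(), probe_chr = character(),
    probe_mb = numeric(), peak_chr = character(), peak_mb = numeric(),
    peak_cm = numeric(), lrs = numeric(), lod = numeric(), additive = numeric(),
    mean_expr = numeric(), p = numeric(), class = character()
  )
  class(out) <- c("peak_catalog", class(out))
  attr(out, "cis_window_mb") <- cis_window_mb
  out
}

#' Tabulate cis/trans counts at LRS thresholds
#'
#' Counts, for each LRS threshold, the catalogued transcripts whose peak LRS
#' meets or exceeds it, split by cis/trans class. Counts are monotone
#' non-increasing in the threshold.
#'
#' @param records A `peak_catalog`.
#' @param thresholds LRS thresholds (default the conventional ladder
#'   12, 16, 20, 30, 50).
#' @return A tibble `threshold`, `n_cis`, `n_trans`.
#' @export
threshold_counts <- function(records, thresholds = c(12, 16, 20, 30, 50)) {
  if (!all(c("lrs", "class") %in% names(records))) {
    abort("`records` must be a peak catalog with lrs and class columns.")
  }
  purrr::map_dfr(sort(thresholds), function(th) {
    tibble(
      threshold = th,
      n_cis = sum(records$class == "cis" & records$lrs >= th),
      n_trans = sum(records$class == "trans" & records$lrs >= th)
    )
  })
}

#' Candidate genes: cis-eQTLs within a phenotype QTL interval
#'
#' Filters a peak catalog to cis-classified transcripts whose annotated
#' position falls inside a closed physical interval on a chromosome and whose
#' peak LRS meets a minimum, the standard shortlisting step for candidate
#' genes under a phenotype QTL.
#'
#' @param records A `peak_catalog`.
#' @param chrom Chromosome label of the query interval.
#' @param start_mb,end_mb Interval bounds in Mb (closed; `start_mb <= end_mb`).
#' @param min_lrs Minimum peak LRS (default 12).
#' @return A tibble `probe_id`, `symbol`, `probe_chr`, `probe_mb`,
#'   `mean_expr`, `lrs`, sorted by position.
#' @export
cis_candidates_in_interval <- function(records, chrom, start_mb, end_mb,
                                       min_lrs = 12) {
  if (!is.numeric(start_mb) || !is.numeric(end_mb) || start_mb > end_mb) {
    abort("malformed interval: need numeric start_mb <= end_mb.")
  }
  records |>
    dplyr::filter(.data$class == "cis",
                  .data$probe_chr == as.character(chrom),
                  .data$probe_mb >= start_mb, .data$probe_mb <= end_mb,
                  .data$lrs >= min_lrs) |>
    dplyr::select("probe_id", "symbol", "probe_chr", "probe_mb",
                  "mean_expr", "lrs") |>
    dplyr::arrange(.data$probe_mb) |>
    as_tibble()
}
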