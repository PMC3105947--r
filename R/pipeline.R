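#' Pipeline configuration
#'
#' Bundles the fixed constants of the analysis (1 cM scan step, 10 Mb cis
#' window, LRS threshold ladder 12/16/20/30/50, correlation threshold 0.8)
#' with input paths and the mandatory seed. Any stochastic stage derives its
#' own child seed from `seed` by stable hashing, so stages can be re-run
#' independently and a rerun with the same config is bit-identical.
#'
#' @param genotypes,signals,samples,probes Input file paths (the dialects of
#'   [read_genotypes()] and [read_expression()]).
#' @param out_dir Output directory (created if absent).
#' @param step_cm Pseudomarker grid step (cM).
#' @param n_perm Permutations for the genome-wide threshold stage; 0 skips it.
#' @param seed Integer seed (mandatory).
#' @param lrs_thresholds LRS ladder for the cis/trans count table.
#' @param cis_window_mb Cis window (Mb).
#' @param cor_threshold Absolute correlation threshold for network pairs.
#' @param min_variance Per-probe variance filter for the transcriptome scan.
#' @param female_marker_probes,male_marker_probes,mendelian_probes Optional QC
#'   marker probe ids; the corresponding check is skipped when empty.
#' @param signature_seeds Optional list of character vectors of seed probe ids;
#'   one signature report per element.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genotypes, signals, samples, probes, out_dir,
                            step_cm = 1, n_perm = 0, seed = 1L,
                            lrs_thresholds = c(12, 16, 20, 30, 50),
                            cis_window_mb = 10, cor_threshold = 0.8,
                            min_variance = 0,
                            female_marker_probes = character(),
                            male_marker_probes = character(),
                            mendelian_probes = character(),
                            signature_seeds = list()) {
  stopifnot(step_cm > 0, cis_window_mb > 0, cor_threshold > 0, n_perm >= 0)
  if (is.null(seed)) abort("`seed` is mandatory.")
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  # the output directory does not affect the analysis, so it is not hashed
  jsonlite::write_json(config[setdiff(names(config), "out_dir")], tmp,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: read inputs, normalize, QC (when marker probes are
#' configured), strain summary, heritability (when replicates exist), grid
#' construction, transcriptome-wide eQTL scan and classification, threshold
#' counts, genome-wide permutation threshold (when `n_perm > 0`), correlation
#' pairs and any configured PC1 signatures. All tables are written to
#' `out_dir` with the manifest hash in a header comment; a `manifest.json`
#' records the config, seed and package version. QC anomalies warn but do not
#' abort unless `strict = TRUE`.
#'
#' @param config A [pipeline_config()].
#' @param strict Abort on QC flags (default FALSE: warn only).
#' @return Invisibly, a list of the in-memory results (`normalized`,
#'   `summary`, `qc`, `heritability`, `peaks`, `counts`, `threshold`,
#'   `pairs`, `signatures`, `manifest`).
#' @export
run_pipeline <- function(config, strict = FALSE) {
  if (!inherits(config, "pipeline_config")) abort("`config` must be a pipeline_config.")
  for (f in c("genotypes", "signals", "samples", "probes")) {
    if (!file.exists(config[[f]])) {
      abort(sprintf("stage read: input file `%s` not found: %s", f, config[[f]]))
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  hdr <- sprintf("manifest_hash: %s", hash)
  out <- function(name) file.path(config$out_dir, name)

  inform("stage read: loading inputs")
  geno <- read_genotypes(config$genotypes)
  raw <- read_expression(config$signals, config$samples, config$probes)

  inform("stage normalize")
  norm <- normalize_panel(raw)

  qc <- NULL
  if (length(c(config$female_marker_probes, config$male_marker_probes)) > 0 ||
      length(config$mendelian_probes) > 0) {
    inform("stage qc")
    qc_parts <- list()
    if (length(c(config$female_marker_probes, config$male_marker_probes)) > 0) {
      sx <- sex_check(norm, config$female_marker_probes, config$male_marker_probes)
      qc_parts$sex <- sx
      if (any(sx$flag)) {
        msg <- sprintf("qc: %d array(s) flagged by the sex check.", sum(sx$flag))
        if (strict) abort(msg) else warn(msg)
      }
    }
    if (length(config$mendelian_probes) > 0) {
      st <- strain_identity_check(norm, geno, config$mendelian_probes)
      qc_parts$strain <- st
      if (any(st$flag)) {
        msg <- sprintf("qc: %d array(s) flagged by the strain-identity check.", sum(st$flag))
        if (strict) abort(msg) else warn(msg)
      }
    }
    qc <- dplyr::bind_rows(qc_parts, .id = "check")
    write_outputs(qc, out("qc_report.tsv"), comments = hdr)
  }

  inform("stage summarize")
  summ <- summarize_by_strain(norm)
  write_outputs(as_tibble(summ$values, rownames = "strain"),
                out("strain_means.tsv"), comments = hdr)

  herit <- NULL
  if (any(table(norm$samples$strain_id[!norm$samples$is_f1]) >= 2)) {
    inform("stage heritability")
    herit <- heritability_table(norm)
    write_outputs(herit, out("heritability.tsv"), comments = hdr)
  } else {
    inform("stage heritability: skipped (no replicate arrays)")
  }

  inform("stage grid")
  grid <- expected_dosage(geno, step_cm = config$step_cm)

  inform("stage scan")
  peaks <- transcriptome_scan(summ, grid, min_variance = config$min_variance,
                              cis_window_mb = config$cis_window_mb)
  write_outputs(peaks, out("peaks.tsv"), comments = hdr)
  counts <- threshold_counts(peaks, config$lrs_thresholds)
  write_outputs(counts, out("threshold_counts.tsv"), comments = hdr)

  thr <- NULL
  if (config$n_perm > 0) {
    inform("stage permutation threshold")
    y <- withr::with_seed(derive_seed(config$seed, "null_trait"),
                          setNames(rnorm(nrow(summ$values)), rownames(summ$values)))
    null <- permutation_null(y, grid, n_perm = config$n_perm,
                             seed = derive_seed(config$seed, "permutation"))
    thr <- genomewide_threshold(null, 0.05)
    write_outputs(tibble(alpha = 0.05, n_perm = config$n_perm, lrs_threshold = thr),
                  out("genomewide_threshold.tsv"), comments = hdr)
  }

  inform("stage networks")
  pairs <- correlation_pairs(summ, threshold = config$cor_threshold)
  write_outputs(pairs, out("correlation_pairs.tsv"), comments = hdr)

  signatures <- purrr::imap(config$signature_seeds, function(seeds, i) {
    sig <- pc_signature(summ, seeds, threshold = config$cor_threshold)
    write_outputs(sig$members, out(sprintf("signature_%s.tsv", i)), comments = hdr)
    sig
  })

  manifest <- list(
    package = "rieqtl",
    version = as.character(utils::packageVersion("rieqtl")),
    seed = config$seed,
    hash = hash,
    config = config[setdiff(names(config), "out_dir")]
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE, pretty = TRUE)
  invisible(list(normalized = norm, summary = summ, qc = qc,
                 heritability = herit, peaks = peaks, counts = counts,
                 threshold = thr, pairs = pairs, signatures = signatures,
                 manifest = manifest))
}

#' Simulate a BXD-scale dataset and write it to disk
#'
#' Generates a synthetic RI panel at the scale of the BXD family (57 strains,
#' 20 chromosomes of ~80 cM carrying ~3,800 markers by default), simulates an
#' expression panel over it with [simulate_expression_panel()], and writes the
#' genotype, signal, sample-sheet, probe-sheet and truth files plus a
#' manifest. Deterministic per seed.
#'
#' @param out_dir Output directory.
#' @param n_strains Number of RI strains (default 57).
#' @param n_chromosomes,chrom_length_cm,marker_spacing_cm,mb_per_cm Marker-map
#'   geometry (defaults: 19 autosomes + X, 80 cM each, 0.42 cM spacing for
#'   ~3,820 markers, 2 Mb/cM).
#' @param seed Integer seed.
#' @param ... Passed to [simulate_expression_panel()] (probe counts, planted
#'   effects, noise).
#' @return Invisibly, a list with `genotypes`, `panel`, `truth` and the file
#'   paths.
#' @export
run_simulate <- function(out_dir, n_strains = 57, n_chromosomes = 20,
                         chrom_length_cm = 80, marker_spacing_cm = 0.42,
                         mb_per_cm = 2, seed = 1L, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  map <- make_marker_map(n_chromosomes, chrom_length_cm, marker_spacing_cm,
                         mb_per_cm, seed = derive_seed(seed, "map"))
  geno <- simulate_ri_genotypes(map, n_strains, seed = derive_seed(seed, "geno"))
  sim <- simulate_expression_panel(geno, seed = derive_seed(seed, "expr"), ...)

  paths <- list(
    genotypes = file.path(out_dir, "genotypes.tsv"),
    signals = file.path(out_dir, "signals.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    probes = file.path(out_dir, "probes.tsv")
  )
  write_genotypes(geno, paths$genotypes)
  write_expression(sim$panel, paths$signals, paths$samples, paths$probes)
  for (nm in names(sim$truth)) {
    write_outputs(sim$truth[[nm]], file.path(out_dir, sprintf("truth_%s.tsv", nm)))
  }
  jsonlite::write_json(
    list(package = "rieqtl",
         version = as.character(utils::packageVersion("rieqtl")),
         seed = seed, n_strains = n_strains, n_markers = nrow(map)),
    file.path(out_dir, "simulate_manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(list(genotypes = geno, panel = sim$panel, truth = sim$truth),
              paths))
}
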