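# On-disk dialects: tab-delimited, UTF-8, "#"-prefixed comment lines permitted.
# Genotypes follow the GeneNetwork-style layout (markers as rows: chromosome,
# marker, cm, mb, then one column per strain, codes B/D/U). Expression panels
# are three files: a signal matrix (arrays x probes), a sample sheet and a
# probe sheet. Result writers emit deterministic row/column order at 6
# significant digits so reruns are byte-identical.

read_tsv_quiet <- function(path, ...) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

# Write a data frame as TSV with numeric columns at 6 significant digits and
# optional "#" comment lines (used for manifest hashes).
write_result_tsv <- function(df, path, comments = NULL) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- fmt_num(df[[j]])
  }
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Write / read a genotype panel
#'
#' Genotype files are tab-delimited with one row per marker: columns
#' `chromosome`, `marker`, `cm`, `mb`, then one column per strain with codes
#' `B` (C57BL/6J-derived allele, internal code -1), `D` (DBA/2J-derived, +1)
#' or `U` (unknown, missing). `#` lines are comments.
#'
#' @param genotypes A `geno_panel`.
#' @param path File path.
#' @return `read_genotypes()` returns a validated `geno_panel`;
#'   `write_genotypes()` returns `path` invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  if (!inherits(genotypes, "geno_panel")) abort("`genotypes` must be a geno_panel.")
  codes <- matrix("U", nrow(genotypes$map), length(genotypes$strains),
                  dimnames = list(NULL, genotypes$strains))
  tcalls <- t(genotypes$calls)
  codes[which(tcalls == -1)] <- "B"
  codes[which(tcalls == 1)] <- "D"
  df <- cbind(
    data.frame(chromosome = genotypes$map$chromosome,
               marker = genotypes$map$marker,
               cm = fmt_num(genotypes$map$cm),
               mb = fmt_num(genotypes$map$mb)),
    as.data.frame(codes)
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(
    chromosome = readr::col_character(), marker = readr::col_character(),
    cm = readr::col_double(), mb = readr::col_double(),
    .default = readr::col_character()
  ))
  req <- c("chromosome", "marker", "cm", "mb")
  if (!all(req %in% names(df)) || ncol(df) <= length(req)) {
    abort("genotype file needs columns chromosome, marker, cm, mb plus strain columns.")
  }
  strains <- setdiff(names(df), req)
  codes <- as.matrix(df[strains])
  bad <- which(matrix(!(codes %in% c("B", "D", "U")), nrow(codes)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("unknown genotype code '%s' at marker %s, strain %s.",
                  codes[bad[1, 1], bad[1, 2]], df$marker[bad[1, 1]],
                  strains[bad[1, 2]]))
  }
  calls <- matrix(NA_real_, length(strains), nrow(df),
                  dimnames = list(strains, df$marker))
  calls[t(codes == "B")] <- -1
  calls[t(codes == "D")] <- 1
  geno_panel(calls, df[c("marker", "chromosome", "cm", "mb")])
}

#' Write / read an expression panel
#'
#' An expression panel is stored as three tab-delimited files: a signal matrix
#' (first column `array_id`, remaining columns one per probe), a sample sheet
#' (`array_id`, `strain_id`, `sex`, `is_f1`) and a probe sheet (`probe_id`,
#' `symbol`, `chromosome`, `mb`). Reading cross-validates the three files:
#' every array must have metadata, every probe annotation, and raw signals
#' must be non-negative.
#'
#' @param panel An `expr_panel`.
#' @param path_signals,path_samples,path_probes File paths.
#' @return `read_expression()` returns an `expr_panel`; `write_expression()`
#'   returns the signal path invisibly.
#' @export
write_expression <- function(panel, path_signals, path_samples, path_probes) {
  if (!inherits(panel, "expr_panel")) abort("`panel` must be an expr_panel.")
  sig <- as.data.frame(panel$signals)
  sig[] <- lapply(sig, fmt_num)
  readr::write_tsv(cbind(data.frame(array_id = rownames(panel$signals)), sig),
                   path_signals, progress = FALSE)
  readr::write_tsv(panel$samples, path_samples, progress = FALSE)
  pr <- panel$probes
  pr$mb <- fmt_num(pr$mb)
  readr::write_tsv(pr, path_probes, progress = FALSE)
  invisible(path_signals)
}

#' @rdname write_expression
#' @export
read_expression <- function(path_signals, path_samples, path_probes) {
  sig_df <- read_tsv_quiet(path_signals)
  samples <- read_tsv_quiet(path_samples, col_types = readr::cols(
    array_id = readr::col_character(), strain_id = readr::col_character(),
    sex = readr::col_character(), is_f1 = readr::col_logical()
  ))
  probes <- read_tsv_quiet(path_probes, col_types = readr::cols(
    probe_id = readr::col_character(), symbol = readr::col_character(),
    chromosome = readr::col_character(), mb = readr::col_double()
  ))
  if (names(sig_df)[1] != "array_id") abort("signal matrix must start with an array_id column.")
  signals <- as.matrix(sig_df[-1])
  rownames(signals) <- sig_df$array_id
  if (!is.numeric(signals)) abort("non-numeric values in signal matrix.")
  if (any(signals < 0, na.rm = TRUE)) abort("negative signal values in matrix.")
  orphans <- setdiff(rownames(signals), samples$array_id)
  if (length(orphans) > 0) {
    abort(sprintf("array(s) missing from sample sheet: %s",
                  paste(orphans, collapse = ", ")))
  }
  expression_panel(signals, samples, probes)
}

#' Write a scan result, peak catalog or other result table
#'
#' Writes any of the pipeline's result tibbles (scan results, peak catalogs,
#' heritability tables, correlation pairs, signature member lists) as TSV with
#' deterministic ordering and numeric values at 6 significant digits, so the
#' same object always produces a byte-identical file. Optional comment lines
#' (prefixed `#`) carry run provenance such as the manifest hash.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param comments Optional character vector of comment lines.
#' @return `path`, invisibly.
#' @export
write_outputs <- function(x, path, comments = NULL) {
  if (!is.data.frame(x)) abort("`x` must be a data frame.")
  write_result_tsv(x, path, comments = comments)
}

#' @rdname write_outputs
#' @export
read_outputs <- function(path) read_tsv_quiet(path)
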