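# Internal helpers shared across modules.

# Chromosome labels in map order (e.g. "1".."19", "X"); used wherever results
# must be sorted genome-wise.
chrom_levels <- function(chroms) unique(as.character(chroms))

chrom_factor <- function(chroms, levels) factor(as.character(chroms), levels = levels)

# Deterministic child seed for a pipeline stage: the user-facing seed fans out
# so stages can be re-run independently. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (strict_min && x <= min) abort(sprintf("`%s` must be > %s.", name, min))
  if (!strict_min && x < min) abort(sprintf("`%s` must be >= %s.", name, min))
  invisible(x)
}

# Population (n-denominator) standard deviation; the normalization contract
# (per-array mean 8, SD 2) is exact only with this denominator.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Trait input normalisation: accept a named numeric vector or a two-column
# data frame (strain, value); return a named numeric vector.
as_strain_values <- function(trait) {
  if (is.data.frame(trait)) {
    if (ncol(trait) < 2L) abort("trait data frame needs columns (strain, value).")
    out <- as.numeric(trait[[2L]])
    names(out) <- as.character(trait[[1L]])
    return(out)
  }
  if (is.numeric(trait)) {
    if (is.null(names(trait))) abort("numeric trait vectors must be named by strain.")
    return(trait)
  }
  abort("trait must be a named numeric vector or a (strain, value) data frame.")
}
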