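#' Simulate an expression panel with planted ground truth
#'
#' Generates raw array intensities over the strains of a genotype panel, with
#' structure emulating an RI-panel microarray study: heritable strain effects
#' with replicate arrays, planted cis- and trans-acting genotype effects,
#' Mendelian bimodal transcripts at their cognate locus, sex-specific
#' transcripts, and latent strain-level module drivers standing in for
#' cell-type proportion variation. The log2-scale generative model is
#'
#' \deqn{y = baseline + a\,g + \lambda z + s_{sex} + u_{strain} + \epsilon_{array}}
#'
#' and raw signals are `2^y`, so the normalization chain sees realistic skew.
#' All planted structure is recorded in a truth table for recovery testing.
#'
#' @param genotypes A `geno_panel`.
#' @param n_probes Total probes on the panel.
#' @param n_replicates Arrays per strain (replicates share the strain effect,
#'   so intended heritability is achieved in expectation).
#' @param n_cis,cis_effect Number of cis-regulated probes and their additive
#'   effect size `a` (log2 units per allele; group means differ by `2a`). Cis
#'   probes are annotated within 2 Mb of their regulating marker.
#' @param n_trans,trans_effect As above, with the regulating marker on a
#'   different chromosome from the probe.
#' @param n_mendelian,mendelian_effect Probes with strong bimodal expression
#'   driven by the marker at their own (cognate) position.
#' @param n_sex,sex_effect Sex-specific probes; alternate female-high /
#'   male-high, shifting affected arrays by `sex_effect` log2 units.
#' @param n_modules,module_size,module_sd_share Latent co-expression modules:
#'   each module has an independent standard-normal strain-level driver; member
#'   probes load on it so the driver accounts for `module_sd_share` of the
#'   strain-mean standard deviation (total strain-mean SD fixed at 1).
#' @param strain_sd Heritable strain-effect SD per probe: a scalar, or a range
#'   `c(lo, hi)` sampled uniformly per probe (log2 units).
#' @param noise_sd Array-level (within-strain) noise SD (log2 units).
#' @param baseline_mean,baseline_sd Per-probe baseline log2 abundance.
#' @param n_f1_arrays Optional F1-hybrid arrays (flagged `is_f1`, genotype
#'   dosage 0 at every locus so Mendelian probes are intermediate); excluded
#'   from mapping by [summarize_by_strain()].
#' @param frac_unmapped Fraction of background probes annotated `"unmapped"`.
#' @param seed Integer seed.
#'
#' @return A list with elements `panel` (an `expr_panel`) and `truth`, a list
#'   of tibbles: `effects` (probe, kind, marker, locus position, effect size),
#'   `modules` (+ `drivers`), `sex_probes`, and `h2` (planted variance
#'   components per probe, the intraclass correlation
#'   `icc = sigma_b^2 / (sigma_b^2 + sigma_e^2)`, and `h2_expected`, the
#'   expected value of the ANOVA mean-square ratio estimator at this panel's
#'   replicate count).
#' @export
simulate_expression_panel <- function(genotypes, n_probes = 500, n_replicates = 2,
                                      n_cis = 0, cis_effect = 1.5,
                                      n_trans = 0, trans_effect = 1.0,
                                      n_mendelian = 0, mendelian_effect = 3,
                                      n_sex = 0, sex_effect = 4,
                                      n_modules = 0, module_size = 20,
                                      module_sd_share = 0.9,
                                      strain_sd = c(0.3, 1.0), noise_sd = 0.5,
                                      baseline_mean = 8, baseline_sd = 1.5,
                                      n_f1_arrays = 0, frac_unmapped = 0,
                                      seed = 1L) {
  if (!inherits(genotypes, "geno_panel")) abort("`genotypes` must be a geno_panel.")
  n_special <- n_cis + n_trans + n_mendelian + n_sex + n_modules * module_size
  if (n_special > n_probes) {
    abort("planted probes (cis + trans + mendelian + sex + modules) exceed n_probes.")
  }
  map <- genotypes$map
  strains <- genotypes$strains
  S <- length(strains)
  P <- as.integer(n_probes)
  m <- as.integer(n_replicates)

  chr_span <- map |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(lo = min(.data$mb), hi = max(.data$mb), .groups = "drop")

  withr::with_seed(as.integer(seed), {
    probe_id <- sprintf("ps%05d_at", seq_len(P))
    symbol <- sprintf("Gene%05d", seq_len(P))
    chr_i <- sample(nrow(chr_span), P, replace = TRUE)
    chromosome <- chr_span$chromosome[chr_i]
    mb <- runif(P, chr_span$lo[chr_i], chr_span$hi[chr_i])

    idx <- seq_len(n_special + (P - n_special))
    take <- function(n) {
      out <- idx[seq_len(n)]
      idx <<- idx[-seq_len(n)]
      out
    }
    cis_idx <- if (n_cis > 0) take(n_cis) else integer()
    trans_idx <- if (n_trans > 0) take(n_trans) else integer()
    mend_idx <- if (n_mendelian > 0) take(n_mendelian) else integer()
    sex_idx <- if (n_sex > 0) take(n_sex) else integer()
    module_idx <- if (n_modules > 0) {
      lapply(seq_len(n_modules), function(i) take(module_size))
    } else list()
    bg_idx <- idx

    # unmapped annotation only on background probes
    if (frac_unmapped > 0 && length(bg_idx) > 0) {
      n_un <- round(frac_unmapped * length(bg_idx))
      un <- bg_idx[seq_len(n_un)]
      chromosome[un] <- "unmapped"
      mb[un] <- NA_real_
    }

    # --- planted genotype effects -------------------------------------------
    plant_locus <- function(i, kind, effect, cognate) {
      j <- sample(nrow(map), 1L)
      if (cognate) {
        chromosome[i] <<- map$chromosome[j]
        lo <- chr_span$lo[chr_span$chromosome == map$chromosome[j]]
        hi <- chr_span$hi[chr_span$chromosome == map$chromosome[j]]
        mb[i] <<- min(max(map$mb[j] + runif(1, -2, 2), lo), hi)
      } else {
        # regulating locus on a different chromosome than the probe
        off <- which(map$chromosome != chromosome[i])
        if (length(off) == 0) abort("trans effects need >= 2 chromosomes in the map.")
        j <- off[sample.int(length(off), 1L)]
      }
      tibble(probe_id = probe_id[i], kind = kind, marker = map$marker[j],
             locus_chr = map$chromosome[j], locus_mb = map$mb[j],
             effect = effect)
    }
    effects <- dplyr::bind_rows(
      purrr::map_dfr(cis_idx, plant_locus, kind = "cis", effect = cis_effect,
                     cognate = TRUE),
      purrr::map_dfr(trans_idx, plant_locus, kind = "trans", effect = trans_effect,
                     cognate = FALSE),
      purrr::map_dfr(mend_idx, plant_locus, kind = "mendelian",
                     effect = mendelian_effect, cognate = TRUE)
    )

    # --- strain-level component ---------------------------------------------
    sd_probe <- if (length(strain_sd) == 1) rep(strain_sd, P)
                else runif(P, strain_sd[1], strain_sd[2])
    strain_mat <- matrix(rnorm(S * P), S, P) * rep(sd_probe, each = S)

    genetic_var <- numeric(P)
    if (nrow(effects) > 0) {
      for (k in seq_len(nrow(effects))) {
        i <- match(effects$probe_id[k], probe_id)
        g <- genotypes$calls[, effects$marker[k]]
        g[is.na(g)] <- 0
        strain_mat[, i] <- strain_mat[, i] + effects$effect[k] * g
        genetic_var[i] <- effects$effect[k]^2 * stats::var(g) * (S - 1) / S
      }
    }

    drivers <- tibble(module = integer(), strain = character(), score = numeric())
    modules <- tibble(module = integer(), probe_id = character(), loading = numeric())
    if (n_modules > 0) {
      lambda <- module_sd_share            # total strain-mean SD fixed at 1
      resid_var <- max(0, 1 - lambda^2 - noise_sd^2 / m)
      for (mod in seq_len(n_modules)) {
        z <- rnorm(S)
        ii <- module_idx[[mod]]
        strain_mat[, ii] <- lambda * z +
          matrix(rnorm(S * length(ii), sd = sqrt(resid_var)), S, length(ii))
        sd_probe[ii] <- sqrt(lambda^2 + resid_var)
        drivers <- dplyr::bind_rows(drivers, tibble(module = mod, strain = strains, score = z))
        modules <- dplyr::bind_rows(modules,
          tibble(module = mod, probe_id = probe_id[ii], loading = lambda))
      }
    }

    sex_tbl <- tibble(probe_id = character(), direction = character(), effect = numeric())
    if (n_sex > 0) {
      dirs <- rep(c("F_high", "M_high"), length.out = n_sex)
      sex_tbl <- tibble(probe_id = probe_id[sex_idx], direction = dirs, effect = sex_effect)
    }

    # --- arrays --------------------------------------------------------------
    baseline <- rnorm(P, baseline_mean, baseline_sd)
    rep_strain <- rep(strains, each = m)
    array_id <- sprintf("%s_a%d", rep_strain, rep(seq_len(m), times = S))
    samples <- tibble(
      array_id = array_id, strain_id = rep_strain,
      sex = sample(c("F", "M"), length(array_id), replace = TRUE),
      is_f1 = FALSE
    )
    log2sig <- strain_mat[rep(seq_len(S), each = m), , drop = FALSE] +
      matrix(rnorm(length(array_id) * P, sd = noise_sd), length(array_id), P)

    if (n_f1_arrays > 0) {
      f1_effect <- rnorm(P) * sd_probe       # F1 line has its own strain effect
      f1_ids <- sprintf("F1_a%d", seq_len(n_f1_arrays))
      samples <- dplyr::bind_rows(samples, tibble(
        array_id = f1_ids, strain_id = "F1",
        sex = sample(c("F", "M"), n_f1_arrays, replace = TRUE), is_f1 = TRUE
      ))
      log2sig <- rbind(log2sig, matrix(f1_effect, n_f1_arrays, P, byrow = TRUE) +
        matrix(rnorm(n_f1_arrays * P, sd = noise_sd), n_f1_arrays, P))
    }

    if (n_sex > 0) {
      for (k in seq_len(nrow(sex_tbl))) {
        i <- match(sex_tbl$probe_id[k], probe_id)
        hit <- if (sex_tbl$direction[k] == "F_high") samples$sex == "F" else samples$sex == "M"
        log2sig[hit, i] <- log2sig[hit, i] + sex_tbl$effect[k]
      }
    }
    log2sig <- sweep(log2sig, 2, baseline, "+")
    signals <- 2^log2sig
    rownames(signals) <- samples$array_id
    colnames(signals) <- probe_id

    sigma_b2 <- sd_probe^2 + genetic_var
    tot <- sigma_b2 + noise_sd^2
    h2_tbl <- tibble(
      probe_id = probe_id,
      sigma_strain = sqrt(sigma_b2), sigma_noise = noise_sd,
      icc = ifelse(tot == 0, 0, sigma_b2 / tot),
      h2_expected = ifelse(tot == 0, 0,
        (noise_sd^2 + m * sigma_b2) / (2 * noise_sd^2 + m * sigma_b2))
    )

    panel <- expression_panel(
      signals = signals,
      samples = samples,
      probes = tibble(probe_id = probe_id, symbol = symbol,
                      chromosome = chromosome, mb = mb)
    )
    list(panel = panel,
         truth = list(effects = effects, modules = modules, drivers = drivers,
                      sex_probes = sex_tbl, h2 = h2_tbl))
  })
}
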