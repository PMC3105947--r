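test_that("marker maps have the requested geometry and invariants", {
  m <- make_marker_map(1, 100, 10, mb_per_cm = 0.5, seed = 1)
  expect_equal(m$cm, seq(0, 100, 10))
  expect_equal(m$mb, m$cm * 0.5)
  expect_equal(unique(m$chromosome), "1")

  big <- make_marker_map(20, 80, 0.42, seed = 2)
  expect_gt(nrow(big), 3700)
  expect_lt(nrow(big), 3900)
  expect_setequal(unique(big$chromosome), c(as.character(1:19), "X"))
  expect_false(anyDuplicated(big$marker) > 0)
  # strictly increasing positions within every chromosome, even with jitter
  j <- make_marker_map(3, 50, 5, jitter_cm = 2, seed = 3)
  for (chr in unique(j$chromosome)) {
    expect_true(all(diff(j$cm[j$chromosome == chr]) > 0))
    expect_true(all(diff(j$mb[j$chromosome == chr]) > 0))
  }
  expect_identical(make_marker_map(3, 50, 5, jitter_cm = 2, seed = 3), j)
  expect_error(make_marker_map(2, 50, -1), "marker_spacing_cm")
})

test_that("RI genotypes are homozygous mosaics with ~0.5 allele frequency", {
  g <- small_panel(n_strains = 60, seed = 21)
  expect_true(all(g$calls %in% c(-1, 1)))
  maf <- colMeans(g$calls == 1)
  expect_true(all(maf > 0.2 & maf < 0.8))
  expect_lt(abs(mean(maf) - 0.5), 0.05)
  # determinism
  g2 <- small_panel(n_strains = 60, seed = 21)
  expect_identical(g$calls, g2$calls)
  expect_error(simulate_ri_genotypes(make_marker_map(1, 10, 1)[0, ], 10), "empty")
})

test_that("adjacent-marker discordance matches the RI-scale recombination fraction", {
  # two markers at the cM distance giving meiotic r = 0.1 -> R = 0.25
  d <- -50 * log(1 - 2 * 0.1)
  map <- tibble::tibble(marker = c("m1", "m2"), chromosome = "1",
                        cm = c(0, d), mb = c(0, 2 * d))
  g <- simulate_ri_genotypes(map, 4000, seed = 7)
  disc <- mean(g$calls[, 1] != g$calls[, 2])
  expect_lt(abs(disc - 0.25), 0.025)

  # r = 0: identical columns; unlinked: ~50% discordance
  map0 <- tibble::tibble(marker = c("a", "b"), chromosome = "1",
                         cm = c(5, 5 + 1e-9), mb = c(5, 5 + 1e-9))
  g0 <- simulate_ri_genotypes(map0, 200, seed = 8)
  expect_equal(g0$calls[, 1], g0$calls[, 2])
  mapU <- tibble::tibble(marker = c("a", "b"), chromosome = "1",
                         cm = c(0, 1e5), mb = c(0, 1e5))
  gU <- simulate_ri_genotypes(mapU, 4000, seed = 9)
  expect_lt(abs(mean(gU$calls[, 1] != gU$calls[, 2]) - 0.5), 0.03)
})

test_that("junction counts per chromosome match map length under RI expansion", {
  map <- make_marker_map(1, 60, 2, seed = 31)
  g <- simulate_ri_genotypes(map, 500, seed = 32)
  junctions <- mean(apply(g$calls, 1, function(x) sum(diff(x) != 0)))
  expected <- sum(ri_recombination_fraction(diff(map$cm)))
  expect_lt(abs(junctions - expected) / expected, 0.1)
})

test_that("expression simulator plants the structure it reports", {
  g <- small_panel(seed = 41)
  sim <- simulate_expression_panel(g, n_probes = 60, n_replicates = 2,
                                   n_cis = 5, n_trans = 5, n_mendelian = 2,
                                   seed = 42)
  expect_s3_class(sim$panel, "expr_panel")
  expect_true(all(sim$panel$signals >= 0))
  eff <- sim$truth$effects
  ann <- sim$panel$probes
  cis <- dplyr::filter(eff, kind %in% c("cis", "mendelian"))
  pos <- ann[match(cis$probe_id, ann$probe_id), ]
  expect_true(all(pos$chromosome == cis$locus_chr))
  expect_true(all(abs(pos$mb - cis$locus_mb) <= 10))
  trans <- dplyr::filter(eff, kind == "trans")
  post <- ann[match(trans$probe_id, ann$probe_id), ]
  expect_true(all(post$chromosome != trans$locus_chr))
  # determinism
  sim2 <- simulate_expression_panel(g, n_probes = 60, n_replicates = 2,
                                    n_cis = 5, n_trans = 5, n_mendelian = 2,
                                    seed = 42)
  expect_identical(sim$panel$signals, sim2$panel$signals)
})

test_that("zero noise and zero effects give identical replicate arrays", {
  g <- small_panel(n_strains = 10, seed = 51)
  sim <- simulate_expression_panel(g, n_probes = 20, n_replicates = 3,
                                   strain_sd = 0, noise_sd = 0, seed = 52)
  sig <- sim$panel$signals
  strain <- sim$panel$samples$strain_id
  for (s in unique(strain)) {
    reps <- sig[strain == s, , drop = FALSE]
    expect_true(all(abs(sweep(reps, 2, reps[1, ])) < 1e-12))
  }
})

test_that("a planted additive effect a separates strain-group means by ~2a on log2 scale", {
  g <- small_panel(n_strains = 50, seed = 61)
  a <- 1.5
  sim <- simulate_expression_panel(g, n_probes = 30, n_replicates = 4,
                                   n_cis = 10, cis_effect = a,
                                   strain_sd = 0.2, noise_sd = 0.2, seed = 62)
  eff <- dplyr::filter(sim$truth$effects, kind == "cis")
  log2sig <- log2(sim$panel$signals)
  strain <- sim$panel$samples$strain_id
  gaps <- vapply(seq_len(nrow(eff)), function(k) {
    geno <- g$calls[, eff$marker[k]]
    means <- tapply(log2sig[, eff$probe_id[k]], strain, mean)[g$strains]
    mean(means[geno == 1]) - mean(means[geno == -1])
  }, numeric(1))
  expect_lt(abs(mean(gaps) - 2 * a), 0.2)
})

test_that("mendelian probes are bimodal and track their cognate-locus genotype", {
  g <- small_panel(n_strains = 40, seed = 71)
  sim <- simulate_expression_panel(g, n_probes = 20, n_replicates = 1,
                                   n_mendelian = 3, mendelian_effect = 3,
                                   strain_sd = 0, noise_sd = 0, seed = 72)
  eff <- dplyr::filter(sim$truth$effects, kind == "mendelian")
  for (k in seq_len(nrow(eff))) {
    x <- sim$panel$signals[, eff$probe_id[k]]
    geno <- g$calls[match(sim$panel$samples$strain_id, g$strains), eff$marker[k]]
    expect_equal(abs(cor(log2(x), geno)), 1, tolerance = 1e-10)
  }
})

test_that("module members share their latent driver", {
  g <- small_panel(n_strains = 40, seed = 81)
  sim <- simulate_expression_panel(g, n_probes = 60, n_replicates = 2,
                                   n_modules = 2, module_size = 10,
                                   module_sd_share = 0.95, seed = 82)
  summ <- summarize_by_strain(normalize_panel(sim$panel))
  for (mod in 1:2) {
    members <- sim$truth$modules$probe_id[sim$truth$modules$module == mod]
    driver <- sim$truth$drivers$score[sim$truth$drivers$module == mod]
    rr <- abs(cor(driver, summ$values[g$strains, members]))
    expect_gt(min(rr), 0.7)
  }
})

test_that("achieved heritability matches the truth table's expected value", {
  g <- small_panel(n_strains = 30, seed = 91)
  sim <- simulate_expression_panel(g, n_probes = 60, n_replicates = 10,
                                   strain_sd = c(0.2, 1.2), noise_sd = 0.5,
                                   seed = 92)
  h <- heritability_table(normalize_panel(sim$panel), sort = FALSE)
  # compare on the raw log2 scale-free ratio: normalization preserves ranks and
  # approximately the variance structure, so match within the stated band
  merged <- dplyr::inner_join(h, sim$truth$h2, by = "probe_id")
  expect_lt(mean(abs(merged$h2 - merged$h2_expected)), 0.1)
})
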