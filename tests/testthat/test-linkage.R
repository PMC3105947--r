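test_that("RI recombination fraction has the right limits and pedigree behaviour", {
  expect_equal(ri_recombination_fraction(0), 0)
  expect_equal(ri_recombination_fraction(1e7), 0.5, tolerance = 1e-9)
  # monotone in distance
  d <- seq(0, 200, by = 5)
  expect_true(all(diff(ri_recombination_fraction(d)) > 0))
  # r = 0.1 -> R = 0.25 under Haldane-Waterman
  d01 <- -50 * log(1 - 2 * 0.1)
  expect_equal(ri_recombination_fraction(d01), 0.25, tolerance = 1e-12)
  expect_error(ri_recombination_fraction(-1), ">= 0")
})

test_that("the RI map-expansion formula matches the sib-mating pedigree oracle", {
  for (r in c(0.01, 0.1, 0.3)) {
    d <- -50 * log(1 - 2 * r)
    n <- 2000
    phat <- ri_pedigree_oracle(r, n_lines = n, seed = round(1000 * r))
    R <- ri_recombination_fraction(d)
    mc_err <- 3.5 * sqrt(R * (1 - R) / n)
    expect_lt(abs(phat - R), mc_err + 0.005)
  }
})

test_that("expected dosage reproduces observed markers and flank symmetry", {
  map <- tibble::tibble(marker = c("m1", "m2"), chromosome = "1",
                        cm = c(0, 20), mb = c(0, 40))
  calls <- rbind(sA = c(1, 1), sB = c(-1, -1), sC = c(-1, 1), sD = c(1, -1))
  colnames(calls) <- map$marker
  grid <- expected_dosage(geno_panel(calls, map), step_cm = 10)
  pos <- grid$positions
  expect_equal(pos$cm, c(0, 10, 20))
  expect_equal(pos$mb, c(0, 20, 40))          # linear cM -> Mb interpolation
  at0 <- grid$dosage[, 1]; mid <- grid$dosage[, 2]; at20 <- grid$dosage[, 3]
  expect_equal(unname(at0), unname(calls[, 1]))   # dosage = observed code at markers
  expect_equal(unname(at20), unname(calls[, 2]))
  expect_gt(mid["sA"], 0)                      # D/D flanks pull midpoint to +1
  expect_lt(mid["sB"], 0)
  expect_equal(unname(mid["sC"]), 0)           # equidistant B|D flank: symmetric
  expect_equal(unname(mid["sD"]), 0)
  expect_equal(unname(mid["sA"]), -unname(mid["sB"]))

  # tighter flanks pull the midpoint closer to +/-1
  map2 <- tibble::tibble(marker = c("m1", "m2"), chromosome = "1",
                         cm = c(0, 5), mb = c(0, 10))
  calls2 <- calls; colnames(calls2) <- map2$marker
  grid2 <- expected_dosage(geno_panel(calls2, map2), step_cm = 2.5)
  expect_gt(grid2$dosage["sA", 2], mid["sA"])
})

test_that("missing genotypes fall back to the nearest informative flanks", {
  map <- tibble::tibble(marker = paste0("m", 1:4), chromosome = "1",
                        cm = c(0, 10, 20, 30), mb = c(0, 20, 40, 60))
  calls <- rbind(s1 = c(1, NA, NA, 1), s2 = c(-1, NA, 1, 1))
  colnames(calls) <- map$marker
  # pad with extra strains so scans have n >= 8 elsewhere; here only dosage
  grid <- expected_dosage(geno_panel(calls, map), step_cm = 10)
  # s1: both informative flanks are D -> interior dosage positive everywhere
  expect_true(all(grid$dosage["s1", ] > 0))
  # s2 at m2 (10 cM): flanks B (10 cM away) and D (10 cM away) -> 0
  expect_equal(unname(grid$dosage["s2", grid$positions$cm == 10]), 0)
})

test_that("hk_scan equals the brute-force OLS statistic at observed markers", {
  g <- small_panel(n_strains = 20, n_chromosomes = 2, length_cm = 50,
                   spacing_cm = 2, seed = 501)
  grid <- expected_dosage(g, step_cm = 1)
  at_marker <- which(paste0(grid$positions$chromosome, ":", grid$positions$cm) %in%
                     paste0(g$map$chromosome, ":", g$map$cm))
  set.seed(502)
  for (i in 1:4) {
    y <- setNames(rnorm(20), g$strains)
    sc <- hk_scan(y, grid)
    for (j in sample(at_marker, 25)) {
      x <- grid$dosage[g$strains, j]
      orc <- ols_lrs_oracle(y, x)
      expect_equal(sc$lrs[j], orc$lrs, tolerance = 1e-9)
      expect_equal(sc$additive[j], orc$additive, tolerance = 1e-9)
    }
  }
})

test_that("a trait equal to a marker's dosage saturates exactly there", {
  g <- small_panel(n_strains = 20, seed = 511)
  grid <- expected_dosage(g, step_cm = 1)
  m <- g$map$marker[100]
  y <- setNames(g$calls[, m], g$strains)
  sc <- hk_scan(y, grid)
  j <- which.max(sc$lrs)
  expect_true(sc$saturated[j])
  expect_equal(sc$chromosome[j], g$map$chromosome[100])
  expect_equal(sc$lrs[j], 20 * log(1e12))
  expect_error(hk_scan(setNames(rep(1, 20), g$strains), grid), "constant trait")
})

test_that("LRS is invariant under affine transformation of the trait", {
  g <- small_panel(n_strains = 25, seed = 521)
  grid <- expected_dosage(g, step_cm = 2)
  y <- setNames(rnorm(25), g$strains)
  s1 <- hk_scan(y, grid)
  s2 <- hk_scan(-2.5 * y + 7, grid)
  expect_equal(s1$lrs, s2$lrs, tolerance = 1e-9)
  expect_equal(s2$additive, -2.5 * s1$additive, tolerance = 1e-9)
})

test_that("permutation null is reproducible, threshold monotone, p-values exact", {
  g <- small_panel(n_strains = 25, seed = 531)
  grid <- expected_dosage(g, step_cm = 2)
  y <- setNames(rnorm(25), g$strains)
  null1 <- permutation_null(y, grid, n_perm = 200, seed = 42)
  null2 <- permutation_null(y, grid, n_perm = 200, seed = 42)
  expect_identical(null1$max_lrs, null2$max_lrs)
  expect_true(all(null1$max_lrs >= 0))
  # threshold monotone nonincreasing in alpha
  alphas <- c(0.01, 0.05, 0.1, 0.5)
  thr <- vapply(alphas, function(a) genomewide_threshold(null1, a), numeric(1))
  expect_true(all(diff(thr) <= 0))
  # plus-one rule
  expect_equal(empirical_p(max(null1$max_lrs) + 1, null1), 1 / 201)
  expect_equal(empirical_p(-1, null1), 1)
  # brute-force count on a 10-value null
  null10 <- structure(list(max_lrs = c(1:10) * 1.0, n_perm = 10L, seed = 1L),
                      class = "null_distribution")
  expect_equal(empirical_p(7.5, null10), (3 + 1) / 11)
  expect_equal(empirical_p(7, null10), (4 + 1) / 11)
})

test_that("LRS/LOD conversion is exact and invertible", {
  expect_equal(lrs_to_lod(0), 0)
  expect_equal(lod_to_lrs(50), 230.2585, tolerance = 1e-4)
  x <- c(0, 3, 18.5, 230)
  expect_equal(lod_to_lrs(lrs_to_lod(x)), x, tolerance = 1e-12)
  expect_error(lrs_to_lod(-1), ">= 0")
})

test_that("scan tidiers and plots expose the peak", {
  g <- small_panel(n_strains = 20, seed = 541)
  grid <- expected_dosage(g, step_cm = 2)
  y <- setNames(g$calls[, 30] + rnorm(20, sd = 0.5), g$strains)
  sc <- hk_scan(y, grid)
  gl <- glance(sc)
  expect_equal(gl$peak_lrs, max(sc$lrs))
  expect_equal(gl$peak_lod, lrs_to_lod(max(sc$lrs)))
  expect_s3_class(tidy(sc), "tbl_df")
  expect_s3_class(autoplot(sc), "ggplot")
  null <- permutation_null(y, grid, n_perm = 100, seed = 2)
  expect_s3_class(autoplot(null), "ggplot")
  expect_equal(nrow(tidy(null)), 100)
})
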