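test_that("correlation p-values match the t transform and a permutation oracle", {
  expect_equal(correlation_test(0, 20), 1)
  expect_lt(correlation_test(0.80, 57), 1e-12)
  p1 <- correlation_test(1, 10)
  expect_equal(as.numeric(p1), 0)
  expect_true(attr(p1, "underflow"))
  # permutation oracle at r = 0.5, n = 20
  set.seed(701)
  x <- rnorm(20)
  y <- 0.5 * scale(x)[, 1] + sqrt(1 - 0.25) * rnorm(20)
  r_obs <- cor(x, y)
  p_t <- correlation_test(r_obs, 20)
  perm <- replicate(10000, abs(cor(x, sample(y))))
  p_perm <- (sum(perm >= abs(r_obs)) + 1) / 10001
  expect_lt(abs(p_t - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 10000) + 0.003)
})

test_that("correlation_pairs finds planted modules and respects the threshold", {
  hits <- 0; false_pairs <- 0; bg_pairs <- 0
  for (s in 1:5) {
    g <- small_panel(n_strains = 60, seed = 710 + s)
    sim <- simulate_expression_panel(g, n_probes = 200, n_replicates = 2,
                                     n_modules = 1, module_size = 10,
                                     module_sd_share = 0.95, noise_sd = 0.3,
                                     seed = 720 + s)
    summ <- summarize_by_strain(normalize_panel(sim$panel))
    pairs <- correlation_pairs(summ, method = "spearman", threshold = 0.8)
    members <- sim$truth$modules$probe_id
    in_mod <- pairs$probe_a %in% members & pairs$probe_b %in% members
    hits <- hits + sum(in_mod)
    false_pairs <- false_pairs + sum(xor(pairs$probe_a %in% members,
                                         pairs$probe_b %in% members))
    bg_pairs <- bg_pairs + length(members) * (ncol(summ$values) - length(members))
  }
  expect_gt(hits / (5 * choose(10, 2)), 0.95)  # within-module pairs found
  expect_lt(false_pairs / bg_pairs, 0.05)      # module-background pairs rare
})

test_that("duplicated probes give r = 1 pairs; threshold 1 returns only duplicates", {
  set.seed(731)
  vals <- matrix(rnorm(20 * 5), 20, 5,
                 dimnames = list(paste0("s", 1:20), paste0("p", 1:5)))
  vals[, 5] <- vals[, 1]
  summ <- as_summary(vals)
  pairs <- correlation_pairs(summ, threshold = 1)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$probe_a, "p1")
  expect_equal(pairs$probe_b, "p5")
  expect_equal(pairs$pearson_r, 1)
  vals2 <- cbind(vals, const = 3)
  expect_warning(p2 <- correlation_pairs(as_summary(vals2), threshold = 0.99),
                 "constant")
  expect_false("const" %in% c(p2$probe_a, p2$probe_b))
})

test_that("pair listing is invariant under a joint strain permutation", {
  set.seed(741)
  vals <- matrix(rnorm(15 * 8), 15, 8,
                 dimnames = list(paste0("s", 1:15), paste0("p", 1:8)))
  p1 <- correlation_pairs(as_summary(vals), threshold = 0.3)
  p2 <- correlation_pairs(as_summary(vals[sample(15), ]), threshold = 0.3)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("PC1 signatures recover planted modules from four seeds", {
  recovered <- 0; total <- 0
  for (s in 1:5) {
    g <- small_panel(n_strains = 50, seed = 750 + s)
    sim <- simulate_expression_panel(g, n_probes = 200, n_replicates = 2,
                                     n_modules = 1, module_size = 20,
                                     module_sd_share = 0.95, noise_sd = 0.3,
                                     seed = 760 + s)
    summ <- summarize_by_strain(normalize_panel(sim$panel))
    members <- sim$truth$modules$probe_id
    sig <- pc_signature(summ, seed_probes = members[1:4], threshold = 0.8)
    rest <- setdiff(members, members[1:4])
    recovered <- recovered + sum(rest %in% sig$members$probe_id)
    total <- total + length(rest)
  }
  expect_gt(recovered / total, 0.9)
})

test_that("signatures seeded in independent modules do not overlap", {
  ok <- 0
  for (s in 1:5) {
    g <- small_panel(n_strains = 40, seed = 770 + s)
    sim <- simulate_expression_panel(g, n_probes = 200, n_replicates = 2,
                                     n_modules = 2, module_size = 15,
                                     module_sd_share = 0.95, noise_sd = 0.3,
                                     seed = 780 + s)
    summ <- summarize_by_strain(normalize_panel(sim$panel))
    m1 <- sim$truth$modules$probe_id[sim$truth$modules$module == 1]
    m2 <- sim$truth$modules$probe_id[sim$truth$modules$module == 2]
    s1 <- pc_signature(summ, m1[1:4], threshold = 0.8)
    s2 <- pc_signature(summ, m2[1:4], threshold = 0.8)
    if (length(intersect(s1$members$probe_id, s2$members$probe_id)) == 0) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("signature orientation and membership are sign/scale invariant in the seeds", {
  set.seed(791)
  z <- rnorm(20)
  vals <- sapply(1:12, function(i) 0.95 * z + rnorm(20, sd = sqrt(1 - 0.95^2)))
  dimnames(vals) <- list(paste0("s", 1:20), paste0("p", 1:12))
  summ <- as_summary(vals)
  s1 <- pc_signature(summ, c("p1", "p2", "p3"), threshold = 0.8)
  flipped <- vals
  flipped[, "p2"] <- -3 * flipped[, "p2"]    # sign and scale of one seed
  s2 <- pc_signature(as_summary(flipped), c("p1", "p2", "p3"), threshold = 0.8)
  expect_setequal(setdiff(s1$members$probe_id, "p2"),
                  setdiff(s2$members$probe_id, "p2"))

  # two identical seeds: PC1 is that probe's standardized profile
  s3 <- pc_signature(summ, c("p1", "p1x" = "p1")[c(1, 1)], threshold = 0.8)
  expect_equal(abs(cor(s3$scores$pc1, vals[, "p1"])), 1, tolerance = 1e-10)
  expect_equal(s3$members$r[s3$members$probe_id == "p1"], 1, tolerance = 1e-10)
})

test_that("signature errors and gates behave as documented", {
  set.seed(795)
  vals <- matrix(rnorm(12 * 6), 12, 6,
                 dimnames = list(paste0("s", 1:12), paste0("p", 1:6)))
  summ <- as_summary(vals)
  expect_error(pc_signature(summ, c("p1", "nope")), "nope")
  expect_error(pc_signature(summ, "p1"), ">= 2 seed")
  vals2 <- vals; vals2[, "p2"] <- 5
  expect_warning(pc_signature(as_summary(vals2), c("p1", "p2", "p3")),
                 "zero-variance")
  sp <- pc_signature(summ, c("p1", "p2"), p_threshold = 0.5)
  expect_true(all(sp$members$p <= 0.5))
  expect_s3_class(glance(sp), "tbl_df")
  expect_s3_class(autoplot(sp), "ggplot")
})
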