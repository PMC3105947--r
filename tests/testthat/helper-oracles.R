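# Independent oracles, deliberately kept naive and separate from the package
# implementation paths they check.

# Forward simulation of a sib-mated RI line to fixation at two loci with
# meiotic recombination fraction r. Returns the fraction of fixed lines whose
# fixed haplotype is recombinant; converges to 4r / (1 + 6r).
ri_pedigree_oracle <- function(r, n_lines = 2000, seed = 1, max_gen = 500) {
  gamete <- function(ind) {
    # ind: 2x2 matrix, rows = haplotypes, cols = loci
    h <- sample(1:2, 1)
    a1 <- ind[h, 1]
    h2 <- if (stats::runif(1) < r) 3 - h else h
    c(a1, ind[h2, 2])
  }
  withr::with_seed(seed, {
    rec <- logical(n_lines)
    for (l in seq_len(n_lines)) {
      # start from two F1 siblings (haplotypes 00 and 11)
      sib1 <- rbind(c(0, 0), c(1, 1))
      sib2 <- rbind(c(0, 0), c(1, 1))
      for (g in seq_len(max_gen)) {
        o1 <- rbind(gamete(sib1), gamete(sib2))
        o2 <- rbind(gamete(sib1), gamete(sib2))
        sib1 <- o1; sib2 <- o2
        all4 <- rbind(sib1, sib2)
        if (all(all4[, 1] == all4[1, 1]) && all(all4[, 2] == all4[1, 2])) break
      }
      rec[l] <- sib1[1, 1] != sib1[1, 2]
    }
    mean(rec)
  })
}

# Brute-force single-position regression statistic n * ln(RSS0 / RSS1) using
# lm() residuals directly.
ols_lrs_oracle <- function(y, x) {
  fit1 <- stats::lm(y ~ x)
  fit0 <- stats::lm(y ~ 1)
  rss1 <- sum(stats::resid(fit1)^2)
  rss0 <- sum(stats::resid(fit0)^2)
  list(lrs = length(y) * log(rss0 / rss1),
       additive = unname(stats::coef(fit1)[2]))
}

# One-way ANOVA mean squares straight from stats::anova(stats::lm()).
anova_oracle <- function(values, strain) {
  tab <- stats::anova(stats::lm(values ~ factor(strain)))
  list(between_ms = tab$`Mean Sq`[1], within_ms = tab$`Mean Sq`[2])
}
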