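test_that("exact HWE test matches enumeration and handles degenerate counts", {
  expect_equal(hwe_exact_p(25, 50, 25), 1, tolerance = 0.05)
  expect_equal(hwe_exact_p(100, 0, 0), 1)   # monomorphic
  expect_lt(hwe_exact_p(50, 0, 50), 1e-6)   # total heterozygote deficit
  # the two-carrier toy: het counts {0, 2} enumerated directly
  expect_equal(hwe_exact_p(1, 0, 1), oracle_hwe(1, 0, 1), tolerance = 1e-12)
  # random small configurations against the genotype-vector enumeration
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    g <- sample(0:2, n, replace = TRUE)
    cnt <- c(sum(g == 0), sum(g == 1), sum(g == 2))
    expect_equal(hwe_exact_p(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe(cnt[1], cnt[2], cnt[3]), tolerance = 1e-10)
  }
  expect_error(hwe_exact_p(-1, 0, 1), ">= 0")
})

test_that("genotype filtering applies call-rate, MAF and HWE rules in order", {
  set.seed(8)
  n <- 200
  # enough clean variants that one missing entry cannot sink a sample
  base <- matrix(rbinom(n * 30, 2, 0.3), n, 30,
                 dimnames = list(NULL, sprintf("ok%02d", 1:30)))
  g_lowcr <- rbinom(n, 2, 0.3)
  g_lowcr[sample.int(n, 0.15 * n)] <- NA       # 85% call rate
  g_lowmaf <- rbinom(n, 2, 0.01)
  g_hwe <- c(rep(0, n / 2), rep(2, n / 2))     # no heterozygotes at AF 0.5
  gmat <- cbind(base, lowcr = g_lowcr, lowmaf = g_lowmaf, hwe = g_hwe)
  rownames(gmat) <- sprintf("i%03d", seq_len(n))
  f <- filter_genotypes(gmat)
  expect_setequal(colnames(f$gmat), colnames(base))
  expect_equal(f$dropped_variants$reason[f$dropped_variants$variant_id == "lowcr"],
               "call_rate")
  expect_equal(f$dropped_variants$reason[f$dropped_variants$variant_id == "lowmaf"],
               "maf")
  expect_equal(f$dropped_variants$reason[f$dropped_variants$variant_id == "hwe"],
               "hwe")
  # dosages 0,1,2,2: alt frequency 0.625 so MAF 0.375 - retained
  g2 <- cbind(v = c(0, 1, 2, 2))
  f2 <- filter_genotypes(g2, min_hwe_p = 0)
  expect_equal(ncol(f2$gmat), 1L)
  # a sample below 90% call rate leaves before variant statistics
  gmat2 <- gmat
  gmat2[1, ] <- NA
  f3 <- filter_genotypes(gmat2)
  expect_true("i001" %in% f3$dropped_samples$sample_id)
  expect_false("i001" %in% rownames(f3$gmat))
})

test_that("phenotype selection keeps common mtDNA variants with zeros for non-carriers", {
  samples <- sprintf("s%02d", 1:50)
  calls <- tibble::tibble(
    sample_id = c(samples[1:3], samples[1]),
    pos = c(4769L, 4769L, 4769L, 9950L),
    ref = "A", alt = "G",
    vaf = c(0.4, 1, 0.8, 0.5), dp = 1000L,
    level = c("heteroplasmic", "homoplasmic", "heteroplasmic",
              "heteroplasmic"))
  ph <- select_mt_phenotypes(calls, samples, min_freq = 0.05)
  # 3/50 = 6% selected; 1/50 = 2% excluded
  expect_equal(setdiff(names(ph), "sample_id"), "m.4769A>G")
  expect_equal(ph$`m.4769A>G`[match("s01", ph$sample_id)], 0.4)
  expect_equal(ph$`m.4769A>G`[match("s04", ph$sample_id)], 0) # non-carrier
  expect_equal(nrow(ph), 50L)
})

test_that("genotype PCA recovers planted population structure with fixed signs", {
  ds <- gen_assoc_dataset(300, 400, two_pop = TRUE, pop_shift = 0.3,
                          seed = 14)
  pcs <- genotype_pca(ds$gmat, k = 2)
  # 1-d silhouette of PC1 against the planted populations
  x <- pcs[, 1]
  sil <- vapply(seq_along(x), function(i) {
    own <- ds$pop == ds$pop[i]
    own[i] <- FALSE
    a <- mean(abs(x[i] - x[own]))
    b <- mean(abs(x[i] - x[!own]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.8)
  # sign convention: recomputing flips nothing
  expect_equal(pcs, genotype_pca(ds$gmat, k = 2))
  # degenerate inputs
  same <- matrix(1, nrow = 10, ncol = 5)
  expect_error(genotype_pca(same, k = 2), "variance")
  expect_error(genotype_pca(ds$gmat[1:5, 1:3], k = 10), "rank")
  expect_equal(ncol(genotype_pca(ds$gmat, k = 0)), 0L)
})

test_that("the covariate-free scan equals the simple-regression closed form", {
  set.seed(3)
  n <- 150
  g <- matrix(rbinom(n * 5, 2, 0.4), n, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  y <- rnorm(n)
  scan <- glm_scan(y, g)
  for (j in 1:5) {
    gv <- g[, j]
    beta_hat <- cov(gv, y) / var(gv)
    res <- y - mean(y) - beta_hat * (gv - mean(gv))
    se_hat <- sqrt(sum(res^2) / (n - 2) / sum((gv - mean(gv))^2))
    expect_equal(scan$results$beta[j], beta_hat, tolerance = 1e-10)
    expect_equal(scan$results$se[j], se_hat, tolerance = 1e-10)
  }
  # and agrees with lm() under covariates
  covs <- cbind(c1 = rnorm(n), c2 = rbinom(n, 1, 0.5))
  scan2 <- glm_scan(y, g, covariates = covs)
  fit <- lm(y ~ g[, 2] + covs)
  expect_equal(scan2$results$beta[2], unname(coef(fit)[2]),
               tolerance = 1e-10)
  expect_equal(scan2$results$p_value[2],
               unname(summary(fit)$coefficients[2, 4]), tolerance = 1e-8)
})

test_that("planted effects are recovered and degenerate dosages yield NA rows", {
  ds <- gen_assoc_dataset(2000, 50, n_causal = 1, beta = 0.1,
                          noise_sd = 0.05, seed = 6)
  scan <- glm_scan(ds$phenotype, ds$gmat)
  hit <- scan$results[scan$results$ndna_variant == ds$truth$variant_id, ]
  expect_lt(abs(hit$beta - 0.1), 3 * hit$se)
  expect_lt(hit$p_value, 1e-10)
  # constant dosage: flagged NA, not dropped
  g2 <- cbind(ds$gmat, mono = rep(2, 2000))
  scan2 <- glm_scan(ds$phenotype, g2)
  mono <- scan2$results[scan2$results$ndna_variant == "mono", ]
  expect_true(is.na(mono$beta))
  expect_equal(nrow(scan2$results), ncol(g2))
  # collinear with covariates: also NA
  covs <- cbind(dup = ds$gmat[, 1])
  scan3 <- glm_scan(ds$phenotype, ds$gmat[, 1:3], covariates = covs)
  expect_true(is.na(scan3$results$beta[1]))
})

test_that("null scans are calibrated and BH q-values behave", {
  ds <- gen_assoc_dataset(400, 800, n_causal = 0, seed = 44)
  scan <- glm_scan(ds$phenotype, ds$gmat)
  p <- scan$results$p_value
  frac <- mean(p <= 0.05)
  bound <- 2.576 * sqrt(0.05 * 0.95 / length(p))
  expect_lt(abs(frac - 0.05), bound + 1e-9)
  # q-values are monotone in p and never smaller
  o <- order(p)
  expect_true(all(diff(scan$results$q_value[o]) >= -1e-12))
  expect_true(all(scan$results$q_value >= p - 1e-12))
  # with everything null, q < 0.05 discoveries are (almost) never made
  expect_lt(sum(scan$results$q_value < 0.05), 3)
})

test_that("95% CIs cover planted betas at nominal rate across a grid", {
  set.seed(71)
  covered <- 0L
  total <- 0L
  for (b in c(0, 0.05, 0.1)) {
    for (rep in 1:60) {
      n <- 400
      g <- matrix(rbinom(n, 2, runif(1, 0.2, 0.4)), ncol = 1,
                  dimnames = list(NULL, "v"))
      y <- 0.4 + b * g[, 1] + rnorm(n, 0, 0.05)
      r <- glm_scan(y, g)$results
      ci <- r$beta + c(-1, 1) * qt(0.975, r$n - 2) * r$se
      covered <- covered + (b >= ci[1] && b <= ci[2])
      total <- total + 1L
    }
  }
  expect_gt(covered / total, 0.95 - 2.576 * sqrt(0.05 * 0.95 / total))
  expect_lt(covered / total, 0.95 + 2.576 * sqrt(0.05 * 0.95 / total) + 1e-9)
})

test_that("significance thresholds divide by the number of mtDNA phenotypes", {
  th <- significance_thresholds(0.05, 5e-8, 93)
  expect_equal(th$primary, 0.05 / 93)
  expect_equal(th$stringent, 5e-8 / 93)
  expect_equal(signif(th$primary, 2), 5.4e-4)
  expect_equal(signif(th$stringent, 2), 5.4e-10)
  expect_equal(significance_thresholds(n_mt = 1),
               list(primary = 0.05, stringent = 5e-8))
  expect_equal(significance_thresholds(alpha = 0, gw = 0, n_mt = 93),
               list(primary = 0, stringent = 0))
  expect_error(significance_thresholds(n_mt = 0), "n_mt")
})

test_that("scan objects support tidy, glance, flagging and plotting", {
  ds <- gen_assoc_dataset(300, 60, n_causal = 1, beta = 0.15, seed = 2)
  scan <- glm_scan(ds$phenotype, ds$gmat, mt_variant = "m.1A>G")
  expect_s3_class(tidy(scan), "tbl_df")
  gl <- glance(scan)
  expect_equal(gl$n_variants, 60L)
  expect_true(gl$lambda_gc > 0.5 && gl$lambda_gc < 2)
  flagged <- flag_significant(scan, significance_thresholds(n_mt = 1))
  expect_true(is.logical(flagged$significant_primary))
  expect_true(any(flagged$significant_stringent)) # the planted hit
  expect_s3_class(ggplot2::autoplot(scan), "ggplot")
  expect_output(print(scan), "mt_assoc_scan")
})
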