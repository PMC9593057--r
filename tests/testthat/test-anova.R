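test_that("RCBD mean squares match the hand-computed 2x2 toy case", {
  # g1: 1, 2 across reps; g2: 3, 4
  tab <- toy_table(matrix(c(1, 3, 2, 4), nrow = 2))
  fit <- rcbd_anova(tab, "X")
  expect_equal(unname(fit$ms[["genotypes"]]), 4)
  expect_equal(unname(fit$ms[["replications"]]), 1)
  expect_equal(unname(fit$ms[["error"]]), 0)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$f[["genotypes"]]))
})

test_that("constant tables are degenerate with zero sums of squares", {
  fit <- rcbd_anova(toy_table(matrix(5, 3, 3)), "X")
  expect_equal(unname(fit$ss), c(0, 0, 0))
  expect_true(all(is.na(fit$f)))
})

test_that("RCBD sums of squares agree with the brute-force decomposition", {
  set.seed(42)
  for (i in 1:10) {
    vals <- matrix(rnorm(15, 10, 2), 5, 3)
    fit <- rcbd_anova(toy_table(vals), "X")
    oracle <- brute_rcbd_ss(vals)
    expect_equal(unname(fit$ss[["genotypes"]]), oracle$ss_g)
    expect_equal(unname(fit$ss[["replications"]]), oracle$ss_r)
    expect_equal(unname(fit$ss[["error"]]), oracle$ss_e)
    # additivity of the decomposition
    expect_equal(sum(fit$ss), oracle$ss_total, tolerance = 1e-9)
  }
})

test_that("entry-mean heritability reproduces the 1 - 1/F identity", {
  expect_equal(round(heritability_entry_mean(12.94, 1, 7), 2), 92.27)
  expect_equal(round(heritability_entry_mean(342.77, 1, 3), 2), 99.71)
  expect_equal(heritability_entry_mean(1, 1, 7), 0)
  expect_warning(h0 <- heritability_entry_mean(0.5, 1, 7), "negative")
  expect_equal(h0, 0)
  expect_error(heritability_entry_mean(2, 0, 7), "positive")
})

test_that("heritability is monotone in F and scale invariant", {
  fs <- c(1.5, 3, 8, 20, 100)
  h <- vapply(fs, function(f) heritability_entry_mean(f, 1, 7), numeric(1))
  expect_true(all(diff(h) > 0))
  expect_true(all(h >= 0 & h <= 100))
  for (c2 in c(0.04, 9, 1e4)) {
    expect_equal(heritability_entry_mean(5 * c2, c2, 7),
                 heritability_entry_mean(5, 1, 7))
  }
})

test_that("LSD follows the t-quantile formula and its scaling law", {
  expect_equal(lsd(2, 4, 30), qt(0.975, 30), tolerance = 1e-12)
  expect_equal(lsd(0, 4, 30), 0)
  expect_equal(lsd(4, 5, 20), sqrt(2) * lsd(2, 5, 20))
})

test_that("variance components floor negatives and bundle H2/LSD", {
  tab <- toy_table(matrix(c(1, 3, 2, 4, 1.5, 3.5), nrow = 2))
  fit <- rcbd_anova(tab, "X")
  vc <- variance_components(fit)
  expect_equal(vc$sigma2_G,
               (fit$ms[["genotypes"]] - fit$ms[["error"]]) / 3,
               ignore_attr = TRUE)
  expect_equal(vc$sigma2_GR, unname(fit$ms[["error"]]))
  # direct arithmetic example
  expect_equal((12.94 - 1) / 7, 1.70571, tolerance = 1e-4)
  # MS_G < MS_e: truncated with flag
  set.seed(3)
  flat <- matrix(rnorm(40), 2, 20)  # 2 genotypes, 20 reps, no signal
  fits <- rcbd_anova(toy_table(flat), "X")
  if (fits$ms[["genotypes"]] < fits$ms[["error"]]) {
    expect_warning(vc2 <- variance_components(fits), "negative")
    expect_equal(vc2$sigma2_G, 0)
    expect_true(vc2$negative_component)
    expect_true(vc2$sigma2_G_raw < 0)
  }
})

test_that("two-factor ANOVA has the expected structure and tests", {
  set.seed(8)
  cfg <- two_treatment_config(12, 3, "P", G_true = matrix(4),
                              E_true = matrix(1),
                              treatment_shift = 5, gxt_sd = 1, seed = 21)
  tab <- simulate_two_treatment(cfg)
  fit <- two_factor_anova(tab, "P")
  expect_named(fit$ss, c("treatments", "replications", "genotypes",
                         "t_x_g", "error"))
  expect_equal(sum(fit$df), nrow(tab[tab$trait == "P", ]) - 1)
  # fixed treatment tested against the interaction mean square
  expect_equal(unname(fit$f[["treatments"]]),
               unname(fit$ms[["treatments"]] / fit$ms[["t_x_g"]]))
  # swapping treatment labels flips the contrast, keeps SS_T
  flipped <- tab
  flipped$treatment <- ifelse(tab$treatment == "control",
                              "drought", "control")
  fit2 <- two_factor_anova(phenotype_table(as.data.frame(flipped)), "P")
  expect_equal(unname(fit2$ss[["treatments"]]),
               unname(fit$ss[["treatments"]]))
  expect_equal(fit2$treatment_contrast, -fit$treatment_contrast)
  # recovery: estimated contrast near the planted shift
  expect_lt(abs(fit$treatment_contrast - 5), 1.5)
})

test_that("additively constructed data has zero interaction SS", {
  g <- rep(1:4, each = 6)
  grid <- expand.grid(rep = 1:3, trt = 1:2, geno = 1:4)
  tab <- phenotype_table(data.frame(
    genotype = paste0("g", grid$geno),
    replication = paste0("r", grid$rep),
    treatment = c("control", "drought")[grid$trt],
    trait = "P",
    value = 2 * grid$geno + 3 * (grid$trt == 2) + 0.5 * grid$rep
  ))
  fit <- two_factor_anova(tab, "P")
  expect_equal(unname(fit$ss[["t_x_g"]]), 0, tolerance = 1e-12)
  expect_error(two_factor_anova(toy_table(matrix(1:4, 2)), "X"),
               "no treatment")
})
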