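test_that("simulators are deterministic given a seed and leave the RNG alone", {
  cfg <- sim_config(10, 3, c("X", "Y"), diag(2), diag(2), seed = 101)
  t1 <- simulate_rcbd(cfg)
  set.seed(999)            # unrelated global state
  before <- runif(1)
  t2 <- simulate_rcbd(cfg)
  expect_identical(t1, t2)
  # the simulator restored the global stream it found
  set.seed(999)
  expect_identical(runif(1), before)
  m1 <- simulate_snp_matrix(5, 50, seed = 101)
  m2 <- simulate_snp_matrix(5, 50, seed = 101)
  expect_identical(m1, m2)
  w1 <- simulate_wilting_series(4, 3, seed = 101)
  expect_identical(w1, simulate_wilting_series(4, 3, seed = 101))
})

test_that("non-PSD covariance configurations are rejected with a diagnostic", {
  bad <- matrix(c(1, 2, 2, 1), 2)  # eigenvalues 3, -1
  expect_error(sim_config(5, 3, c("X", "Y"), bad, diag(2)),
               "positive semidefinite")
  asym <- matrix(c(1, 0.5, 0.1, 1), 2)
  expect_error(sim_config(5, 3, c("X", "Y"), asym, diag(2)), "symmetric")
  expect_error(sim_config(5, 1, "X", matrix(1), matrix(1)), "n_reps")
})

test_that("zero residual covariance drives heritability to 100", {
  cfg <- sim_config(15, 4, c("X", "Y"), diag(c(2, 3)),
                    matrix(0, 2, 2), seed = 7)
  tab <- simulate_rcbd(cfg)
  for (tr in c("X", "Y")) {
    vc <- variance_components(rcbd_anova(tab, tr))
    expect_equal(vc$H2, 100)
  }
})

test_that("empirical genotype-effect covariance approaches G_true", {
  G_true <- matrix(c(2, 0.8, 0.8, 1), 2)
  frob <- function(n_sims) {
    acc <- matrix(0, 2, 2)
    for (s in seq_len(n_sims)) {
      cfg <- sim_config(80, 2, c("X", "Y"), G_true, diag(c(1e-8, 1e-8)),
                        seed = 1000 + s)
      means <- genotype_means(simulate_rcbd(cfg))
      acc <- acc + cov(means)
    }
    sqrt(sum((acc / n_sims - G_true)^2))
  }
  expect_lt(frob(30), frob(2) + 0.15)
  expect_lt(frob(30), 0.25)
})

test_that("null two-treatment simulations give F near 1 and nominal size", {
  # gxt_sd = 0: interaction mean square matches the error mean square
  f_tg <- f_t <- numeric(120)
  for (s in seq_len(120)) {
    cfg <- two_treatment_config(10, 3, "P", G_true = matrix(2),
                                E_true = matrix(1),
                                treatment_shift = 0, gxt_sd = 0,
                                seed = 5000 + s)
    fit <- two_factor_anova(simulate_two_treatment(cfg), "P")
    f_tg[s] <- fit$f[["t_x_g"]]
    f_t[s] <- fit$p[["treatments"]]
  }
  expect_lt(abs(mean(f_tg) - 1), 0.15)
  # null treatment: type-I error near alpha
  expect_lt(abs(mean(f_t < 0.05) - 0.05), 0.05)
})

test_that("a planted treatment shift is recovered from the contrast", {
  shifts <- numeric(40)
  for (s in seq_len(40)) {
    cfg <- two_treatment_config(15, 3, "P", G_true = matrix(2),
                                E_true = matrix(1),
                                treatment_shift = 4, gxt_sd = 0.5,
                                seed = 7000 + s)
    shifts[s] <- two_factor_anova(simulate_two_treatment(cfg),
                                  "P")$treatment_contrast
  }
  expect_lt(abs(mean(shifts) - 4), 3 * sd(shifts) / sqrt(40) + 0.05)
})

test_that("RCBD genotype F-test has nominal size under a null panel", {
  rejections <- logical(200)
  for (s in seq_len(200)) {
    cfg <- sim_config(8, 3, "X", G_true = matrix(0), E_true = matrix(1),
                      seed = 9000 + s)
    fit <- rcbd_anova(simulate_rcbd(cfg), "X")
    rejections[s] <- fit$p[["genotypes"]] < 0.05
  }
  expect_lt(abs(mean(rejections) - 0.05), 0.045)
})

test_that("wilting series respect the scale, monotonicity and latents", {
  w <- simulate_wilting_series(6, 4, tolerance_latents = runif(6), seed = 3)
  expect_true(all(w$score >= 1 & w$score <= 9))
  for (key in split(w, paste(w$genotype, w$plant))) {
    expect_true(all(diff(key$score[order(key$date)]) >= 0))
  }
  # fully tolerant: all scores 1, summed score 5
  top <- simulate_wilting_series(2, 3, tolerance_latents = 1, seed = 4)
  expect_true(all(top$score == 1))
  s_lw <- tapply(top$score, paste(top$genotype, top$plant), sum)
  expect_true(all(s_lw == 5))
  # fully susceptible: every plant reaches the ceiling, sums near 45
  bottom <- simulate_wilting_series(2, 30, tolerance_latents = 0, seed = 4)
  expect_true(all(tapply(bottom$score, paste(bottom$genotype, bottom$plant),
                         max) == 9))
  s_lw_b <- tapply(bottom$score, paste(bottom$genotype, bottom$plant), sum)
  expect_gt(mean(s_lw_b), 40)
  expect_true(all(s_lw_b <= 45))
})

test_that("SNP simulation controls missingness and cluster structure", {
  m <- simulate_snp_matrix(20, 2000, missing_rate = 0.1, seed = 5)
  miss <- mean(is.na(m))
  ci <- qbinom(c(0.0005, 0.9995), length(m), 0.1) / length(m)
  expect_gt(miss, ci[1])
  expect_lt(miss, ci[2])
  # identical rows injected: distance exactly zero
  m0 <- simulate_snp_matrix(4, 100, missing_rate = 0, seed = 6)
  m0 <- rbind(m0, dup = m0[1, ])
  d <- as.matrix(simple_matching_distance(m0))
  expect_equal(d["G001", "dup"], 0)
  # two well-separated clusters recovered by UPGMA in >= 95% of sims
  hits <- 0L
  n_sims <- 60L
  for (s in seq_len(n_sims)) {
    ms <- simulate_snp_matrix(8, 150, n_clusters = 2, cluster_drift = 2,
                              seed = 300 + s)
    truth <- attr(ms, "cluster")
    tree <- upgma(simple_matching_distance(ms))
    splits <- lapply(phylo_clades(tree), `[[`, "tips")
    want <- sort(rownames(ms)[truth == 1])
    want2 <- sort(rownames(ms)[truth == 2])
    if (any(vapply(splits, identical, logical(1), want)) ||
        any(vapply(splits, identical, logical(1), want2))) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_sims, 0.95)
})

test_that("the wheat panel generator plants recoverable tolerant lines", {
  tab <- simulate_wheat_panel(n_genotypes = 50, n_reps = 7,
                              n_tolerant = 5, seed = 77)
  planted <- attr(tab, "planted_tolerant")
  expect_length(planted, 5)
  means <- genotype_means(tab)
  # planted genotypes sit on the tolerant side of every trait on average
  meta <- wheat_trait_metadata()
  for (tr in colnames(means)) {
    dir <- meta$direction[match(tr, meta$trait)]
    delta <- mean(means[planted, tr]) - mean(means[!rownames(means) %in%
                                                     planted, tr])
    if (dir == "low") expect_lt(delta, 0) else expect_gt(delta, 0)
  }
})
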