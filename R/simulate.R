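# Seed discipline: every simulator draws from its own stream derived from
# the single user seed plus a per-simulator offset, and restores the global
# RNG state on exit, so adding or reordering simulators never perturbs the
# draws of another.
local_seed <- function(seed, stream) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  derived <- (as.double(seed) * 48271 + stream * 16807) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(derived))
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

check_psd <- function(m, name) {
  m <- as.matrix(m)
  if (!isSymmetric(unname(m), tol = 1e-8)) {
    stop(name, " must be symmetric")
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop(name, " is not positive semidefinite (min eigenvalue ",
         format(min(ev)), ")")
  }
  invisible(m)
}

# MVN sampler that tolerates singular (PSD) covariance matrices.
rmvn <- function(n, sigma) {
  sigma <- as.matrix(sigma)
  k <- ncol(sigma)
  e <- eigen(sigma, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), k)
  z <- matrix(stats::rnorm(n * k), n, k)
  z %*% t(L)
}

#' Configuration for a balanced RCBD simulation
#'
#' Ground-truth generative parameters for a multi-trait randomized
#' complete block trial: genotype effects are multivariate normal with
#' covariance `G_true`, plot errors (the genotype x replication interaction)
#' multivariate normal with covariance `E_true`, and replication effects
#' independent normal per trait.
#'
#' @param n_genotypes number of genotypes (>= 2).
#' @param n_reps number of replications (>= 2).
#' @param trait_names trait labels; length sets the trait dimension.
#' @param G_true genotypic covariance matrix (trait x trait, PSD).
#' @param E_true residual covariance matrix (trait x trait, PSD).
#' @param rep_effect_sd standard deviation of replication effects (>= 0).
#' @param mu trait means added to every observation (default 0).
#' @param seed integer seed; a fixed seed yields identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genotypes, n_reps, trait_names,
                       G_true, E_true, rep_effect_sd = 0,
                       mu = rep(0, length(trait_names)), seed = 1L) {
  k <- length(trait_names)
  G_true <- as.matrix(G_true)
  E_true <- as.matrix(E_true)
  if (!all(dim(G_true) == k) || !all(dim(E_true) == k)) {
    stop("G_true and E_true must be ", k, " x ", k,
         " to match trait_names")
  }
  check_psd(G_true, "G_true")
  check_psd(E_true, "E_true")
  if (n_reps < 2) stop("n_reps must be at least 2")
  if (n_genotypes < 2) stop("n_genotypes must be at least 2")
  if (rep_effect_sd < 0) stop("rep_effect_sd must be non-negative")
  if (length(mu) != k) stop("mu must have one entry per trait")
  structure(list(n_genotypes = n_genotypes, n_reps = n_reps,
                 trait_names = trait_names, G_true = G_true,
                 E_true = E_true, rep_effect_sd = rep_effect_sd,
                 mu = mu, seed = seed),
            class = "sim_config")
}

#' Simulate a balanced multi-trait RCBD trial
#'
#' Draws `Y_ijt = mu_t + g_it + r_jt + e_ijt` with genotype effect vectors
#' `g_i ~ MVN(0, G_true)`, plot errors `e_ij ~ MVN(0, E_true)` and
#' replication effects `r_jt ~ N(0, rep_effect_sd^2)` independent per trait.
#'
#' @param config a [sim_config()].
#' @param genotype_shift optional genotype x trait matrix added to the
#'   genotype effects (used to plant known tolerant genotypes).
#' @return A balanced [phenotype_table()] with
#'   `n_genotypes * n_reps` rows per trait.
#' @export
simulate_rcbd <- function(config, genotype_shift = NULL) {
  stopifnot(inherits(config, "sim_config"))
  restore <- local_seed(config$seed, stream = 1L)
  on.exit(restore())
  ng <- config$n_genotypes
  nr <- config$n_reps
  k <- length(config$trait_names)
  genos <- sprintf("G%03d", seq_len(ng))
  reps <- sprintf("R%d", seq_len(nr))

  g <- rmvn(ng, config$G_true)
  if (!is.null(genotype_shift)) {
    genotype_shift <- as.matrix(genotype_shift)
    if (!all(dim(genotype_shift) == c(ng, k))) {
      stop("genotype_shift must be n_genotypes x n_traits")
    }
    g <- g + genotype_shift
  }
  r_eff <- matrix(stats::rnorm(nr * k, sd = config$rep_effect_sd), nr, k)
  e <- rmvn(ng * nr, config$E_true)

  idx_g <- rep(seq_len(ng), each = nr)
  idx_r <- rep(seq_len(nr), times = ng)
  y <- matrix(config$mu, ng * nr, k, byrow = TRUE) +
    g[idx_g, , drop = FALSE] + r_eff[idx_r, , drop = FALSE] + e
  out <- data.frame(
    genotype = rep(genos[idx_g], times = k),
    replication = rep(reps[idx_r], times = k),
    trait = rep(config$trait_names, each = ng * nr),
    value = as.vector(y),
    stringsAsFactors = FALSE
  )
  phenotype_table(out)
}

#' Configuration for a two-treatment (control/drought) simulation
#'
#' Extends [sim_config()] with a fixed per-trait treatment shift and a
#' genotype x treatment interaction scale. Both treatments share the same
#' genotype main effects.
#'
#' @inheritParams sim_config
#' @param treatment_shift per-trait fixed effect of drought (drought minus
#'   control).
#' @param gxt_sd per-trait standard deviation of the genotype x treatment
#'   interaction (>= 0).
#' @return A list of class `two_treatment_config` (also `sim_config`).
#' @export
two_treatment_config <- function(n_genotypes, n_reps = 3, trait_names,
                                 G_true, E_true,
                                 treatment_shift = rep(0, length(trait_names)),
                                 gxt_sd = rep(0, length(trait_names)),
                                 rep_effect_sd = 0,
                                 mu = rep(0, length(trait_names)),
                                 seed = 1L) {
  cfg <- sim_config(n_genotypes, n_reps, trait_names, G_true, E_true,
                    rep_effect_sd, mu, seed)
  if (length(treatment_shift) != length(trait_names) ||
      length(gxt_sd) != length(trait_names)) {
    stop("treatment_shift and gxt_sd must have one entry per trait")
  }
  if (any(gxt_sd < 0)) stop("gxt_sd must be non-negative")
  cfg$treatment_shift <- treatment_shift
  cfg$gxt_sd <- gxt_sd
  class(cfg) <- c("two_treatment_config", "sim_config")
  cfg
}

#' Simulate a balanced two-treatment trial
#'
#' Draws `Y_ijkt = mu_t + g_it + r_jt + t_kt + tg_ikt + e_ijkt`: genotype
#' main effects shared across treatments, the drought level shifted by
#' `treatment_shift`, and an independent genotype x treatment interaction
#' with per-trait scale `gxt_sd`.
#'
#' @param config a [two_treatment_config()].
#' @return A balanced [phenotype_table()] with a `treatment` column
#'   (`control`/`drought`).
#' @export
simulate_two_treatment <- function(config) {
  stopifnot(inherits(config, "two_treatment_config"))
  restore <- local_seed(config$seed, stream = 2L)
  on.exit(restore())
  ng <- config$n_genotypes
  nr <- config$n_reps
  k <- length(config$trait_names)
  genos <- sprintf("G%03d", seq_len(ng))
  reps <- sprintf("R%d", seq_len(nr))
  trts <- c("control", "drought")

  g <- rmvn(ng, config$G_true)
  r_eff <- matrix(stats::rnorm(nr * k, sd = config$rep_effect_sd), nr, k)
  tg <- array(stats::rnorm(ng * 2 * k, sd = rep(config$gxt_sd,
                                                each = ng * 2)),
              dim = c(ng, 2, k))
  e <- rmvn(ng * nr * 2, config$E_true)

  grid <- expand.grid(rep = seq_len(nr), trt = 1:2, geno = seq_len(ng))
  shift <- outer(grid$trt == 2L, config$treatment_shift)
  tg_rows <- tg[cbind(rep(grid$geno, k), rep(grid$trt, k),
                      rep(seq_len(k), each = nrow(grid)))]
  y <- matrix(config$mu, nrow(grid), k, byrow = TRUE) +
    g[grid$geno, , drop = FALSE] + r_eff[grid$rep, , drop = FALSE] +
    shift + matrix(tg_rows, nrow(grid), k) + e
  out <- data.frame(
    genotype = rep(genos[grid$geno], times = k),
    replication = rep(reps[grid$rep], times = k),
    treatment = rep(trts[grid$trt], times = k),
    trait = rep(config$trait_names, each = nrow(grid)),
    value = as.vector(y),
    stringsAsFactors = FALSE
  )
  phenotype_table(out)
}

#' Simulate ordinal leaf-wilting time series
#'
#' Each plant carries a latent cumulative stress process: non-negative
#' increments accrue at each scoring date, scaled by one minus the
#' genotype's tolerance latent, and the visible score is the latent floored
#' onto the 1..9 scale. Scores are therefore non-decreasing within plant;
#' a fully tolerant latent (1) keeps every score at 1, and a fully
#' susceptible latent (0) is guaranteed to reach 9 before the last date.
#'
#' @param n_genotypes number of genotypes.
#' @param n_plants plants scored per genotype.
#' @param n_dates number of scoring dates (default 5, giving the summed
#'   score its 5..45 range).
#' @param tolerance_latents per-genotype tolerance in 0..1 (1 = fully
#'   tolerant); recycled if scalar.
#' @param seed integer seed.
#' @return Data frame with `genotype`, `plant`, `date`, `score` (integer in
#'   1..9, non-decreasing over dates within plant).
#' @export
simulate_wilting_series <- function(n_genotypes, n_plants, n_dates = 5,
                                    tolerance_latents = 0.5, seed = 1L) {
  if (n_dates < 1) stop("n_dates must be at least 1")
  tol <- rep_len(tolerance_latents, n_genotypes)
  if (any(tol < 0 | tol > 1)) stop("tolerance latents must lie in [0, 1]")
  restore <- local_seed(seed, stream = 3L)
  on.exit(restore())
  n <- n_genotypes * n_plants
  # per-date latent increment: (4 + Exp(0.5)) * (1 - tol); the floor of 4
  # makes the fully susceptible trajectory reach the scale ceiling surely
  inc <- matrix((4 + stats::rexp(n * n_dates, rate = 0.5)) *
                  rep(1 - tol, each = n_plants),
                n, n_dates)
  latent <- t(apply(inc, 1L, cumsum))
  if (n_dates == 1L) latent <- matrix(inc, n, 1L)
  score <- pmin(1L + floor(latent), 9L)  # matrix first: keeps dimensions
  data.frame(
    genotype = rep(sprintf("G%03d", seq_len(n_genotypes)),
                   each = n_plants * n_dates),
    plant = rep(rep(seq_len(n_plants), each = n_dates),
                times = n_genotypes),
    date = rep(seq_len(n_dates), times = n),
    score = as.integer(t(score)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a clustered biallelic SNP matrix with missing calls
#'
#' Markers get ancestral allele frequencies drawn from `maf_range`; each
#' cluster perturbs them with its own drift so within-cluster pairs are more
#' similar than between-cluster pairs in expectation. Calls are categorical
#' genotype symbols (`"AA"`, `"AB"`, `"BB"`) from binomial sampling of two
#' alleles, with the requested fraction masked as missing.
#'
#' @param n_genotypes number of genotypes.
#' @param n_markers number of markers.
#' @param maf_range ancestral minor-allele frequency range, within (0, 0.5].
#' @param n_clusters number of latent clusters (>= 1).
#' @param missing_rate fraction of calls set to `NA`, in `[0, 1)`.
#' @param cluster_drift standard deviation of the per-cluster logit-scale
#'   perturbation of allele frequencies; larger values separate clusters.
#' @param seed integer seed.
#' @return A character matrix (genotypes x markers) with attributes
#'   `cluster` (integer cluster assignment) recording the truth.
#' @export
simulate_snp_matrix <- function(n_genotypes, n_markers,
                                maf_range = c(0.1, 0.5), n_clusters = 1,
                                missing_rate = 0, cluster_drift = 1.5,
                                seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  if (n_clusters < 1) stop("n_clusters must be at least 1")
  restore <- local_seed(seed, stream = 4L)
  on.exit(restore())
  p0 <- stats::runif(n_markers, maf_range[1], maf_range[2])
  logit <- function(p) log(p / (1 - p))
  inv_logit <- function(x) 1 / (1 + exp(-x))
  cluster <- rep_len(seq_len(n_clusters), n_genotypes)
  cl_p <- sapply(seq_len(n_clusters), function(cl) {
    inv_logit(logit(p0) + stats::rnorm(n_markers, sd = cluster_drift))
  })  # markers x clusters
  counts <- matrix(stats::rbinom(n_genotypes * n_markers, size = 2,
                                 prob = t(cl_p[, cluster, drop = FALSE])),
                   n_genotypes, n_markers, byrow = FALSE)
  calls <- matrix(c("AA", "AB", "BB")[counts + 1L],
                  n_genotypes, n_markers,
                  dimnames = list(sprintf("G%03d", seq_len(n_genotypes)),
                                  sprintf("M%05d", seq_len(n_markers))))
  if (missing_rate > 0) {
    mask <- stats::runif(length(calls)) < missing_rate
    calls[mask] <- NA_character_
  }
  attr(calls, "cluster") <- cluster
  calls
}
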