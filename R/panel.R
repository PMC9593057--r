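#' Default generative parameters for a diverse seedling drought panel
#'
#' Entry-mean summaries used as generator defaults for the six directly
#' scored traits: trait mean, phenotypic standard deviation of entry means,
#' and entry-mean heritability, parameterised from a published 172-genotype
#' spring wheat screen, together with the genotypic correlation structure
#' estimated there. The correlation matrix as printed contains a -1.00 pair
#' and is not positive semidefinite; it is repaired once, deterministically,
#' by flooring eigenvalues and rescaling to unit diagonal.
#'
#' @return A list with `stats` (data frame: trait, mean, sd_entry, h2) and
#'   `G_cor` (PSD genotypic correlation matrix).
#' @export
wheat_panel_defaults <- function() {
  stats_df <- data.frame(
    trait = c("SL", "S_LW", "DTW", "DTR", "RB", "DSR"),
    mean = c(15.75, 20.53, 5.68, 78.5, 11.98, 19.6),
    sd_entry = c(2.602, 2.334, 0.744, 12.075, 18.808, 21.862),
    h2 = c(0.9227, 0.8493, 0.8385, 0.8755, 0.9132, 0.8398),
    stringsAsFactors = FALSE
  )
  g <- diag(6)
  dimnames(g) <- list(stats_df$trait, stats_df$trait)
  fill <- function(a, b, v) {
    g[a, b] <<- v
    g[b, a] <<- v
  }
  fill("SL", "S_LW", 0.53); fill("SL", "DTW", -0.74)
  fill("SL", "DTR", 0.55);  fill("SL", "RB", -0.59)
  fill("SL", "DSR", -0.60)
  fill("S_LW", "DTW", -0.86); fill("S_LW", "DTR", 0.63)
  fill("S_LW", "RB", -0.60);  fill("S_LW", "DSR", -0.62)
  fill("DTW", "DTR", -0.55); fill("DTW", "RB", 0.54)
  fill("DTW", "DSR", 0.56)
  fill("DTR", "RB", -0.92); fill("DTR", "DSR", -1.00)
  fill("RB", "DSR", 0.95)
  list(stats = stats_df, G_cor = make_psd_correlation(g))
}

# Nearest-ish PSD correlation matrix: floor eigenvalues at a small positive
# value, reassemble, rescale to unit diagonal. Deterministic and adequate
# for a generator default; not a full Higham projection.
make_psd_correlation <- function(m, floor = 1e-4) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= floor) return(m)
  v <- e$vectors %*% diag(pmax(e$values, floor)) %*% t(e$vectors)
  d <- sqrt(diag(v))
  out <- v / tcrossprod(d)
  dimnames(out) <- dimnames(m)
  out
}

#' Simulate a diverse seedling drought panel with planted tolerant lines
#'
#' Generates a balanced RCBD panel for the six screening traits with the
#' default means, heritabilities and genotypic correlation structure of
#' [wheat_panel_defaults()], optionally planting `n_tolerant` genotypes
#' whose genotype effects are shifted toward tolerance in every trait by
#' `tolerant_effect` genotypic standard deviations. The default effect of
#' 3.5 SD matches the separation observed for the most tolerant lines in
#' diverse panels (3 or more phenotypic SD from the panel mean).
#'
#' @param n_genotypes panel size (default 172).
#' @param n_reps replications (default 7).
#' @param n_tolerant number of planted tolerant genotypes (default 0).
#' @param tolerant_effect shift in genotypic SD units (default 3.5).
#' @param seed integer seed.
#' @return A balanced [phenotype_table()] for traits `SL`, `S_LW`, `DTW`,
#'   `DTR`, `RB`, `DSR`, with attribute `planted_tolerant` naming the
#'   planted genotypes.
#' @export
simulate_wheat_panel <- function(n_genotypes = 172, n_reps = 7,
                                 n_tolerant = 0, tolerant_effect = 3.5,
                                 seed = 1L) {
  defs <- wheat_panel_defaults()
  st <- defs$stats
  sigma_g <- sqrt(st$h2) * st$sd_entry
  sigma_e <- sqrt(n_reps * (1 - st$h2)) * st$sd_entry
  G_true <- defs$G_cor * tcrossprod(sigma_g)
  E_true <- diag(sigma_e^2)
  dimnames(E_true) <- dimnames(G_true)
  cfg <- sim_config(n_genotypes, n_reps, st$trait, G_true, E_true,
                    rep_effect_sd = 0.1 * mean(sigma_e), mu = st$mean,
                    seed = seed)
  shift <- NULL
  planted <- character(0)
  if (n_tolerant > 0) {
    restore <- local_seed(seed, stream = 5L)
    idx <- sort(sample.int(n_genotypes, n_tolerant))
    restore()
    planted <- sprintf("G%03d", idx)
    dir_sign <- ifelse(
      wheat_trait_metadata()$direction[
        match(st$trait, wheat_trait_metadata()$trait)] == "low", -1, 1)
    shift <- matrix(0, n_genotypes, length(st$trait))
    shift[idx, ] <- rep(tolerant_effect * dir_sign * sigma_g,
                        each = n_tolerant)
  }
  out <- simulate_rcbd(cfg, genotype_shift = shift)
  attr(out, "planted_tolerant") <- planted
  out
}

#' Default generative parameters for the physiological assays
#'
#' Per-trait control means, entry-mean phenotypic SDs and heritabilities,
#' and the average drought shift for the six physiological traits (protein,
#' amino acids, proline, glucose, fructose, total soluble carbohydrates),
#' parameterised from the same published screen (three replications).
#'
#' @return Data frame with `trait`, `mu_control`, `shift` (drought minus
#'   control mean), `sd_entry`, `h2`.
#' @export
physiology_defaults <- function() {
  data.frame(
    trait = c("P", "AM", "PRO", "G", "F", "TSC"),
    mu_control = c(140.68, 8.74, 1.63, 73.33, 86.69, 202.55),
    shift = c(-12.94, 0.35, 0.82, 12.14, 1.48, 24.18),
    sd_entry = c(35.55, 3.96, 0.47, 18.51, 35.31, 39.78),
    h2 = c(0.9641, 0.9786, 0.9868, 0.9839, 0.9742, 0.969),
    stringsAsFactors = FALSE
  )
}

#' Simulate the two-treatment physiological assay
#'
#' Balanced control/drought trial for the six physiological traits over
#' three replications, using [physiology_defaults()]; genotype main effects
#' are shared across treatments and the genotype x treatment interaction
#' scale defaults to half the genotypic SD per trait.
#'
#' @param n_genotypes panel size (default 172).
#' @param n_reps replications (default 3).
#' @param gxt_fraction interaction SD as a fraction of the genotypic SD.
#' @param seed integer seed.
#' @return A balanced two-treatment [phenotype_table()].
#' @export
simulate_physiology_panel <- function(n_genotypes = 172, n_reps = 3,
                                      gxt_fraction = 0.5, seed = 1L) {
  st <- physiology_defaults()
  sigma_g <- sqrt(st$h2) * st$sd_entry
  sigma_e <- sqrt(n_reps * (1 - st$h2)) * st$sd_entry
  cfg <- two_treatment_config(
    n_genotypes, n_reps, st$trait,
    G_true = diag(sigma_g^2), E_true = diag(sigma_e^2),
    treatment_shift = st$shift, gxt_sd = gxt_fraction * sigma_g,
    mu = st$mu_control, seed = seed
  )
  simulate_two_treatment(cfg)
}
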