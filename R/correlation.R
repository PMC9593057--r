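#' Spearman rank correlation matrix of entry means
#'
#' Phenotypic correlations at the genotype level: Spearman's rank
#' correlation with average ranks for ties, with two-sided p-values from the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`. Cells are marked
#' `*` / `**` at the 0.05 / 0.01 levels.
#'
#' @param means genotype x trait matrix of entry means (see
#'   [genotype_means()]); at least 3 genotypes, no missing entries.
#' @return An object of class `correlation_matrix` with elements `r`, `p`,
#'   `mark`, `kind = "phenotypic"` and `n_genotypes`. A constant column gives
#'   `NA` coefficients with that trait.
#' @export
spearman_matrix <- function(means) {
  means <- as.matrix(means)
  n <- nrow(means)
  if (n < 3L) stop("at least 3 genotypes are required")
  if (anyNA(means)) stop("entry-mean matrix must have no missing entries")
  constant <- apply(means, 2L, function(v) stats::sd(v) == 0)
  r <- suppressWarnings(stats::cor(means, method = "spearman"))
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  diag(r)[!constant] <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  mark <- matrix(significance_mark(p), nrow = nrow(p), dimnames = dimnames(p))
  structure(list(r = r, p = p, mark = mark, kind = "phenotypic",
                 n_genotypes = n),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat(x$kind, "correlation matrix over", x$n_genotypes, "genotypes\n")
  disp <- matrix(paste0(formatC(x$r, digits = digits, format = "f"), x$mark),
                 nrow = nrow(x$r), dimnames = dimnames(x$r))
  disp[is.na(x$r)] <- "NA"
  print(as.data.frame(disp), right = TRUE)
  if (x$kind == "genotypic" && any(abs(x$r) > 1, na.rm = TRUE)) {
    cat("note: coefficients outside [-1, 1] occur (sampling estimates)\n")
  }
  invisible(x)
}

# Balanced two-way mean cross-product decomposition for a pair of traits,
# mirroring the RCBD sums of squares. Returns genotype, replication and
# error mean products plus the dfs needed downstream.
cross_product_decomposition <- function(table, trait_x, trait_y) {
  sx <- table[table$trait == trait_x, c("genotype", "replication", "value")]
  sy <- table[table$trait == trait_y, c("genotype", "replication", "value")]
  if (nrow(sx) == 0L) stop("trait not found: ", trait_x)
  if (nrow(sy) == 0L) stop("trait not found: ", trait_y)
  m <- merge(sx, sy, by = c("genotype", "replication"),
             suffixes = c("_x", "_y"))
  if (nrow(m) != nrow(sx) || nrow(m) != nrow(sy)) {
    stop("traits ", trait_x, " and ", trait_y,
         " are not observed on identical (genotype, replication) keys")
  }
  check_balanced(phenotype_table(data.frame(
    genotype = m$genotype, replication = m$replication,
    trait = trait_x, value = m$value_x)))
  g <- length(unique(m$genotype))
  r <- length(unique(m$replication))

  xg <- tapply(m$value_x, m$genotype, mean)
  yg <- tapply(m$value_y, m$genotype, mean)
  xr <- tapply(m$value_x, m$replication, mean)
  yr <- tapply(m$value_y, m$replication, mean)
  xm <- mean(m$value_x)
  ym <- mean(m$value_y)

  sp_g <- r * sum((xg - xm) * (yg - ym))
  sp_r <- g * sum((xr - xm) * (yr - ym))
  sp_tot <- sum((m$value_x - xm) * (m$value_y - ym))
  sp_e <- sp_tot - sp_g - sp_r
  list(mp_g = sp_g / (g - 1),
       mp_r = sp_r / (r - 1),
       mp_e = sp_e / ((g - 1) * (r - 1)),
       df_g = g - 1, df_e = (g - 1) * (r - 1),
       n_genotypes = g, n_reps = r)
}

#' Genotype and error mean cross-products for a trait pair
#'
#' Analysis-of-covariance decomposition of cross-products mirroring the RCBD
#' ANOVA: with `trait_y == trait_x` the mean products equal the ANOVA mean
#' squares.
#'
#' @param table a balanced single-treatment [phenotype_table()] carrying both
#'   traits on identical (genotype, replication) keys.
#' @param trait_x,trait_y trait names.
#' @return A list with `mp_g` (genotype mean product), `mp_e` (error mean
#'   product) and `n_reps`.
#' @export
mean_cross_products <- function(table, trait_x, trait_y) {
  d <- cross_product_decomposition(table, trait_x, trait_y)
  list(mp_g = d$mp_g, mp_e = d$mp_e, n_reps = d$n_reps)
}

#' Genotypic correlation between two traits
#'
#' Estimated from expected mean products: the genotypic covariance is
#' `(MP_G - MP_e) / r` and the genotypic correlation is its value
#' standardised by the genotypic standard deviations of the two traits.
#' Estimates can exceed 1 in magnitude and are flagged, not clipped. The
#' coefficient is marked `+` / `++` when it exceeds one / two times its
#' approximate standard error (a Mode-Robinson-style approximation built
#' from the sampling variances of the heritabilities; see the methods
#' vignette).
#'
#' @inheritParams mean_cross_products
#' @return A list with `r_g`, `se`, `mark` (`""`, `"+"`, or `"++"`),
#'   `cov_g`, and `exceeds_unit` flag; `r_g` is `NA` when either trait has
#'   no genotypic variance.
#' @export
genotypic_correlation <- function(table, trait_x, trait_y) {
  dxy <- cross_product_decomposition(table, trait_x, trait_y)
  dx <- cross_product_decomposition(table, trait_x, trait_x)
  dy <- cross_product_decomposition(table, trait_y, trait_y)
  r <- dxy$n_reps
  cov_g <- (dxy$mp_g - dxy$mp_e) / r
  var_gx <- (dx$mp_g - dx$mp_e) / r
  var_gy <- (dy$mp_g - dy$mp_e) / r
  if (var_gx <= 0 || var_gy <= 0) {
    warning("zero or negative genotypic variance; genotypic correlation ",
            "undefined for (", trait_x, ", ", trait_y, ")")
    return(list(r_g = NA_real_, se = NA_real_, mark = "",
                cov_g = cov_g, exceeds_unit = NA))
  }
  r_g <- cov_g / sqrt(var_gx * var_gy)
  se <- rg_standard_error(r_g, dx, dy)
  mark <- if (is.na(se)) "" else
    if (abs(r_g) > 2 * se) "++" else if (abs(r_g) > se) "+" else ""
  list(r_g = r_g, se = se, mark = mark, cov_g = cov_g,
       exceeds_unit = abs(r_g) > 1)
}

# Mode-Robinson-style SE: SE(r_g) = (1 - r_g^2)/sqrt(2) *
# sqrt(SE(H2_x) * SE(H2_y) / (H2_x * H2_y)), with Var(sigma2_G) from the
# chi-square sampling variances of the mean squares. An approximation; the
# +/++ convention only needs its order of magnitude.
rg_standard_error <- function(r_g, dx, dy) {
  h2_se <- function(d) {
    r <- d$n_reps
    s2g <- (d$mp_g - d$mp_e) / r
    s2p <- s2g + d$mp_e / r          # entry-mean phenotypic variance
    if (s2g <= 0 || s2p <= 0) return(c(NA_real_, NA_real_))
    var_msg <- 2 * d$mp_g^2 / (d$df_g + 2)
    var_mse <- 2 * d$mp_e^2 / (d$df_e + 2)
    var_s2g <- (var_msg + var_mse) / r^2
    # delta method on H2 = s2g / s2p with s2p ~ MS_G / r
    se_h2 <- sqrt(var_s2g) / s2p
    c(s2g / s2p, se_h2)
  }
  hx <- h2_se(dx)
  hy <- h2_se(dy)
  if (anyNA(c(hx, hy)) || hx[1] <= 0 || hy[1] <= 0) return(NA_real_)
  (1 - min(r_g^2, 1)) / sqrt(2) *
    sqrt((hx[2] * hy[2]) / (hx[1] * hy[1]))
}

#' Full genotypic correlation matrix
#'
#' @param table a balanced single-treatment [phenotype_table()].
#' @param traits traits to include; default all traits in the table.
#' @return A `correlation_matrix` (kind `"genotypic"`) with `r`, `se`,
#'   `mark` and `n_genotypes`.
#' @export
genotypic_matrix <- function(table, traits = unique(table$trait)) {
  k <- length(traits)
  r <- se <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  mark <- matrix("", k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) {
    r[i, i] <- 1
    for (j in seq_len(k)) {
      if (j <= i) next
      gc <- genotypic_correlation(table, traits[i], traits[j])
      r[i, j] <- r[j, i] <- gc$r_g
      se[i, j] <- se[j, i] <- gc$se
      mark[i, j] <- mark[j, i] <- gc$mark
    }
  }
  structure(list(r = r, se = se, p = NULL, mark = mark, kind = "genotypic",
                 n_genotypes = length(unique(table$genotype))),
            class = "correlation_matrix")
}

#' Phenotypic and genotypic covariance matrices on the entry-mean basis
#'
#' For each trait pair the genotype mean product divided by the number of
#' replications is the phenotypic covariance of entry means (`P`), and
#' `(MP_G - MP_e) / r` is the genotypic covariance (`G`). Diagonal elements
#' of `G` are floored at zero. These are the matrices the Smith-Hazel index
#' weights `b = P^-1 G a` are built from.
#'
#' @param table a balanced single-treatment [phenotype_table()].
#' @param traits traits to include, in index order.
#' @return A list of class `cov_matrices` with `P`, `G`, `n_reps`.
#' @export
cov_matrices <- function(table, traits = unique(table$trait)) {
  k <- length(traits)
  P <- G <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  n_reps <- NA_integer_
  for (i in seq_len(k)) {
    for (j in i:k) {
      d <- cross_product_decomposition(table, traits[i], traits[j])
      n_reps <- d$n_reps
      P[i, j] <- P[j, i] <- d$mp_g / d$n_reps
      G[i, j] <- G[j, i] <- (d$mp_g - d$mp_e) / d$n_reps
    }
  }
  neg <- diag(G) < 0
  if (any(neg)) {
    warning("negative genotypic variance floored at 0 for: ",
            paste(traits[neg], collapse = ", "))
    diag(G)[neg] <- 0
  }
  structure(list(P = P, G = G, n_reps = n_reps), class = "cov_matrices")
}
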