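#' RCBD analysis of variance for one trait
#'
#' Fits the single-treatment randomized-complete-block model
#' `Y_ij = mu + g_i + r_j + e_ij`, where the genotype x replication
#' interaction is the error term. Genotypes are tested against the error
#' mean square with `(g - 1, (g - 1)(r - 1))` degrees of freedom.
#'
#' @param table a balanced single-treatment [phenotype_table()].
#' @param trait trait name to analyse.
#' @return An object of class `rcbd_anova`: a list with the ANOVA table
#'   (`df`, `ss`, `ms`, `f`, `p` per source), `n_genotypes`, `n_reps`,
#'   `grand_mean` and `trait`. `f` is `NA` (flagged degenerate) when the
#'   error mean square is zero.
#' @seealso [variance_components()] for heritability and LSD.
#' @export
rcbd_anova <- function(table, trait) {
  sub <- table[table$trait == trait, , drop = FALSE]
  if (nrow(sub) == 0L) stop("trait not found: ", trait)
  if ("treatment" %in% names(sub) && length(unique(sub$treatment)) > 1L) {
    stop("rcbd_anova expects a single treatment; use two_factor_anova")
  }
  sub <- phenotype_table(sub)
  check_balanced(sub)
  g <- length(unique(sub$genotype))
  r <- length(unique(sub$replication))
  if (g < 2L || r < 2L) stop("need at least 2 genotypes and 2 replications")

  fit <- stats::aov(value ~ genotype + replication,
                    data = transform(sub,
                                     genotype = factor(genotype),
                                     replication = factor(replication)))
  tab <- summary(fit)[[1L]]
  ss <- tab[["Sum Sq"]]
  df <- tab[["Df"]]
  ms <- tab[["Mean Sq"]]
  names(ss) <- names(df) <- names(ms) <-
    c("genotypes", "replications", "error")
  degenerate <- ms[["error"]] <= .Machine$double.eps * max(1, ms[["genotypes"]])
  f <- c(genotypes = if (degenerate) NA_real_ else
           ms[["genotypes"]] / ms[["error"]],
         replications = if (degenerate) NA_real_ else
           ms[["replications"]] / ms[["error"]])
  p <- c(genotypes = if (degenerate) NA_real_ else
           stats::pf(f[["genotypes"]], df[["genotypes"]], df[["error"]],
                     lower.tail = FALSE),
         replications = if (degenerate) NA_real_ else
           stats::pf(f[["replications"]], df[["replications"]], df[["error"]],
                     lower.tail = FALSE))
  structure(list(trait = trait, df = df, ss = ss, ms = ms, f = f, p = p,
                 n_genotypes = g, n_reps = r,
                 grand_mean = mean(sub$value),
                 degenerate = degenerate, model = "rcbd"),
            class = "rcbd_anova")
}

#' Two-factor ANOVA for control/drought trait data
#'
#' Fits `Y_ijk = mu + g_i + r_j + t_k + tg_ik + e_ijk` with treatment fixed
#' and genotypes and replications random. Genotypes and the treatment x
#' genotype interaction are tested against the residual; the fixed treatment
#' effect is tested against the interaction mean square, its expectation
#' under the mixed model.
#'
#' @param table a balanced [phenotype_table()] with exactly two treatment
#'   levels.
#' @param trait trait name to analyse.
#' @return An object of class `rcbd_anova` with sources `treatments`,
#'   `replications`, `genotypes`, `t_x_g` and `error`, plus
#'   `treatment_contrast` (drought mean minus control mean).
#' @export
two_factor_anova <- function(table, trait) {
  sub <- table[table$trait == trait, , drop = FALSE]
  if (nrow(sub) == 0L) stop("trait not found: ", trait)
  if (!"treatment" %in% names(sub)) stop("table has no treatment column")
  trts <- sort(unique(sub$treatment))
  if (length(trts) != 2L) {
    stop("exactly 2 treatment levels are required, found ", length(trts))
  }
  sub <- phenotype_table(sub)
  check_balanced(sub)
  g <- length(unique(sub$genotype))
  r <- length(unique(sub$replication))

  fit <- stats::aov(value ~ treatment + replication + genotype +
                      treatment:genotype,
                    data = transform(sub,
                                     genotype = factor(genotype),
                                     replication = factor(replication),
                                     treatment = factor(treatment)))
  tab <- summary(fit)[[1L]]
  src <- c("treatments", "replications", "genotypes", "t_x_g", "error")
  ss <- stats::setNames(tab[["Sum Sq"]], src)
  df <- stats::setNames(tab[["Df"]], src)
  ms <- stats::setNames(tab[["Mean Sq"]], src)
  f <- c(treatments = ms[["treatments"]] / ms[["t_x_g"]],
         replications = ms[["replications"]] / ms[["error"]],
         genotypes = ms[["genotypes"]] / ms[["error"]],
         t_x_g = ms[["t_x_g"]] / ms[["error"]])
  p <- c(treatments = stats::pf(f[["treatments"]], df[["treatments"]],
                                df[["t_x_g"]], lower.tail = FALSE),
         replications = stats::pf(f[["replications"]], df[["replications"]],
                                  df[["error"]], lower.tail = FALSE),
         genotypes = stats::pf(f[["genotypes"]], df[["genotypes"]],
                               df[["error"]], lower.tail = FALSE),
         t_x_g = stats::pf(f[["t_x_g"]], df[["t_x_g"]], df[["error"]],
                           lower.tail = FALSE))
  contrast <- mean(sub$value[sub$treatment == "drought"]) -
    mean(sub$value[sub$treatment == "control"])
  structure(list(trait = trait, df = df, ss = ss, ms = ms, f = f, p = p,
                 n_genotypes = g, n_reps = r, treatments = trts,
                 treatment_contrast = contrast,
                 grand_mean = mean(sub$value),
                 degenerate = FALSE, model = "two_factor"),
            class = "rcbd_anova")
}

#' @export
print.rcbd_anova <- function(x, ...) {
  cat("Analysis of variance (", x$model, ") for trait ", x$trait, "\n",
      sep = "")
  out <- data.frame(Df = x$df, `Sum Sq` = signif(x$ss, 6),
                    `Mean Sq` = signif(x$ms, 6),
                    check.names = FALSE)
  out$F <- signif(x$f[rownames(out)], 5)
  out$`Pr(>F)` <- format.pval(x$p[rownames(out)], digits = 4)
  out$sig <- significance_mark(x$p[rownames(out)])
  print(out)
  invisible(x)
}

significance_mark <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "")))
}

#' Entry-mean broad-sense heritability from mean squares
#'
#' In a balanced RCBD the genotypic variance is
#' `sigma2_G = (MS_G - MS_e) / r` and the heritability of genotype means is
#' `H2 = sigma2_G / (sigma2_G + MS_e / r)`, which simplifies to `1 - 1/F`.
#' Returned as a percentage, truncated to 0..100; a genotype mean square
#' below the error mean square yields 0 with a warning.
#'
#' @param ms_g genotype mean square.
#' @param ms_e error mean square (> 0).
#' @param n_reps number of replications.
#' @return Heritability percent in 0..100.
#' @export
#' @examples
#' heritability_entry_mean(12.94, 1, 7)  # 92.27
heritability_entry_mean <- function(ms_g, ms_e, n_reps) {
  if (ms_e <= 0) stop("ms_e must be positive")
  if (n_reps < 1) stop("n_reps must be at least 1")
  if (ms_g < ms_e) {
    warning("negative genotypic variance component; heritability set to 0")
    return(0)
  }
  sigma2_g <- (ms_g - ms_e) / n_reps
  h2 <- 100 * sigma2_g / (sigma2_g + ms_e / n_reps)
  min(max(h2, 0), 100)
}

#' Least significant difference between genotype means
#'
#' `LSD = t(1 - alpha/2, df_e) * sqrt(2 * MS_e / r)`, the smallest difference
#' between two genotype means declared significant at level `alpha`.
#'
#' @param ms_e error mean square.
#' @param n_reps number of replications.
#' @param df_error error degrees of freedom (>= 1).
#' @param alpha significance level, default 0.05.
#' @return The LSD value.
#' @export
lsd <- function(ms_e, n_reps, df_error, alpha = 0.05) {
  if (df_error < 1) stop("df_error must be at least 1")
  if (ms_e < 0) stop("ms_e must be non-negative")
  stats::qt(1 - alpha / 2, df_error) * sqrt(2 * ms_e / n_reps)
}

#' Variance components, heritability and LSD from an RCBD fit
#'
#' @param anova an object from [rcbd_anova()].
#' @param alpha significance level for the LSD.
#' @return A list of class `variance_components` with `sigma2_G` (floored at
#'   0), `sigma2_G_raw`, `sigma2_GR` (the error variance), `H2` percent,
#'   `LSD`, `negative_component` flag and `n_reps`.
#' @export
variance_components <- function(anova, alpha = 0.05) {
  stopifnot(inherits(anova, "rcbd_anova"))
  if (anova$model != "rcbd") {
    stop("variance_components expects a model-1 (single treatment) fit")
  }
  ms_g <- anova$ms[["genotypes"]]
  ms_e <- anova$ms[["error"]]
  r <- anova$n_reps
  raw <- (ms_g - ms_e) / r
  negative <- raw < 0
  if (negative) {
    warning("negative genotypic variance estimate for ", anova$trait,
            " truncated to 0")
  }
  h2 <- if (ms_e > 0) {
    if (negative) 0 else heritability_entry_mean(ms_g, ms_e, r)
  } else {
    100  # no error variance: all variation genotypic
  }
  structure(list(trait = anova$trait,
                 sigma2_G = max(raw, 0), sigma2_G_raw = raw,
                 sigma2_GR = ms_e, H2 = h2,
                 LSD = lsd(ms_e, r, anova$df[["error"]], alpha),
                 alpha = alpha,
                 negative_component = negative, n_reps = r),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components for ", x$trait, " (r = ", x$n_reps, ")\n",
      "  sigma2_G  = ", signif(x$sigma2_G, 6),
      if (x$negative_component) " (raw negative, truncated)" else "", "\n",
      "  sigma2_GR = ", signif(x$sigma2_GR, 6), "\n",
      "  H2        = ", round(x$H2, 2), " %\n",
      "  LSD(", x$alpha, ") = ", signif(x$LSD, 5), "\n", sep = "")
  invisible(x)
}
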