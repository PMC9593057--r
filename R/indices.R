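#' Published Smith-Hazel index weights for the seedling drought screen
#'
#' The tolerance index (TI) describes the summed leaf-wilting score using
#' days to wilting and seedling length as auxiliary traits; the recovery
#' index (RI) describes the regrowth disposition using regrowth biomass and
#' survival rate. These coefficient vectors were estimated on a 172-genotype
#' spring wheat panel and ship as constants so published scores can be
#' reproduced exactly.
#'
#' @return A named list with numeric vectors `TI` (over `S_LW`, `DTW`, `SL`)
#'   and `RI` (over `DTR`, `RB`, `DSR`).
#' @export
#' @examples
#' printed_index_weights()$TI
printed_index_weights <- function() {
  list(TI = c(S_LW = 0.7429, DTW = -0.3808, SL = 0.0186),
       RI = c(DTR = 0.6424, RB = -0.1389, DSR = -0.0267))
}

#' Smith-Hazel selection index weights
#'
#' Solves `b = P^-1 G a` for the index coefficients that maximise the
#' correlation between the linear index `b'x` and the aggregate genotype
#' `a'g`, given the phenotypic (`P`) and genotypic (`G`) entry-mean
#' covariance matrices. The system is solved directly; no explicit inverse
#' is formed. The reciprocal condition number of `P` is reported and a
#' numerically singular `P` is rejected.
#'
#' @param cov a [cov_matrices()] object (or a list with matrices `P`, `G`).
#' @param a economic weight vector, one entry per trait in the matrices'
#'   order.
#' @return An object of class `index_weights`: list with `traits`, `b`, `a`,
#'   `provenance = "estimated"` and `rcond_P`.
#' @export
smith_hazel_weights <- function(cov, a) {
  P <- as.matrix(cov$P)
  G <- as.matrix(cov$G)
  if (!isTRUE(all.equal(dim(P), dim(G))) || nrow(P) != length(a)) {
    stop("P, G and a must have matching dimensions")
  }
  rc <- rcond(P)
  if (!is.finite(rc) || rc < .Machine$double.eps * 100) {
    stop("phenotypic covariance matrix is numerically singular ",
         "(rcond = ", format(rc), ")")
  }
  b <- drop(solve(P, G %*% a))
  traits <- rownames(P)
  if (!is.null(traits)) names(b) <- traits
  structure(list(traits = traits, b = b, a = a,
                 provenance = "estimated", rcond_P = rc),
            class = "index_weights")
}

#' Wrap published coefficients as index weights
#'
#' @param which `"TI"` or `"RI"` (see [printed_index_weights()]).
#' @return An `index_weights` object with `provenance = "printed"`.
#' @export
printed_weights <- function(which = c("TI", "RI")) {
  which <- match.arg(which)
  b <- printed_index_weights()[[which]]
  structure(list(traits = names(b), b = b, a = NULL,
                 provenance = "printed", rcond_P = NA_real_),
            class = "index_weights")
}

#' @export
print.index_weights <- function(x, ...) {
  cat("Selection index weights (", x$provenance, ")\n", sep = "")
  print(round(x$b, 4))
  invisible(x)
}

#' Apply a linear selection index to genotype trait values
#'
#' Computes `b'x` per genotype. Trait columns must match the weight names
#' (reordered if needed); a mismatch is an error, never silently recycled.
#'
#' @param values genotype x trait matrix (or data frame) of entry means.
#' @param weights an `index_weights` object or named numeric vector.
#' @return Named numeric vector of index scores, one per genotype (row).
#' @export
#' @examples
#' x <- rbind(g1 = c(S_LW = 20.53, DTW = 5.68, SL = 15.75))
#' linear_index(x, printed_weights("TI"))  # 13.38
linear_index <- function(values, weights) {
  b <- if (inherits(weights, "index_weights")) weights$b else weights
  values <- as.matrix(values)
  if (is.null(colnames(values)) || is.null(names(b))) {
    if (ncol(values) != length(b)) {
      stop("values and weights have mismatched lengths and no names")
    }
  } else {
    missing_tr <- setdiff(names(b), colnames(values))
    if (length(missing_tr) > 0L) {
      stop("trait(s) required by the index are absent: ",
           paste(missing_tr, collapse = ", "))
    }
    values <- values[, names(b), drop = FALSE]
  }
  drop(values %*% b)
}

#' Composite drought tolerance index
#'
#' The arithmetic mean of the tolerance and recovery indices after each is
#' standardised by its population standard deviation:
#' `DTI = (TI/SD_TI + RI/SD_RI) / 2`. Low values indicate tolerance.
#'
#' @param ti,ri tolerance and recovery index scores (vectors of equal
#'   length, or scalars).
#' @param sd_ti,sd_ri positive population standard deviations of TI and RI.
#' @return DTI scores.
#' @export
#' @examples
#' dti(13.38, 48.27, 1.992, 10.655)  # 5.62
dti <- function(ti, ri, sd_ti, sd_ri) {
  if (!is.finite(sd_ti) || sd_ti <= 0) stop("sd_ti must be positive")
  if (!is.finite(sd_ri) || sd_ri <= 0) stop("sd_ri must be positive")
  (ti / sd_ti + ri / sd_ri) / 2
}

#' Per-genotype TI, RI and DTI scores
#'
#' Applies the tolerance and recovery indices to a table of entry means and
#' combines them into the composite drought tolerance index. In `"printed"`
#' mode the published coefficients are used; in `"estimate"` mode the
#' Smith-Hazel weights are re-estimated from the data's own phenotypic and
#' genotypic covariance matrices, with economic weight 1 on the primary
#' trait (S_LW for TI, DTR for RI) and 0 on the auxiliaries by default.
#'
#' @param means genotype x trait matrix with columns `S_LW`, `DTW`, `SL`,
#'   `DTR`, `RB`, `DSR` (extra columns ignored).
#' @param weights `"printed"` or `"estimate"`.
#' @param table the [phenotype_table()] the means came from; required for
#'   `"estimate"` mode.
#' @param a_ti,a_ri economic weight vectors for estimate mode, in the trait
#'   order `(S_LW, DTW, SL)` and `(DTR, RB, DSR)`.
#' @return An object of class `index_scores`: data frame with `genotype`,
#'   `TI`, `RI`, `DTI` plus attributes `sd_ti`, `sd_ri`, `weights_ti`,
#'   `weights_ri`, `provenance`.
#' @export
index_scores <- function(means, weights = c("printed", "estimate"),
                         table = NULL,
                         a_ti = c(1, 0, 0), a_ri = c(1, 0, 0)) {
  weights <- match.arg(weights)
  if (weights == "printed") {
    w_ti <- printed_weights("TI")
    w_ri <- printed_weights("RI")
  } else {
    if (is.null(table)) stop("estimate mode requires the phenotype table")
    cov_ti <- cov_matrices(table, c("S_LW", "DTW", "SL"))
    cov_ri <- cov_matrices(table, c("DTR", "RB", "DSR"))
    w_ti <- smith_hazel_weights(cov_ti, a_ti)
    w_ri <- smith_hazel_weights(cov_ri, a_ri)
  }
  ti <- linear_index(means, w_ti)
  ri <- linear_index(means, w_ri)
  sd_ti <- stats::sd(ti)
  sd_ri <- stats::sd(ri)
  if (!is.finite(sd_ti) || sd_ti <= 0 || !is.finite(sd_ri) || sd_ri <= 0) {
    stop("index standard deviations must be positive; ",
         "need at least 2 distinct genotypes")
  }
  out <- data.frame(genotype = rownames(as.matrix(means)),
                    TI = ti, RI = ri,
                    DTI = dti(ti, ri, sd_ti, sd_ri),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, sd_ti = sd_ti, sd_ri = sd_ri,
            weights_ti = w_ti, weights_ri = w_ri,
            provenance = weights,
            class = c("index_scores", "data.frame"))
}

#' @export
print.index_scores <- function(x, ...) {
  cat("Selection index scores (", attr(x, "provenance"), " weights; ",
      "SD_TI = ", signif(attr(x, "sd_ti"), 4),
      ", SD_RI = ", signif(attr(x, "sd_ri"), 4),
      "; low DTI = tolerant)\n", sep = "")
  NextMethod()
}
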