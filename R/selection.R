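#' Rank genotypes by a trait in the direction of tolerance
#'
#' @param means genotype x trait matrix of entry means.
#' @param trait trait name (a column of `means`).
#' @param direction `"low"` if low values indicate tolerance, `"high"`
#'   otherwise; defaults to the declaration in [wheat_trait_metadata()].
#' @return Character vector of genotype labels, most tolerant first; ties
#'   broken alphabetically by label so the ordering is deterministic.
#' @export
rank_by_trait <- function(means, trait, direction = NULL) {
  means <- as.matrix(means)
  if (!trait %in% colnames(means)) stop("trait not found: ", trait)
  if (is.null(direction)) {
    meta <- wheat_trait_metadata()
    direction <- meta$direction[match(trait, meta$trait)]
    if (is.na(direction)) {
      stop("no declared tolerance direction for trait ", trait)
    }
  }
  if (!direction %in% c("low", "high")) {
    stop("direction must be 'low' or 'high', got: ", direction)
  }
  v <- means[, trait]
  labels <- rownames(means)
  ord <- order(if (direction == "low") v else -v, labels)
  labels[ord]
}

#' Multi-trait top-k selection
#'
#' A genotype is selected when it lies in the top `k` (most tolerant) of at
#' least `m` of the trait rankings and, when `require_dti` is set, also in
#' the top `k` of the composite drought tolerance index. Genotypes tied with
#' the k-th ranked value are all admitted (the effective k inflates and the
#' inflation is recorded).
#'
#' @param means genotype x trait matrix including the index columns; the
#'   default trait set is the nine screening columns `SL`, `S_LW`, `DTW`,
#'   `DTR`, `DSR`, `RB`, `TI`, `RI`, `DTI`.
#' @param k top-rank cutoff per trait (default 20).
#' @param m minimum number of qualifying traits (default 5).
#' @param require_dti additionally require top-k membership in `DTI`.
#' @param traits trait columns to score.
#' @param directions named character vector of tolerance directions;
#'   defaults to [wheat_trait_metadata()].
#' @return An object of class `selection_report`: data frame with one row
#'   per genotype, logical top-k flags per trait, `n_traits` (count of true
#'   flags), and `selected`; ordered by `n_traits` descending. Attribute
#'   `tie_inflation` records traits where ties inflated k.
#' @export
multi_trait_select <- function(means, k = 20, m = 5, require_dti = TRUE,
                               traits = c("SL", "S_LW", "DTW", "DTR", "DSR",
                                          "RB", "TI", "RI", "DTI"),
                               directions = NULL) {
  means <- as.matrix(means)
  missing_tr <- setdiff(traits, colnames(means))
  if (length(missing_tr) > 0L) {
    stop("missing trait ranking(s): ", paste(missing_tr, collapse = ", "))
  }
  n <- nrow(means)
  if (k > n) stop("k = ", k, " exceeds the number of genotypes (", n, ")")
  if (require_dti && !"DTI" %in% traits) {
    stop("require_dti needs a DTI column")
  }
  genos <- rownames(means)
  flags <- matrix(FALSE, n, length(traits), dimnames = list(genos, traits))
  ties <- character(0)
  for (tr in traits) {
    dir <- if (is.null(directions)) NULL else directions[[tr]]
    ranked <- rank_by_trait(means, tr, dir)
    v <- means[ranked, tr]
    cut <- v[k]
    # admit everything at least as tolerant as the k-th ranked value
    meta_dir <- if (is.null(dir)) {
      meta <- wheat_trait_metadata()
      meta$direction[match(tr, meta$trait)]
    } else dir
    keep <- if (meta_dir == "low") means[, tr] <= cut else means[, tr] >= cut
    if (sum(keep) > k) ties <- c(ties, tr)
    flags[, tr] <- keep
  }
  n_traits <- rowSums(flags)
  selected <- n_traits >= m & (!require_dti | flags[, "DTI"])
  out <- data.frame(genotype = genos, flags, n_traits = n_traits,
                    selected = selected, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- out[order(-out$n_traits, out$genotype), ]
  rownames(out) <- NULL
  structure(out, k = k, m = m, require_dti = require_dti,
            tie_inflation = ties,
            class = c("selection_report", "data.frame"))
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Multi-trait selection: top-", attr(x, "k"), " in >= ", attr(x, "m"),
      " traits", if (attr(x, "require_dti")) " and DTI", "; ",
      sum(x$selected), " of ", nrow(x), " genotypes selected\n", sep = "")
  ties <- attr(x, "tie_inflation")
  if (length(ties) > 0L) {
    cat("ties inflated k for:", paste(ties, collapse = ", "), "\n")
  }
  disp <- x
  for (cl in names(disp)) {
    if (is.logical(disp[[cl]])) disp[[cl]] <- ifelse(disp[[cl]], "+", "")
  }
  print(as.data.frame(disp))
  invisible(x)
}

#' Categorize genotypes by composite drought tolerance index
#'
#' Three-way partition of DTI scores into tolerant / intermediate /
#' susceptible by two cutpoints. Lower DTI means more tolerant, so scores
#' at or below the first cutpoint are tolerant and scores above the second
#' are susceptible. Default cutpoints are the tertiles of the scores.
#'
#' @param dti_scores named numeric vector of DTI values.
#' @param cutpoints increasing numeric vector of length 2; default tertiles.
#' @return A list with `category` (factor per genotype, levels tolerant /
#'   intermediate / susceptible), `counts`, and the `cutpoints` used.
#' @export
categorize_dti <- function(dti_scores, cutpoints = NULL) {
  if (length(dti_scores) < 1L) stop("at least one genotype is required")
  if (is.null(cutpoints)) {
    cutpoints <- unname(stats::quantile(dti_scores, c(1 / 3, 2 / 3)))
  }
  if (length(cutpoints) != 2L || diff(cutpoints) < 0) {
    stop("cutpoints must be two non-decreasing values")
  }
  lev <- c("tolerant", "intermediate", "susceptible")
  category <- factor(ifelse(dti_scores <= cutpoints[1L], lev[1L],
                            ifelse(dti_scores <= cutpoints[2L],
                                   lev[2L], lev[3L])),
                     levels = lev)
  names(category) <- names(dti_scores)
  list(category = category,
       counts = table(category),
       cutpoints = cutpoints)
}
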