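#' Simple-matching genetic distance with pairwise deletion
#'
#' For each genotype pair the distance is one minus the fraction of matching
#' calls among markers where both genotypes have a non-missing call.
#' Heterozygous or multi-symbol calls match only as exact categorical
#' symbols. A pair with no comparable markers is an error.
#'
#' @param snp genotype x marker matrix of categorical calls (character or
#'   factor); `NA` marks a missing call.
#' @return A [stats::dist] object (method `"simple matching"`), entries in
#'   0..1.
#' @export
#' @examples
#' m <- rbind(a = c("AA", "AB", "BB"), b = c("AA", "BB", "BB"))
#' simple_matching_distance(m)  # 1/3
simple_matching_distance <- function(snp) {
  snp <- as.matrix(snp)
  if (nrow(snp) < 2L) stop("at least 2 genotypes are required")
  mode(snp) <- "character"
  n <- nrow(snp)
  labels <- rownames(snp)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(snp[i, ]) & !is.na(snp[j, ])
      m <- sum(ok)
      if (m == 0L) {
        stop("genotypes ", labels[i], " and ", labels[j],
             " share no non-missing marker")
      }
      d[i, j] <- d[j, i] <- 1 - sum(snp[i, ok] == snp[j, ok]) / m
    }
  }
  stats::as.dist(d)
}

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage hierarchical clustering (UPGMA): at each step the two
#' closest clusters merge at half their average distance, producing a rooted
#' ultrametric tree. Ties are broken deterministically by cluster label.
#'
#' @param dist a [stats::dist] object or symmetric distance matrix with zero
#'   diagonal.
#' @param linkage `"average"` (UPGMA, the default), `"single"` or
#'   `"complete"`.
#' @return An [ape::phylo] tree (rooted, ultrametric for complete data);
#'   node heights equal half the merge distances.
#' @export
upgma <- function(dist, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (!inherits(dist, "dist")) {
    dist <- as.matrix(dist)
    if (!isSymmetric(unname(dist), tol = 1e-8)) {
      stop("distance matrix must be symmetric")
    }
    if (any(abs(diag(dist)) > 1e-12)) {
      stop("distance matrix must have a zero diagonal")
    }
    dist <- stats::as.dist(dist)
  }
  # stable label-based tie handling: hclust merges the first minimal pair
  # in its scan order, which is determined by the (fixed) label order here
  hc <- stats::hclust(dist, method = linkage)
  # as.phylo halves the merge heights, giving the ultrametric convention
  # where a cherry sits at half the pairwise distance
  ape::as.phylo(hc)
}

#' Write a tree in newick format
#'
#' @param tree an [ape::phylo] object.
#' @param path optional file path; when `NULL` the newick string is
#'   returned.
#' @return The newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}

#' Summarise a gene presence/absence panel against DTI
#'
#' Row totals of a binary gene panel (e.g. DREB transcription-factor allele
#' presence among selected genotypes) and the Pearson correlation between
#' the per-genotype gene count and the composite drought tolerance index.
#'
#' @param panel genotype x gene matrix or data frame of 0/1 (or logical)
#'   presence flags, genotype labels as row names.
#' @param dti_scores named numeric vector of DTI values covering the same
#'   genotypes.
#' @return A list with `totals` (named integer vector), `r` (Pearson
#'   correlation of totals with DTI), `p` (two-sided), and `n`.
#' @export
gene_panel_summary <- function(panel, dti_scores) {
  panel <- as.matrix(panel)
  mode(panel) <- "numeric"
  if (!all(panel %in% c(0, 1))) stop("panel flags must be binary")
  genos <- rownames(panel)
  if (is.null(genos) || is.null(names(dti_scores))) {
    stop("panel rows and dti_scores must be named by genotype")
  }
  if (!setequal(genos, names(dti_scores))) {
    stop("genotype sets differ between panel and DTI scores")
  }
  totals <- rowSums(panel)
  dti <- dti_scores[genos]
  ct <- stats::cor.test(totals, dti, method = "pearson")
  list(totals = stats::setNames(as.integer(totals), genos),
       r = unname(ct$estimate), p = ct$p.value, n = length(genos))
}
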