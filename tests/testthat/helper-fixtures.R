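# Small programmatic fixtures shared across test files.

# Balanced single-treatment table from a genotype x replication value matrix
# (one trait).
toy_table <- function(values, trait = "X") {
  g <- nrow(values)
  r <- ncol(values)
  phenotype_table(data.frame(
    genotype = rep(sprintf("g%02d", seq_len(g)), times = r),
    replication = rep(sprintf("r%d", seq_len(r)), each = g),
    trait = trait,
    value = as.vector(values)
  ))
}

# Two traits on the same keys.
toy_table2 <- function(x, y, traits = c("X", "Y")) {
  rbind(toy_table(x, traits[1]), toy_table(y, traits[2]))
}

# Brute-force RCBD sums of squares by direct mean decomposition.
brute_rcbd_ss <- function(values) {
  g <- nrow(values); r <- ncol(values)
  gm <- mean(values)
  gi <- rowMeans(values); rj <- colMeans(values)
  ss_g <- r * sum((gi - gm)^2)
  ss_r <- g * sum((rj - gm)^2)
  resid <- sweep(sweep(values, 1, gi), 2, rj) + gm
  list(ss_g = ss_g, ss_r = ss_r, ss_e = sum(resid^2),
       ss_total = sum((values - gm)^2))
}

# Brute-force average-linkage (UPGMA) merge heights and tip partitions.
brute_upgma <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(rownames(d))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d - 1e-12) {
          best_d <- dd; best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d / 2)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    merges <- c(merges, list(sort(merged)))
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# Clade tip sets (size > 1) with their heights from an ultrametric phylo.
phylo_clades <- function(tree) {
  n_tip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  node_height <- max(depth) - depth
  lapply((n_tip + 1):(n_tip + tree$Nnode), function(nd) {
    tips <- ape::extract.clade(tree, nd)$tip.label
    list(tips = sort(tips), height = node_height[nd])
  })
}
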