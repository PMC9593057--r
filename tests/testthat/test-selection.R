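mk_means <- function(...) {
  vals <- list(...)
  m <- do.call(cbind, vals)
  rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  m
}

test_that("trait ranking follows the declared tolerance direction", {
  m <- mk_means(DSR = c(10, 90, 50), S_LW = c(12, 30, 20))
  expect_equal(rank_by_trait(m, "DSR"), c("g02", "g03", "g01"))
  expect_equal(rank_by_trait(m, "S_LW"), c("g01", "g03", "g02"))
  # ties break alphabetically by label, identically across calls
  tie <- mk_means(DSR = c(5, 5, 1))
  expect_equal(rank_by_trait(tie, "DSR"), c("g01", "g02", "g03"))
  expect_identical(rank_by_trait(tie, "DSR"), rank_by_trait(tie, "DSR"))
  expect_error(rank_by_trait(m, "DSR", direction = "up"), "low")
  expect_error(rank_by_trait(m, "XX"), "not found")
})

test_that("multi-trait selection applies the top-k / m-trait / DTI rule", {
  set.seed(6)
  n <- 12
  cols <- c("SL", "S_LW", "DTW", "DTR", "DSR", "RB", "TI", "RI", "DTI")
  m <- matrix(rnorm(n * 9), n, 9, dimnames = list(sprintf("g%02d", 1:n),
                                                  cols))
  # genotype 1 best in every trait
  meta <- wheat_trait_metadata()
  for (tr in cols) {
    dir <- meta$direction[match(tr, meta$trait)]
    m[1, tr] <- if (dir == "low") min(m[, tr]) - 1 else max(m[, tr]) + 1
  }
  rep <- multi_trait_select(m, k = 3, m = 5)
  row1 <- rep[rep$genotype == "g01", ]
  expect_true(row1$selected)
  expect_equal(row1$n_traits, 9)
  # m - 1 qualifying traits plus DTI is not enough
  m2 <- m
  worst <- function(tr) {
    dir <- meta$direction[match(tr, meta$trait)]
    if (dir == "low") max(m2[, tr]) + 1 else min(m2[, tr]) - 1
  }
  for (tr in c("SL", "S_LW", "DTW", "DTR", "DSR")) m2[1, tr] <- worst(tr)
  # g01 now qualifies only in RB, TI, RI, DTI = 4 < m
  rep2 <- multi_trait_select(m2, k = 3, m = 5)
  expect_false(rep2[rep2$genotype == "g01", "selected"])
  expect_error(multi_trait_select(m, k = 50), "exceeds")
})

test_that("selection matches a brute-force enumeration on a planted panel", {
  tab <- simulate_wheat_panel(n_genotypes = 30, n_reps = 5,
                              n_tolerant = 4, seed = 13)
  run <- run_pipeline(tab, k = 8, m = 5)
  means <- run$means
  meta <- wheat_trait_metadata()
  k <- 8
  brute_selected <- vapply(rownames(means), function(g) {
    hits <- vapply(colnames(means), function(tr) {
      dir <- meta$direction[match(tr, meta$trait)]
      v <- sort(means[, tr], decreasing = (dir == "high"))
      cut <- v[k]
      if (dir == "low") means[g, tr] <= cut else means[g, tr] >= cut
    }, logical(1))
    sum(hits) >= 5 && hits[["DTI"]]
  }, logical(1))
  got <- run$selection$selected[match(rownames(means),
                                      run$selection$genotype)]
  expect_equal(unname(got), unname(brute_selected))
})

test_that("selection is monotone and invariant to row order", {
  set.seed(20)
  cols <- c("SL", "S_LW", "DTW", "DTR", "DSR", "RB", "TI", "RI", "DTI")
  m <- matrix(rnorm(20 * 9), 20, 9,
              dimnames = list(sprintf("g%02d", 1:20), cols))
  rep1 <- multi_trait_select(m, k = 6, m = 4)
  # improving a selected genotype's DSR (high = tolerant) keeps it selected
  sel_ids <- rep1$genotype[rep1$selected]
  if (length(sel_ids) > 0) {
    m_imp <- m
    m_imp[sel_ids[1], "DSR"] <- max(m[, "DSR"]) + 1
    rep_imp <- multi_trait_select(m_imp, k = 6, m = 4)
    expect_true(rep_imp[rep_imp$genotype == sel_ids[1], "selected"])
  }
  shuffled <- m[sample(nrow(m)), ]
  rep2 <- multi_trait_select(shuffled, k = 6, m = 4)
  expect_equal(rep1[order(rep1$genotype), ],
               rep2[order(rep2$genotype), ],
               ignore_attr = TRUE)
})

test_that("ties at the k-th rank admit all tied genotypes", {
  cols <- c("SL", "S_LW", "DTW", "DTR", "DSR", "RB", "TI", "RI", "DTI")
  m <- matrix(rep(c(1, 1, 1, 2), 9), 4, 9,
              dimnames = list(sprintf("g%02d", 1:4), cols))
  rep <- multi_trait_select(m, k = 2, m = 5)
  # three genotypes tie at the low value in every low-direction trait
  expect_true(length(attr(rep, "tie_inflation")) > 0)
  low_traits <- c("SL", "S_LW", "DTR", "TI", "RI", "DTI")
  expect_true(all(rep[rep$genotype %in% c("g01", "g02", "g03"),
                      low_traits[1]]))
})

test_that("DTI categorization partitions by cutpoints", {
  same <- categorize_dti(setNames(rep(4, 6), paste0("g", 1:6)))
  expect_equal(length(unique(same$category)), 1L)
  nine <- setNames(1:9, paste0("g", 1:9))
  three <- categorize_dti(nine, cutpoints = c(3, 6))
  expect_equal(unname(as.integer(three$counts)), c(3, 3, 3))
  # planted three-cluster scores recovered by tertile cutpoints
  clust <- setNames(c(rnorm(5, 0, 0.05), rnorm(5, 5, 0.05),
                      rnorm(5, 10, 0.05)), paste0("g", 1:15))
  got <- categorize_dti(clust)
  expect_equal(unname(as.integer(got$counts)), c(5, 5, 5))
  expect_equal(unname(got$category[1:5]),
               factor(rep("tolerant", 5),
                      levels = c("tolerant", "intermediate", "susceptible")),
               ignore_attr = TRUE)
  expect_error(categorize_dti(nine, cutpoints = c(6, 3)), "non-decreasing")
})
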