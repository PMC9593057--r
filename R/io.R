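#' Read a long-format phenotype table from delimited text
#'
#' Expects tab-separated columns `genotype`, `replication`, `trait`,
#' `value` and optionally `treatment`; comment lines starting with `#`
#' (output headers) are skipped. The table is validated: missing columns,
#' duplicate keys and out-of-range values are rejected.
#'
#' @param path file path.
#' @param trait_meta optional trait metadata (see [wheat_trait_metadata()]).
#' @param sep field separator, default tab.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path, trait_meta = NULL, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  phenotype_table(df, trait_meta = trait_meta)
}

#' Write a phenotype table as delimited text
#'
#' @param table a [phenotype_table()].
#' @param path output path.
#' @param header optional character vector of `#`-prefixed header lines.
#' @param sep field separator, default tab.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(table, path, header = NULL, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(as.data.frame(table), con, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a SNP call matrix from delimited text
#'
#' Genotypes in rows (first column holds the genotype label), markers in
#' columns; the literal strings `NA` and `.` (and empty fields) are treated
#' as missing calls.
#'
#' @param path file path.
#' @param sep field separator, default tab.
#' @return Character matrix of calls with genotype row names.
#' @export
read_snp_matrix <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE,
                          row.names = 1L, na.strings = c("NA", ".", ""))
  m <- as.matrix(df)
  mode(m) <- "character"
  m
}

# Small deterministic config digest (polynomial rolling hash over the
# deparsed object); identifies a run in output headers without external
# dependencies.
config_digest <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

run_header <- function(seed, digest) {
  c(paste0("droughtsel ",
           as.character(utils::packageVersion("droughtsel"))),
    paste0("seed=", seed),
    paste0("config=", digest))
}

write_tsv_with_header <- function(df, path, header,
                                  row_names = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = row_names,
                     col.names = if (row_names) NA else TRUE)
  invisible(path)
}

#' Run the full screening pipeline on a panel
#'
#' Orchestrates the analysis end to end: per-trait RCBD ANOVA with variance
#' components and heritability; per-plot TI/RI/DTI index traits (linear
#' indices commute with averaging, so entry means of the plot-level index
#' equal the index of entry means); Spearman phenotypic and mean-product
#' genotypic correlation matrices over the nine screening columns;
#' multi-trait top-k selection; DTI categorization; optional physiological
#' change contrasts on a two-treatment table; optional simple-matching
#' distance and UPGMA dendrogram for the selected genotypes. The run is
#' deterministic given identical inputs and configuration.
#'
#' @param table a balanced single-treatment [phenotype_table()] carrying
#'   the six screening traits `SL`, `S_LW`, `DTW`, `DTR`, `RB`, `DSR`.
#' @param weights `"printed"` or `"estimate"` index coefficients.
#' @param k,m,require_dti selection rule (see [multi_trait_select()]).
#' @param alpha significance level for LSDs.
#' @param cutpoints optional DTI category cutpoints (default tertiles).
#' @param physiology optional two-treatment [phenotype_table()].
#' @param snp optional SNP call matrix for the selected genotypes (row
#'   names must cover them).
#' @param linkage clustering linkage for the dendrogram.
#' @param seed integer seed recorded in output headers (the analysis itself
#'   is deterministic).
#' @param out_dir optional directory; when given, every stage writes a
#'   delimited text file with a header carrying package version, seed and
#'   config digest.
#' @return A list of class `drought_run` with elements `anova`
#'   (per-trait data frame), `components`, `means` (entry means including
#'   index columns), `phenotypic`, `genotypic` (correlation matrices),
#'   `indices`, `selection`, `categories`, `physiology`, `distance`,
#'   `tree`, `newick`, `warnings`, `digest`, `seed`.
#' @export
run_pipeline <- function(table,
                         weights = c("printed", "estimate"),
                         k = 20, m = 5, require_dti = TRUE,
                         alpha = 0.05, cutpoints = NULL,
                         physiology = NULL, snp = NULL,
                         linkage = "average",
                         seed = 1L, out_dir = NULL) {
  weights <- match.arg(weights)
  base_traits <- c("SL", "S_LW", "DTW", "DTR", "RB", "DSR")
  missing_tr <- setdiff(base_traits, unique(table$trait))
  if (length(missing_tr) > 0L) {
    stop("pipeline stage 'input': missing trait(s) ",
         paste(missing_tr, collapse = ", "))
  }
  cfg <- list(weights = weights, k = k, m = m, require_dti = require_dti,
              alpha = alpha, cutpoints = cutpoints, linkage = linkage,
              seed = seed)
  digest <- config_digest(cfg)
  collected <- character(0)
  note <- function(w) collected <<- c(collected, w)
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      note(paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # indices at plot level so ANOVA and genotypic correlations cover them
  means6 <- stage("entry_means", genotype_means(table))
  idx <- stage("indices",
               index_scores(means6, weights = weights, table = table))
  wide <- stats::reshape(as.data.frame(table),
                         idvar = c("genotype", "replication"),
                         timevar = "trait", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  ti_plot <- linear_index(wide[base_traits], attr(idx, "weights_ti"))
  ri_plot <- linear_index(wide[base_traits], attr(idx, "weights_ri"))
  dti_plot <- dti(ti_plot, ri_plot, attr(idx, "sd_ti"), attr(idx, "sd_ri"))
  aug <- rbind(
    as.data.frame(table)[c("genotype", "replication", "trait", "value")],
    data.frame(genotype = rep(wide$genotype, 3L),
               replication = rep(wide$replication, 3L),
               trait = rep(c("TI", "RI", "DTI"), each = nrow(wide)),
               value = c(ti_plot, ri_plot, dti_plot),
               stringsAsFactors = FALSE))
  aug <- phenotype_table(aug)
  all_traits <- c(base_traits, "TI", "RI", "DTI")

  fits <- stage("anova",
                lapply(all_traits, function(tr) rcbd_anova(aug, tr)))
  comps <- stage("components",
                 lapply(fits, variance_components, alpha = alpha))
  anova_df <- do.call(rbind, lapply(fits, function(f) {
    data.frame(trait = f$trait, df_g = f$df[["genotypes"]],
               ms_g = f$ms[["genotypes"]], ms_e = f$ms[["error"]],
               f = f$f[["genotypes"]], p = f$p[["genotypes"]],
               sig = significance_mark(f$p[["genotypes"]]),
               stringsAsFactors = FALSE)
  }))
  comp_df <- do.call(rbind, lapply(comps, function(cm) {
    data.frame(trait = cm$trait, sigma2_G = cm$sigma2_G,
               sigma2_GR = cm$sigma2_GR, H2 = cm$H2, LSD = cm$LSD,
               negative_component = cm$negative_component,
               stringsAsFactors = FALSE)
  }))

  means <- stage("entry_means", genotype_means(aug))[, all_traits]
  pheno_cor <- stage("phenotypic_correlation", spearman_matrix(means))
  geno_cor <- stage("genotypic_correlation",
                    genotypic_matrix(aug, all_traits))
  if (any(abs(geno_cor$r) > 1, na.rm = TRUE)) {
    note("genotypic_correlation: coefficient(s) outside [-1, 1]")
  }
  sel <- stage("selection",
               multi_trait_select(means, k = k, m = m,
                                  require_dti = require_dti))
  if (length(attr(sel, "tie_inflation")) > 0L) {
    note(paste0("selection: ties inflated k for ",
                paste(attr(sel, "tie_inflation"), collapse = ", ")))
  }
  cats <- stage("categorize",
                categorize_dti(stats::setNames(idx$DTI, idx$genotype),
                               cutpoints))

  physio <- NULL
  if (!is.null(physiology)) {
    selected_ids <- sel$genotype[sel$selected]
    ranked_dti <- names(sort(stats::setNames(idx$DTI, idx$genotype)))
    n_grp <- min(10L, floor(length(ranked_dti) / 2))
    physio <- stage("physiology", {
      pop <- population_change(physiology)
      grp <- group_contrast(physiology,
                            utils::head(ranked_dti, n_grp),
                            utils::tail(ranked_dti, n_grp))
      rbind(cbind(group = "population", pop, stringsAsFactors = FALSE),
            grp)
    })
  }

  dist_m <- tree <- newick <- NULL
  if (!is.null(snp)) {
    sel_ids <- sel$genotype[sel$selected]
    snp_use <- if (all(sel_ids %in% rownames(snp)) && length(sel_ids) >= 2) {
      snp[sel_ids, , drop = FALSE]
    } else snp
    dist_m <- stage("distance", simple_matching_distance(snp_use))
    tree <- stage("dendrogram", upgma(dist_m, linkage = linkage))
    newick <- write_newick(tree)
  }

  out <- structure(list(anova = anova_df, components = comp_df,
                        means = means, phenotypic = pheno_cor,
                        genotypic = geno_cor, indices = idx,
                        selection = sel, categories = cats,
                        physiology = physio, distance = dist_m,
                        tree = tree, newick = newick,
                        warnings = collected, digest = digest,
                        seed = seed),
                   class = "drought_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

# Serialise every stage of a pipeline run as delimited text with headers.
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hd <- run_header(run$seed, run$digest)
  w <- function(df, name, row_names = FALSE) {
    write_tsv_with_header(df, file.path(out_dir, name), hd, row_names)
  }
  w(run$anova, "anova.tsv")
  w(run$components, "components.tsv")
  w(round(run$means, 6), "entry_means.tsv", row_names = TRUE)
  w(round(run$phenotypic$r, 4), "correlation_phenotypic.tsv",
    row_names = TRUE)
  w(round(run$genotypic$r, 4), "correlation_genotypic.tsv",
    row_names = TRUE)
  w(as.data.frame(run$indices), "indices.tsv")
  w(as.data.frame(run$selection), "selection.tsv")
  w(data.frame(genotype = names(run$categories$category),
               category = as.character(run$categories$category)),
    "dti_categories.tsv")
  if (!is.null(run$physiology)) w(run$physiology, "physiology.tsv")
  if (!is.null(run$distance)) {
    w(round(as.matrix(run$distance), 6), "distance.tsv", row_names = TRUE)
  }
  if (!is.null(run$newick)) {
    writeLines(c(paste0("# ", hd), run$newick),
               file.path(out_dir, "dendrogram.nwk"))
  }
  summary_lines <- c(
    paste0("selected=", paste(run$selection$genotype[run$selection$selected],
                              collapse = ",")),
    paste0("n_selected=", sum(run$selection$selected)),
    paste0("categories=",
           paste(names(run$categories$counts),
                 as.integer(run$categories$counts),
                 sep = ":", collapse = ",")),
    paste0("warnings=", length(run$warnings)),
    run$warnings
  )
  writeLines(c(paste0("# ", hd), summary_lines),
             file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' @export
print.drought_run <- function(x, ...) {
  cat("Seedling drought screening run (digest ", x$digest, ", seed ",
      x$seed, ")\n", sep = "")
  cat("  genotypes:", nrow(x$means), " traits:", ncol(x$means), "\n")
  cat("  selected:", sum(x$selection$selected), "genotypes;",
      "DTI categories:",
      paste(names(x$categories$counts), as.integer(x$categories$counts),
            sep = ":", collapse = ", "), "\n")
  if (length(x$warnings) > 0L) {
    cat("  warnings:", length(x$warnings), "\n")
  }
  invisible(x)
}
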