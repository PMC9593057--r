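#' Trait metadata for the standard seedling drought screen
#'
#' Direction of tolerance and valid range for the morphological traits and
#' selection indices scored in a seedling drought screen. Direction `"low"`
#' means low values indicate tolerance (seedling length, summed leaf wilting,
#' days to regrowth and the three selection indices); `"high"` means high
#' values indicate tolerance (days to wilting, survival rate, regrowth
#' biomass).
#'
#' @return A data frame with columns `trait`, `direction` (`"low"` or
#'   `"high"`), `min`, `max`.
#' @export
#' @examples
#' wheat_trait_metadata()
wheat_trait_metadata <- function() {
  data.frame(
    trait = c("SL", "S_LW", "DTW", "DTR", "RB", "DSR", "TI", "RI", "DTI"),
    direction = c("low", "low", "high", "low", "high", "high",
                  "low", "low", "low"),
    min = c(0, 5, 0, 0, 0, 0, -Inf, -Inf, -Inf),
    max = c(Inf, 45, Inf, 90, Inf, 100, Inf, Inf, Inf),
    stringsAsFactors = FALSE
  )
}

#' Construct a replicated phenotype table
#'
#' The unit of every downstream analysis: one numeric observation per
#' (genotype, replication, optional treatment, trait) key. Keys must be
#' unique; values are checked against trait ranges when metadata is supplied.
#'
#' @param data data frame with columns `genotype`, `replication`, `trait`,
#'   `value`, and optionally `treatment` (levels `control`/`drought`).
#' @param trait_meta optional data frame with columns `trait`, `direction`,
#'   `min`, `max` (see [wheat_trait_metadata()]). Traits absent from the
#'   metadata are accepted with unrestricted range.
#' @return The validated data frame with class `phenotype_table` and the
#'   metadata stored in `attr(, "trait_meta")`.
#' @export
phenotype_table <- function(data, trait_meta = NULL) {
  required <- c("genotype", "replication", "trait", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("phenotype table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$genotype <- as.character(data$genotype)
  data$replication <- as.character(data$replication)
  data$trait <- as.character(data$trait)
  data$value <- as.numeric(data$value)
  if ("treatment" %in% names(data)) {
    data$treatment <- as.character(data$treatment)
    bad <- setdiff(unique(data$treatment), c("control", "drought"))
    if (length(bad) > 0L) {
      stop("treatment levels must be 'control'/'drought'; found: ",
           paste(bad, collapse = ", "))
    }
  }
  key_cols <- intersect(c("genotype", "replication", "treatment", "trait"),
                        names(data))
  key <- do.call(paste, c(data[key_cols], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (",
         paste(key_cols, collapse = ", "),
         ") key: ", gsub("\r", " / ", dup))
  }
  if (!is.null(trait_meta)) {
    for (i in seq_len(nrow(trait_meta))) {
      tr <- trait_meta$trait[i]
      v <- data$value[data$trait == tr]
      out <- which(v < trait_meta$min[i] | v > trait_meta$max[i])
      if (length(out) > 0L) {
        stop("trait ", tr, ": ", length(out), " value(s) outside [",
             trait_meta$min[i], ", ", trait_meta$max[i], "], e.g. ",
             v[out[1L]])
      }
    }
  }
  structure(data,
            trait_meta = trait_meta,
            class = c("phenotype_table", "data.frame"))
}

#' Check that a phenotype table is balanced
#'
#' A table is balanced when every genotype is observed in every replication
#' (and every treatment, if present) for every trait it carries.
#'
#' @param table a [phenotype_table()].
#' @return `TRUE` invisibly if balanced, otherwise an error listing the
#'   offending keys.
#' @export
check_balanced <- function(table) {
  has_trt <- "treatment" %in% names(table)
  for (tr in unique(table$trait)) {
    sub <- table[table$trait == tr, , drop = FALSE]
    cells <- if (has_trt) {
      table(sub$genotype, sub$replication, sub$treatment)
    } else {
      table(sub$genotype, sub$replication)
    }
    if (any(cells != 1L)) {
      bad <- which(cells != 1L, arr.ind = TRUE)
      lbl <- apply(bad, 1L, function(idx) {
        paste(mapply(function(d, i) dimnames(cells)[[d]][i],
                     seq_along(idx), idx), collapse = "/")
      })
      stop("trait ", tr, " is unbalanced at: ",
           paste(utils::head(lbl, 5L), collapse = ", "),
           if (length(lbl) > 5L) " ..." else "")
    }
  }
  invisible(TRUE)
}

#' Sum the five leaf-wilting scores into one trait
#'
#' Visual leaf-wilting is scored on an ordinal 1 (no wilting) to 9 (fully
#' wilted) scale on five dates during the stress period; the sum condenses
#' the wilting trajectory into one trait ranging from 5 (no wilting) to 45
#' (fully wilted). Lower values indicate tolerance.
#'
#' @param scores integer vector of exactly 5 scores, each in 1..9.
#' @return The integer sum, in 5..45.
#' @export
#' @examples
#' sum_leaf_wilting(c(1, 2, 4, 6, 8))  # 21
sum_leaf_wilting <- function(scores) {
  if (length(scores) != 5L) {
    stop("exactly 5 leaf-wilting scores are required, got ", length(scores))
  }
  if (anyNA(scores) || any(scores < 1 | scores > 9) ||
      any(scores != round(scores))) {
    stop("leaf-wilting scores must be integers in 1..9")
  }
  as.integer(sum(scores))
}

#' Days to wilting of a genotype from per-plant onsets
#'
#' The smallest day on which the cumulative fraction of wilted plants reaches
#' the threshold (default 50%). Plants that never wilted during the stress
#' window enter the denominator as censored (`NA` onset). Higher values
#' indicate tolerance.
#'
#' @param onsets numeric vector of per-plant wilt-onset days; `NA` marks a
#'   plant that never wilted.
#' @param threshold cumulative wilted fraction defining the event, in (0, 1].
#' @param censor_day if not `NULL` and the threshold is never reached, return
#'   this day (the length of the stress window) instead of `NA`.
#' @return The day, or `NA` (with a warning) if the threshold is never
#'   reached and `censor_day` is `NULL`.
#' @export
#' @examples
#' days_to_wilting(c(3, 3, 5, 9))  # 3: two of four plants wilted by day 3
days_to_wilting <- function(onsets, threshold = 0.5, censor_day = NULL) {
  if (length(onsets) < 1L) stop("at least one plant is required")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  n <- length(onsets)
  obs <- sort(onsets[!is.na(onsets)])
  if (length(obs) > 0L) {
    frac <- seq_along(obs) / n
    hit <- which(frac >= threshold)
    if (length(hit) > 0L) return(obs[hit[1L]])
  }
  if (!is.null(censor_day)) return(censor_day)
  warning("wilting threshold never reached; returning NA")
  NA_real_
}

#' Arctangent disposition-to-regrowth score
#'
#' Days to regrowth after cutting and re-watering are mapped onto a bounded
#' 0-90 degree scale: a plant that regrew after `x` days scores
#' `atan(x / mu_x)` in degrees, where `mu_x` is the mean regrowth time among
#' all plants that regrew; a plant that never regrew is lifeless and scores
#' exactly 90. Lower values indicate tolerance.
#'
#' @param x days from cutting to the first new leaf; `NA` for a plant that
#'   did not regrow.
#' @param mu_x mean regrowth days among regrowing plants (> 0). The
#'   population-wide mean keeps scores comparable across genotypes; a
#'   per-genotype mean can be passed instead.
#' @return Score in degrees: in (0, 90) for regrowers, exactly 90 otherwise.
#' @export
#' @examples
#' regrowth_disposition(NA, 6)  # 90, no regrowth
#' regrowth_disposition(6, 6)   # 45
regrowth_disposition <- function(x, mu_x) {
  if (!is.numeric(mu_x) || length(mu_x) != 1L || is.na(mu_x) || mu_x <= 0) {
    stop("mu_x must be a single positive number")
  }
  if (!is.na(x) && x <= 0) stop("regrowth days must be positive")
  if (is.na(x)) return(90)
  atan(x / mu_x) * 180 / pi
}

#' Drought survival rate
#'
#' Percentage of cut plants that survived the stress period and regrew after
#' re-watering. Higher values indicate tolerance.
#'
#' @param n_survived number of surviving plants (0..`n_cut`).
#' @param n_cut number of cut plants (>= 1).
#' @return Percentage in 0..100.
#' @export
#' @examples
#' drought_survival_rate(3, 4)  # 75
drought_survival_rate <- function(n_survived, n_cut) {
  if (n_cut < 1) stop("n_cut must be at least 1")
  if (n_survived < 0 || n_survived > n_cut) {
    stop("n_survived must lie in 0..n_cut")
  }
  100 * n_survived / n_cut
}

#' Entry means: genotype-by-trait matrix of replication means
#'
#' @param table a balanced [phenotype_table()] with a single treatment.
#' @return Numeric matrix, genotypes in rows (sorted), traits in columns.
#' @export
genotype_means <- function(table) {
  if ("treatment" %in% names(table) &&
      length(unique(table$treatment)) > 1L) {
    stop("genotype_means expects a single-treatment table; subset first")
  }
  check_balanced(table)
  genos <- sort(unique(table$genotype))
  traits <- unique(table$trait)
  m <- matrix(NA_real_, nrow = length(genos), ncol = length(traits),
              dimnames = list(genos, traits))
  agg <- stats::aggregate(value ~ genotype + trait, data = table, FUN = mean)
  m[cbind(agg$genotype, agg$trait)] <- agg$value
  m
}
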