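#' Percent change in a trait mean due to drought
#'
#' Asymmetric change metrics with the larger treatment mean as denominator:
#' when the control mean exceeds the drought mean the reduction is
#' `100 * (XC - XD) / XC`; when the drought mean is larger the increase is
#' `100 * (XD - XC) / XD`; equal means give 0 with direction `"none"`.
#'
#' @param xc control mean (> 0).
#' @param xd drought mean (> 0).
#' @param trait optional trait label carried through to the result.
#' @return A list of class `change_metric` with `trait`, `xc`, `xd`,
#'   `direction` (`"reduction"`, `"increase"` or `"none"`) and `percent`
#'   (>= 0).
#' @export
#' @examples
#' change_due_to_drought(140.68, 127.74)  # 9.2% reduction
change_due_to_drought <- function(xc, xd, trait = NA_character_) {
  if (!is.finite(xc) || xc <= 0) stop("control mean must be positive")
  if (!is.finite(xd) || xd <= 0) stop("drought mean must be positive")
  if (xc > xd) {
    direction <- "reduction"
    percent <- 100 * (xc - xd) / xc
  } else if (xd > xc) {
    direction <- "increase"
    percent <- 100 * (xd - xc) / xd
  } else {
    direction <- "none"
    percent <- 0
  }
  structure(list(trait = trait, xc = xc, xd = xd,
                 direction = direction, percent = percent),
            class = "change_metric")
}

#' @export
print.change_metric <- function(x, ...) {
  cat(if (!is.na(x$trait)) paste0(x$trait, ": ") else "",
      x$direction, " of ", round(x$percent, 2), "% (control ",
      signif(x$xc, 5), " -> drought ", signif(x$xd, 5), ")\n", sep = "")
  invisible(x)
}

# Per-trait treatment means over a set of genotypes.
treatment_means <- function(table, ids, traits) {
  sub <- table[table$genotype %in% ids & table$trait %in% traits, ,
               drop = FALSE]
  agg <- stats::aggregate(value ~ trait + treatment, data = sub, FUN = mean)
  agg
}

#' Drought-induced change per trait, population- or group-level
#'
#' Computes [change_due_to_drought()] for each trait from treatment means
#' over a genotype set: the whole panel (population-level changes) or a
#' subgroup such as the most tolerant genotypes.
#'
#' @param table a two-treatment [phenotype_table()].
#' @param traits traits to summarise; default all traits in the table.
#' @param ids genotypes to average over; default all.
#' @return A data frame with `trait`, `xc`, `xd`, `direction`, `percent`.
#' @export
population_change <- function(table, traits = unique(table$trait),
                              ids = unique(table$genotype)) {
  if (!"treatment" %in% names(table)) stop("table has no treatment column")
  agg <- treatment_means(table, ids, traits)
  out <- lapply(traits, function(tr) {
    xc <- agg$value[agg$trait == tr & agg$treatment == "control"]
    xd <- agg$value[agg$trait == tr & agg$treatment == "drought"]
    if (length(xc) != 1L || length(xd) != 1L) {
      stop("trait ", tr, " lacks a mean under one treatment")
    }
    cm <- change_due_to_drought(xc, xd, tr)
    data.frame(trait = tr, xc = xc, xd = xd,
               direction = cm$direction, percent = cm$percent,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Contrast drought-induced changes between genotype groups
#'
#' Change metrics computed on within-group trait means for each treatment,
#' typically contrasting the most tolerant against the most susceptible
#' genotypes.
#'
#' @param table a two-treatment [phenotype_table()].
#' @param tolerant_ids,susceptible_ids disjoint, non-empty genotype sets.
#' @param traits traits to summarise; default all traits in the table.
#' @return A data frame with `group`, `trait`, `xc`, `xd`, `direction`,
#'   `percent`.
#' @export
group_contrast <- function(table, tolerant_ids, susceptible_ids,
                           traits = unique(table$trait)) {
  if (length(tolerant_ids) < 1L || length(susceptible_ids) < 1L) {
    stop("both groups must contain at least one genotype")
  }
  overlap <- intersect(tolerant_ids, susceptible_ids)
  if (length(overlap) > 0L) {
    stop("groups overlap: ", paste(overlap, collapse = ", "))
  }
  missing_ids <- setdiff(c(tolerant_ids, susceptible_ids),
                         unique(table$genotype))
  if (length(missing_ids) > 0L) {
    stop("genotype(s) not in table: ", paste(missing_ids, collapse = ", "))
  }
  tol <- population_change(table, traits, tolerant_ids)
  sus <- population_change(table, traits, susceptible_ids)
  rbind(cbind(group = "tolerant", tol, stringsAsFactors = FALSE),
        cbind(group = "susceptible", sus, stringsAsFactors = FALSE))
}
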