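# Compartmentalized densities, percentages among parent populations, and
# population ratios. Per-sample statistics pool cells and areas across fields
# (total count / total area), not means of per-field values: this matches the
# count-based ratios and is robust to near-empty fields.

.count_pheno <- function(sample, phenotype, compartment) {
  cells <- sample$cells
  labels <- attr(cells, "phenotype_labels")
  if (is.null(labels)) .err("phenotypes not assigned; call assign_phenotypes() first")
  if (!phenotype %in% labels) .err("unknown phenotype label '%s'", phenotype)
  sel <- cells[[phenotype]]
  if (compartment != "both") sel <- sel & cells$compartment == compartment
  sum(sel)
}

#' Cell density (cells/mm^2)
#'
#' Pooled over all fields of the lesion: total phenotype count divided by the
#' total compartment area. An empty compartment with zero cells yields `NA`
#' (density undefined, not zero); a nonzero count over zero area is an
#' inconsistency error.
#'
#' @param sample a `lesion_sample` with phenotypes assigned.
#' @param phenotype phenotype label.
#' @param compartment `"tumor"`, `"stroma"` or `"both"`.
#' @return density in cells/mm^2 (length-1 numeric, possibly `NA`).
#' @export
cell_density <- function(sample, phenotype, compartment = c("both", "tumor", "stroma")) {
  compartment <- match.arg(compartment)
  n <- .count_pheno(sample, phenotype, compartment)
  a <- lesion_areas(sample)
  area_um2 <- if (compartment == "both") sum(a) else a[[compartment]]
  if (area_um2 <= 0) {
    if (n > 0) .err("nonzero count (%d) over zero %s area", n, compartment)
    return(NA_real_)
  }
  n / (area_um2 / 1e6)
}

#' Tidy density profile of a lesion
#'
#' One row per (phenotype, compartment) with count, area and density; the
#' quantification stage's standard tabular output.
#'
#' @param sample a `lesion_sample` with phenotypes assigned.
#' @return data.frame: `sample_id, phenotype, compartment, count, area_mm2,
#'   density`.
#' @export
density_profile <- function(sample) {
  counts <- phenotype_counts(sample)
  a <- lesion_areas(sample) / 1e6
  counts$area_mm2 <- a[counts$compartment]
  counts$density <- ifelse(counts$area_mm2 > 0, counts$count / counts$area_mm2, NA_real_)
  data.frame(sample_id = sample$sample_id, counts,
             row.names = NULL, check.names = FALSE)
}

#' Percentage of a child population among its parent population
#'
#' e.g. the share of CD8+CD103+ cells among all CD8+ cells. The child rule
#' must be a refinement of the parent rule (every parent requirement also
#' required by the child), which is validated from the attached rule set.
#'
#' @param sample a `lesion_sample` with phenotypes assigned.
#' @param child,parent phenotype labels.
#' @param compartment `"tumor"`, `"stroma"` or `"both"`.
#' @return percentage in `[0, 100]`, or `NA` when the parent count is zero.
#' @export
percentage_among_parent <- function(sample, child, parent,
                                    compartment = c("both", "tumor", "stroma")) {
  compartment <- match.arg(compartment)
  rules <- attr(sample$cells, "phenotype_rules")
  if (!is.null(rules) && child %in% names(rules) && parent %in% names(rules)) {
    rc <- rules[[child]]; rp <- rules[[parent]]
    refines <- all(rp$positive %in% rc$positive) && all(rp$negative %in% rc$negative)
    if (!refines) {
      .err("'%s' is not a refinement of '%s' (its rule does not imply the parent rule)",
           child, parent)
    }
  }
  n_child <- .count_pheno(sample, child, compartment)
  n_parent <- .count_pheno(sample, parent, compartment)
  if (n_parent == 0L) {
    .warnf("parent population '%s' empty in %s/%s; percentage reported as missing",
           parent, sample$sample_id, compartment)
    return(NA_real_)
  }
  100 * n_child / n_parent
}

#' Ratio between two cell populations
#'
#' e.g. the CD8+/FoxP3+ ratio within tumor areas.
#'
#' @inheritParams percentage_among_parent
#' @param numerator,denominator phenotype labels.
#' @return count ratio (>= 0), or `NA` when the denominator count is zero.
#' @export
population_ratio <- function(sample, numerator, denominator,
                             compartment = c("both", "tumor", "stroma")) {
  compartment <- match.arg(compartment)
  n_num <- .count_pheno(sample, numerator, compartment)
  n_den <- .count_pheno(sample, denominator, compartment)
  if (n_den == 0L) {
    .warnf("denominator population '%s' empty in %s/%s; ratio reported as missing",
           denominator, sample$sample_id, compartment)
    return(NA_real_)
  }
  n_num / n_den
}
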