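# Marker-call phenotyping and compartment assignment.

#' Phenotype rule
#'
#' A phenotype label defined by required-positive and required-negative
#' markers on one panel. A cell matches when every required-positive marker
#' call is 1 and every required-negative call is 0; labels are non-exclusive,
#' so one cell can carry CD8+, CD8+CD103+ and CD8+CD103+PD-1+ simultaneously.
#'
#' @param label phenotype label.
#' @param positive markers required positive.
#' @param negative markers required negative (disjoint from `positive`).
#' @param panel the `marker_panel` the rule applies to.
#' @return object of class `phenotype_rule`.
#' @export
phenotype_rule <- function(label, positive, negative = character(), panel) {
  stopifnot(inherits(panel, "marker_panel"))
  positive <- as.character(positive); negative <- as.character(negative)
  if (length(intersect(positive, negative))) {
    .err("rule '%s': a marker cannot be required both positive and negative", label)
  }
  unknown <- setdiff(c(positive, negative), panel$markers)
  if (length(unknown)) {
    .err("rule '%s' references marker(s) absent from panel '%s': %s",
         label, panel$name, paste(unknown, collapse = ", "))
  }
  structure(list(label = as.character(label), positive = positive,
                 negative = negative, panel = panel$name),
            class = "phenotype_rule")
}

#' Default phenotype rule sets
#'
#' The shipped rules reproducing the study's phenotype definitions. On the
#' 9-color panel: tumor cells (CK+), cytotoxic T lymphocytes (CD8+),
#' regulatory T cells (FoxP3+ CD8-), macrophages (CD68+) with the
#' M2-polarized subset (CD68+CD163+) and its M1-like complement (CD68+CD163-),
#' tissue-resident memory T cells (CD8+CD103+), the PD-1+ CTL subsets, and
#' PD-L1+ tumor/macrophage variants. On the 6-color panel: T helper cells
#' (CD4+ CK-), CTLA-4+ T cells, CD4+CTLA-4+ cells and HLA-I-negative tumor
#' cells. The Treg CD8- and Th CK- exclusions are package conventions (they
#' prevent double-counting of co-staining cells) and can be overridden by
#' supplying custom rules.
#'
#' @param panel a `marker_panel` (or panel name).
#' @return named list of `phenotype_rule` objects.
#' @export
default_phenotype_rules <- function(panel = marker_panel("9-color")) {
  if (is.character(panel)) panel <- marker_panel(panel)
  r <- function(label, pos, neg = character()) phenotype_rule(label, pos, neg, panel)
  rules <- if (panel$name == "9-color") {
    list(
      r("tumor", "CK"),
      r("CTL", "CD8"),
      r("Treg", "FoxP3", "CD8"),
      r("macrophage", "CD68"),
      r("M1-TAM", "CD68", "CD163"),
      r("M2-TAM", c("CD68", "CD163")),
      r("TRM", c("CD8", "CD103")),
      r("CD8+PD-1+", c("CD8", "PD-1")),
      r("CD8+CD103+PD-1+", c("CD8", "CD103", "PD-1")),
      r("PD-L1+ tumor", c("CK", "PD-L1")),
      r("PD-L1+ M1-TAM", c("CD68", "PD-L1"), "CD163"),
      r("PD-L1+ M2-TAM", c("CD68", "CD163", "PD-L1")),
      r("PD-L1+", "PD-L1")
    )
  } else if (panel$name == "6-color") {
    list(
      r("tumor", "CK"),
      r("CTL", "CD8"),
      r("Th", "CD4", "CK"),
      r("CTLA-4+ T", "CTLA-4"),
      r("CD4+CTLA-4+", c("CD4", "CTLA-4")),
      r("HLA-I- tumor", "CK", "HLA-I")
    )
  } else {
    .err("no default rules for panel '%s'", panel$name)
  }
  stats::setNames(rules, vapply(rules, function(x) x$label, character(1)))
}

#' Assign phenotype labels from marker calls
#'
#' Evaluates every rule on every cell and appends one logical column per
#' phenotype label. The rule list is attached as attribute
#' `phenotype_rules` and the label set as `phenotype_labels`.
#'
#' @param cells a `cell_table`.
#' @param rules list of `phenotype_rule` (default: the panel's shipped set).
#' @return `cells` with one logical column per label.
#' @examples
#' # a CD8+CD103+ cell is both a CTL and a TRM cell
#' @export
assign_phenotypes <- function(cells, rules = default_phenotype_rules(attr(cells, "panel"))) {
  panel <- attr(cells, "panel")
  if (is.null(panel)) .err("'cells' must be a cell_table with an attached panel")
  for (rule in rules) {
    unknown <- setdiff(c(rule$positive, rule$negative), panel$markers)
    if (length(unknown)) {
      .err("rule '%s' references marker(s) not in panel '%s': %s",
           rule$label, panel$name, paste(unknown, collapse = ", "))
    }
    match_pos <- rep(TRUE, nrow(cells))
    for (m in rule$positive) match_pos <- match_pos & cells[[m]] == 1L
    for (m in rule$negative) match_pos <- match_pos & cells[[m]] == 0L
    cells[[rule$label]] <- match_pos
  }
  attr(cells, "phenotype_rules") <- rules
  attr(cells, "phenotype_labels") <- vapply(rules, function(x) x$label, character(1))
  cells
}

#' Assign tumor/stroma compartments from nest geometry
#'
#' A cell is intra-tumoral iff its centroid lies inside or on the boundary of
#' any tumor-nest polygon of its field; otherwise stromal.
#'
#' @param cells a `cell_table`.
#' @param fields list of `field_geometry` (named by field_id) covering every
#'   `field_id` in `cells`.
#' @return `cells` with the `compartment` column recomputed.
#' @export
assign_compartment <- function(cells, fields) {
  ids <- vapply(fields, function(f) f$field_id, character(1))
  names(fields) <- ids
  unknown <- setdiff(unique(cells$field_id), ids)
  if (length(unknown)) {
    .err("no geometry for field_id(s): %s", paste(unknown, collapse = ", "))
  }
  comp <- cells$compartment
  for (fid in unique(cells$field_id)) {
    geom <- fields[[fid]]
    idx <- which(cells$field_id == fid)
    px <- cells$x[idx]; py <- cells$y[idx]
    out_of_field <- px < 0 | px > geom$width | py < 0 | py > geom$height
    if (any(out_of_field)) {
      .err("cell '%s' lies outside field '%s' (%g x %g um)",
           cells$cell_id[idx[which(out_of_field)[1]]], fid, geom$width, geom$height)
    }
    comp[idx] <- ifelse(point_in_nests(geom, px, py), "tumor", "stroma")
  }
  cells$compartment <- comp
  cells
}

#' Phenotype counts by compartment
#'
#' Counts of each assigned phenotype label in each compartment, summed over
#' all fields of a lesion.
#'
#' @param sample a `lesion_sample` whose cells carry phenotype columns.
#' @return data.frame with columns `phenotype`, `compartment`, `count` (all
#'   label x compartment combinations, zero-filled).
#' @export
phenotype_counts <- function(sample) {
  stopifnot(inherits(sample, "lesion_sample"))
  labels <- attr(sample$cells, "phenotype_labels")
  if (is.null(labels)) .err("phenotypes not assigned; call assign_phenotypes() first")
  comps <- c("tumor", "stroma")
  grid <- expand.grid(phenotype = labels, compartment = comps,
                      stringsAsFactors = FALSE)
  grid$count <- mapply(function(ph, cp) {
    sum(sample$cells[[ph]] & sample$cells$compartment == cp)
  }, grid$phenotype, grid$compartment)
  grid[order(match(grid$phenotype, labels), grid$compartment), , drop = FALSE]
}
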