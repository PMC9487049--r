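# Spatial proximity statistics: mean nearest-neighbor distance and the
# count-within-radius percentage. Distances are Euclidean center-to-center
# between cell coordinates, computed within each field only (cells in
# different fields are never neighbors), with no edge correction — cells near
# field borders have truncated neighborhoods, a known downward bias shared
# with the upstream imaging tools.

# Per-reference minimum distance to query cells within one field.
# ref_rows/query_rows are row indices into the same cell table, so a cell that
# is both reference and query is never its own neighbor.
.min_query_dist <- function(cells, ref_rows, query_rows, chunk = 512L) {
  nr <- length(ref_rows)
  nq <- length(query_rows)
  if (nr == 0L || nq == 0L) return(numeric(0))
  rx <- cells$x[ref_rows]; ry <- cells$y[ref_rows]
  qx <- cells$x[query_rows]; qy <- cells$y[query_rows]
  out <- numeric(nr)
  for (start in seq(1L, nr, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nr)
    d2 <- outer(rx[idx], qx, "-")^2 + outer(ry[idx], qy, "-")^2
    self <- outer(ref_rows[idx], query_rows, "==")
    if (any(self)) d2[self] <- Inf
    out[idx] <- sqrt(apply(d2, 1L, min))
  }
  out
}

.prox_rows <- function(sample, label, compartment = "both") {
  cells <- sample$cells
  labels <- attr(cells, "phenotype_labels")
  if (is.null(labels)) .err("phenotypes not assigned; call assign_phenotypes() first")
  if (!label %in% labels) .err("unknown phenotype label '%s'", label)
  sel <- cells[[label]]
  if (compartment != "both") sel <- sel & cells$compartment == compartment
  which(sel)
}

#' Mean nearest-neighbor distance between two phenotypes
#'
#' For each reference cell, the distance to the nearest query-phenotype cell
#' in the same field; the statistic is the mean over all reference cells that
#' have at least one (distinct) query cell in their field. References in
#' fields lacking any query cell are excluded from the mean (not assigned an
#' infinite distance) and counted in the `n_excluded` attribute.
#'
#' @param sample a `lesion_sample` with phenotypes assigned.
#' @param reference,query phenotype labels.
#' @param compartment compartment scope applied to the *reference* cells
#'   (`"both"`, `"tumor"`, `"stroma"`); query cells are taken from the whole
#'   field.
#' @return mean distance in um (`NA` when there are no usable reference
#'   cells), with attributes `n_reference`, `n_query`, `n_excluded`.
#' @export
nn_mean_distance <- function(sample, reference, query,
                             compartment = c("both", "tumor", "stroma")) {
  compartment <- match.arg(compartment)
  ref_rows <- .prox_rows(sample, reference, compartment)
  query_rows <- .prox_rows(sample, query, "both")
  dists <- numeric(0)
  n_excluded <- 0L
  for (fid in unique(sample$cells$field_id[ref_rows])) {
    fr <- ref_rows[sample$cells$field_id[ref_rows] == fid]
    fq <- query_rows[sample$cells$field_id[query_rows] == fid]
    fq_usable <- fq  # self-pairs removed per reference inside .min_query_dist
    only_self <- length(fq_usable) == 0L ||
      (length(fq_usable) == 1L && length(fr) == 1L && fq_usable == fr)
    if (only_self) {
      n_excluded <- n_excluded + length(fr)
      next
    }
    d <- .min_query_dist(sample$cells, fr, fq_usable)
    usable <- is.finite(d)
    n_excluded <- n_excluded + sum(!usable)
    dists <- c(dists, d[usable])
  }
  val <- if (length(dists)) mean(dists) else NA_real_
  structure(val, n_reference = length(ref_rows), n_query = length(query_rows),
            n_excluded = n_excluded)
}

#' Count-within-radius percentage
#'
#' Percentage of reference cells, among all reference cells, that have at
#' least one query-phenotype cell within `radius` um in the same field
#' (boundary inclusive: a query cell at exactly `radius` counts).
#'
#' @inheritParams nn_mean_distance
#' @param radius radius in um (default 20).
#' @return percentage in `[0, 100]` (`NA` when there are no reference cells),
#'   with attributes `n_reference` and `n_query`.
#' @export
pct_within_radius <- function(sample, reference, query, radius = 20,
                              compartment = c("both", "tumor", "stroma")) {
  compartment <- match.arg(compartment)
  if (radius <= 0) .err("radius must be > 0")
  ref_rows <- .prox_rows(sample, reference, compartment)
  query_rows <- .prox_rows(sample, query, "both")
  if (length(ref_rows) == 0L) {
    return(structure(NA_real_, n_reference = 0L, n_query = length(query_rows)))
  }
  n_hit <- 0L
  for (fid in unique(sample$cells$field_id[ref_rows])) {
    fr <- ref_rows[sample$cells$field_id[ref_rows] == fid]
    fq <- query_rows[sample$cells$field_id[query_rows] == fid]
    if (length(fq) == 0L) next
    d <- .min_query_dist(sample$cells, fr, fq)
    n_hit <- n_hit + sum(d <= radius)
  }
  structure(100 * n_hit / length(ref_rows),
            n_reference = length(ref_rows), n_query = length(query_rows))
}

#' Default proximity pair list
#'
#' The shipped (reference, query, compartment) pairs reproducing the study's
#' figure panels on the 9-color phenotypes: tumor cells against the CD8+
#' subsets, and CD163+ macrophages / Treg cells against CD8+ T lymphocytes by
#' compartment, plus the PD-L1+/PD-1+ checkpoint pairs.
#'
#' @return data.frame with columns `reference`, `query`, `compartment`.
#' @export
default_proximity_pairs <- function() {
  rbind(
    data.frame(reference = "tumor",
               query = c("CTL", "TRM", "CD8+PD-1+"),
               compartment = "both", stringsAsFactors = FALSE),
    expand.grid(reference = c("M2-TAM", "Treg"), query = "CTL",
                compartment = c("tumor", "stroma"),
                stringsAsFactors = FALSE),
    data.frame(reference = "PD-L1+ tumor", query = "CD8+PD-1+",
               compartment = "both", stringsAsFactors = FALSE),
    expand.grid(reference = c("PD-L1+ M1-TAM", "PD-L1+ M2-TAM"),
                query = "CD8+PD-1+", compartment = c("tumor", "stroma"),
                stringsAsFactors = FALSE)
  )
}

#' Proximity panel
#'
#' Both proximity statistics for every requested (reference, query,
#' compartment) pair of one lesion. Reference and query roles are not
#' symmetric: "share of tumor cells near a CTL" generally differs from
#' "share of CTLs near a tumor cell".
#'
#' @param sample a `lesion_sample` with phenotypes assigned.
#' @param pairs data.frame with columns `reference`, `query`, `compartment`
#'   (default [default_proximity_pairs()]).
#' @param config an [analysis_config()]; supplies the radius.
#' @return tidy data.frame, one row per pair x statistic.
#' @export
proximity_panel <- function(sample, pairs = default_proximity_pairs(),
                            config = analysis_config()) {
  labels <- attr(sample$cells, "phenotype_labels")
  unknown <- setdiff(unique(c(pairs$reference, pairs$query)), labels)
  if (length(unknown)) {
    .err("proximity pair list references unknown phenotype label(s): %s",
         paste(unknown, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ref <- pairs$reference[i]; qry <- pairs$query[i]; comp <- pairs$compartment[i]
    nn <- nn_mean_distance(sample, ref, qry, comp)
    pct <- pct_within_radius(sample, ref, qry, config$proximity_radius, comp)
    data.frame(
      sample_id = sample$sample_id, reference = ref, query = qry,
      compartment = comp,
      statistic = c("nn_mean_distance_um", "pct_within_radius"),
      radius_um = c(NA_real_, config$proximity_radius),
      value = c(as.numeric(nn), as.numeric(pct)),
      n_reference = attr(nn, "n_reference"),
      n_query = attr(nn, "n_query"),
      n_excluded = c(attr(nn, "n_excluded"), NA_integer_),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
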