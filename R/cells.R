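# Segmented cell tables and lesion samples.
#
# A cell table is a data.frame with one row per segmented cell:
#   cell_id, field_id, x, y (um), compartment ("tumor"/"stroma"), and one
#   integer 0/1 column per panel marker. The on-disk dialect is comma-separated
#   UTF-8 with "." decimals and columns cell_id, field_id, x_um, y_um,
#   compartment, <markers...>.

.CELL_META_COLS <- c("cell_id", "field_id", "x", "y", "compartment")

#' Construct / validate a cell table
#'
#' @param cells data.frame with columns `cell_id`, `field_id`, `x`, `y`,
#'   `compartment`, and one 0/1 (or logical) column per panel marker.
#' @param panel the `marker_panel` whose calls the table carries.
#' @return the validated data.frame, class `cell_table`, with the panel
#'   attached as attribute `panel`.
#' @export
cell_table <- function(cells, panel) {
  stopifnot(inherits(panel, "marker_panel"))
  cells <- as.data.frame(cells, check.names = FALSE)
  missing_cols <- setdiff(c(.CELL_META_COLS, panel$markers), names(cells))
  if (length(missing_cols)) {
    .err("cell table is missing required column(s): %s",
         paste(missing_cols, collapse = ", "))
  }
  for (cc in c("x", "y")) {
    v <- cells[[cc]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v < 0)) {
      bad <- which(!is.numeric(v) | is.na(v) | !is.finite(v) | v < 0)[1]
      .err("column '%s' must be finite and >= 0 (first offending row: %d)", cc, bad)
    }
  }
  if (!all(cells$compartment %in% c("tumor", "stroma"))) {
    bad <- which(!cells$compartment %in% c("tumor", "stroma"))[1]
    .err("compartment must be 'tumor' or 'stroma' (row %d has '%s')",
         bad, cells$compartment[bad])
  }
  for (m in panel$markers) {
    v <- cells[[m]]
    if (is.logical(v)) v <- as.integer(v)
    if (!is.numeric(v) || anyNA(v) || !all(v %in% c(0, 1))) {
      bad <- which(is.na(v) | !(v %in% c(0, 1)))[1]
      .err("marker column '%s' must be 0/1 (row %d)", m, bad)
    }
    cells[[m]] <- as.integer(v)
  }
  cells$cell_id <- as.character(cells$cell_id)
  cells$field_id <- as.character(cells$field_id)
  attr(cells, "panel") <- panel
  class(cells) <- unique(c("cell_table", class(cells)))
  cells
}

#' Read a segmented cell table
#'
#' Reads the package's canonical CSV dialect (comma-separated, header row,
#' columns `cell_id, field_id, x_um, y_um, compartment` plus one 0/1 column
#' per panel marker). Unknown extra columns are kept but flagged with a
#' warning; missing required columns and malformed values are errors.
#'
#' @param path file path.
#' @param panel `marker_panel` declaring the expected marker columns.
#' @return a `cell_table` (row order preserved).
#' @export
read_cell_table <- function(path, panel) {
  if (!file.exists(path)) .err("cell table file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("cell_id", "field_id", "x_um", "y_um", "compartment", panel$markers)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    .err("cell table '%s' is missing required column(s): %s",
         basename(path), paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    .warnf("ignoring unknown column(s) in '%s': %s",
           basename(path), paste(extra, collapse = ", "))
  }
  for (cc in c("x_um", "y_um")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v)) {
      .err("non-numeric coordinate in column '%s' of '%s' (row %d)",
           cc, basename(path), which(is.na(v))[1])
    }
    df[[cc]] <- v
  }
  for (m in panel$markers) {
    v <- suppressWarnings(as.numeric(df[[m]]))
    if (anyNA(v) || !all(v %in% c(0, 1))) {
      .err("marker column '%s' of '%s' has values outside {0,1}", m, basename(path))
    }
  }
  out <- df[required]
  names(out)[names(out) == "x_um"] <- "x"
  names(out)[names(out) == "y_um"] <- "y"
  cell_table(out, panel)
}

#' Write a segmented cell table
#'
#' Emits the dialect [read_cell_table()] accepts; `read(write(x))` is the
#' identity on the canonical fields. Column order is fixed, so output is
#' byte-stable for a given table.
#'
#' @param cells a `cell_table` (or data.frame with the canonical columns).
#' @param panel the `marker_panel`; defaults to the table's own.
#' @param path output file path.
#' @export
write_cell_table <- function(cells, panel = attr(cells, "panel"), path) {
  if (is.null(panel)) .err("no panel supplied and none attached to 'cells'")
  missing_cols <- setdiff(panel$markers, names(cells))
  if (length(missing_cols)) {
    .err("cells lack call column(s) for panel marker(s): %s",
         paste(missing_cols, collapse = ", "))
  }
  out <- as.data.frame(cells, check.names = FALSE)[
    , c(.CELL_META_COLS, panel$markers), drop = FALSE]
  names(out)[names(out) == "x"] <- "x_um"
  names(out)[names(out) == "y"] <- "y_um"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Lesion sample
#'
#' One lesion (primary tumor or lymph-node metastasis) of one patient: a set
#' of imaged fields with their nest geometry, plus the pooled cell table.
#'
#' @param sample_id,patient_id identifiers.
#' @param lesion_type `"primary"` or `"metastasis"`.
#' @param fields list of `field_geometry` objects (>= 1).
#' @param cells a `cell_table`; every `field_id` must match a field.
#' @return object of class `lesion_sample`.
#' @export
lesion_sample <- function(sample_id, patient_id, lesion_type, fields, cells) {
  lesion_type <- match.arg(lesion_type, c("primary", "metastasis"))
  if (length(fields) < 1L) .err("a lesion sample needs at least one field")
  ids <- vapply(fields, function(f) f$field_id, character(1))
  if (anyDuplicated(ids)) .err("duplicate field_id in lesion fields")
  names(fields) <- ids
  unknown <- setdiff(unique(cells$field_id), ids)
  if (length(unknown)) {
    .err("cells reference unknown field_id(s): %s", paste(unknown, collapse = ", "))
  }
  structure(
    list(sample_id = as.character(sample_id),
         patient_id = as.character(patient_id),
         lesion_type = lesion_type, fields = fields, cells = cells),
    class = "lesion_sample"
  )
}

#' @export
print.lesion_sample <- function(x, ...) {
  cat(sprintf("<lesion_sample> %s (patient %s, %s): %d field(s), %d cell(s)\n",
              x$sample_id, x$patient_id, x$lesion_type,
              length(x$fields), nrow(x$cells)))
  labs <- attr(x$cells, "phenotype_labels")
  if (!is.null(labs)) cat("  phenotypes:", paste(labs, collapse = ", "), "\n")
  invisible(x)
}

#' Total compartment areas of a lesion (summed over fields)
#'
#' @param sample a `lesion_sample`.
#' @return named numeric `c(tumor=, stroma=)` in um^2.
#' @export
lesion_areas <- function(sample) {
  stopifnot(inherits(sample, "lesion_sample"))
  a <- vapply(sample$fields, compartment_areas, numeric(2))
  c(tumor = sum(a["tumor", ]), stroma = sum(a["stroma", ]))
}
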