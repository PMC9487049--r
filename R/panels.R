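#' Marker panels
#'
#' The two multiplex-immunofluorescence panels used throughout the package: a
#' 9-color panel (macrophage/CTL/Treg/checkpoint markers plus pan-cytokeratin)
#' and a 6-color panel (CTLA-4, CD4, CD8, HLA class I, pan-cytokeratin).
#' DAPI nuclear counterstain is upstream of segmentation and carries no call,
#' so it is not part of a panel. Custom panels may be declared by passing
#' `markers` explicitly.
#'
#' @param name panel name; `"9-color"` and `"6-color"` ship with their
#'   standard marker sets.
#' @param markers optional character vector of marker names (unique); required
#'   when `name` is not one of the shipped panels.
#' @return An object of class `marker_panel` with fields `name` and `markers`.
#' @examples
#' marker_panel("9-color")
#' @export
marker_panel <- function(name, markers = NULL) {
  shipped <- list(
    "9-color" = c("CD68", "CD8", "FoxP3", "CD163", "CD103", "PD-1", "PD-L1", "CK"),
    "6-color" = c("CTLA-4", "CD4", "CD8", "HLA-I", "CK")
  )
  if (is.null(markers)) {
    if (!name %in% names(shipped)) {
      .err("unknown panel '%s'; supply 'markers' for a custom panel", name)
    }
    markers <- shipped[[name]]
  }
  markers <- as.character(markers)
  if (anyDuplicated(markers)) .err("marker names must be unique within a panel")
  if (length(markers) == 0L) .err("a panel needs at least one marker")
  structure(list(name = name, markers = markers), class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> %s: %s\n", x$name, paste(x$markers, collapse = ", ")))
  invisible(x)
}

#' @rdname marker_panel
#' @param panel a `marker_panel`.
#' @export
panel_markers <- function(panel) {
  stopifnot(inherits(panel, "marker_panel"))
  panel$markers
}
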