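# Expression matrices, signature sets, and analysis configuration.

#' Expression matrix container
#'
#' Genes x samples values from an immune expression panel, with the
#' housekeeping genes flagged and the processing scale tracked
#' (`raw_counts` -> `normalized` -> `log2`).
#'
#' @param values numeric matrix, genes in rows (rownames = gene names),
#'   samples in columns (colnames = sample IDs).
#' @param housekeeping character vector of housekeeping gene names (subset of
#'   rownames).
#' @param scale one of `"raw_counts"`, `"normalized"`, `"log2"`.
#' @return object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, housekeeping, scale = c("raw_counts", "normalized", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    .err("expression values need gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    .err("duplicate gene name(s): %s",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  missing_hk <- setdiff(housekeeping, rownames(values))
  if (length(missing_hk)) {
    .err("housekeeping gene(s) absent from matrix: %s", paste(missing_hk, collapse = ", "))
  }
  if (scale == "raw_counts" && any(values < 0)) .err("raw counts must be non-negative")
  structure(list(values = values, housekeeping = as.character(housekeeping),
                 scale = scale),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples (%d housekeeping), scale = %s\n",
              nrow(x$values), ncol(x$values), length(x$housekeeping), x$scale))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read a raw expression matrix with its housekeeping-gene list
#'
#' @param path delimited text (comma- or tab-separated inferred from the
#'   extension: .tsv/.txt are tab), first column gene names, remaining columns
#'   one per sample.
#' @param housekeeping_path plain-text file, one housekeeping gene per line.
#' @return an `expr_matrix` with `scale = "raw_counts"`.
#' @export
read_expression_matrix <- function(path, housekeeping_path) {
  if (!file.exists(path)) .err("expression file not found: %s", path)
  if (!file.exists(housekeeping_path)) .err("housekeeping file not found: %s", housekeeping_path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    .err("duplicate gene name(s) in '%s': %s", basename(path),
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) .err("non-numeric expression values in '%s'", basename(path))
  if (any(m < 0)) .err("negative count(s) in '%s'", basename(path))
  rownames(m) <- genes
  hk <- readLines(housekeeping_path, warn = FALSE)
  hk <- hk[nzchar(trimws(hk))]
  expr_matrix(m, trimws(hk), scale = "raw_counts")
}

#' Write an expression matrix (and optionally its housekeeping list)
#'
#' @param em an `expr_matrix`.
#' @param path output path (.csv comma, .tsv tab).
#' @param housekeeping_path optional path for the one-gene-per-line list.
#' @export
write_expression_matrix <- function(em, path, housekeeping_path = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(gene = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  if (!is.null(housekeeping_path)) writeLines(em$housekeeping, housekeeping_path)
  invisible(path)
}

#' Signature set
#'
#' A named gene list used for cell-type or pathway scoring.
#'
#' @param name signature name.
#' @param kind `"cell_type"` or `"pathway"`.
#' @param genes non-empty character vector of member genes.
#' @return object of class `signature_set`.
#' @export
signature_set <- function(name, kind = c("cell_type", "pathway"), genes) {
  kind <- match.arg(kind)
  genes <- as.character(genes)
  if (length(genes) == 0L) .err("signature '%s' has an empty gene list", name)
  structure(list(name = as.character(name), kind = kind, genes = genes),
            class = "signature_set")
}

#' Read signature sets (YAML or CSV)
#'
#' YAML layout: a mapping `name -> {kind: ..., genes: [...]}`. CSV layout:
#' columns `name, kind, genes` with genes comma-joined inside the cell.
#'
#' @param path file path.
#' @return named list of `signature_set` objects.
#' @export
read_signature_sets <- function(path) {
  if (!file.exists(path)) .err("signature file not found: %s", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    sets <- lapply(names(raw), function(nm) {
      signature_set(nm, raw[[nm]]$kind %||% "cell_type",
                    unlist(raw[[nm]]$genes))
    })
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    sets <- lapply(seq_len(nrow(df)), function(i) {
      signature_set(df$name[i], df$kind[i],
                    trimws(strsplit(df$genes[i], ",")[[1]]))
    })
  }
  nms <- vapply(sets, function(s) s$name, character(1))
  if (anyDuplicated(nms)) .err("duplicate signature name(s) in '%s'", basename(path))
  stats::setNames(sets, nms)
}

#' Analysis configuration
#'
#' Bundles the tunable thresholds used across the pipeline: the proximity
#' radius (um), the tie rule for median dichotomization, and the DEG-calling
#' thresholds.
#'
#' @param proximity_radius count-within radius in um (default 20).
#' @param median_tie_rule currently only `"le_median_is_low"` (values equal to
#'   the median go to the low group).
#' @param deg_log2fc_threshold absolute log2 fold-change cut for DEG calls.
#' @param deg_alpha BH-adjusted p-value cut for DEG calls.
#' @param rng_seed optional integer seed recorded with the run.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(proximity_radius = 20,
                            median_tie_rule = "le_median_is_low",
                            deg_log2fc_threshold = 1,
                            deg_alpha = 0.05,
                            rng_seed = NULL) {
  if (proximity_radius <= 0) .err("proximity_radius must be > 0")
  if (deg_alpha <= 0 || deg_alpha >= 1) .err("deg_alpha must lie in (0, 1)")
  median_tie_rule <- match.arg(median_tie_rule, "le_median_is_low")
  structure(list(proximity_radius = proximity_radius,
                 median_tie_rule = median_tie_rule,
                 deg_log2fc_threshold = deg_log2fc_threshold,
                 deg_alpha = deg_alpha,
                 rng_seed = rng_seed),
            class = "analysis_config")
}
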