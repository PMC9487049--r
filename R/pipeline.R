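# End-to-end orchestration: simulate (or ingest) -> phenotype -> quantify ->
# proximity -> expression profiling -> group comparison -> survival screen,
# with a run manifest recording config, seeds, file digests, row counts and
# warnings. A single master seed fans out to per-stage child seeds (see
# derive_seeds), so each stage is individually reproducible.

.pipe_write <- function(df, dir, name, manifest) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  manifest$files[[name]] <- list(md5 = unname(tools::md5sum(path)), rows = nrow(df))
  manifest
}

#' Run the full analysis pipeline
#'
#' With `simulate = TRUE` (the default), generates a seeded synthetic cohort
#' at the configured study sizes and runs every downstream stage, writing
#' tidy CSV outputs and a JSON manifest into `out_dir`. With
#' `simulate = FALSE`, ingests `patients.csv` (patient_id, hpv_status, sex,
#' dfs_time, dfs_event), `expression.csv` and `housekeeping.txt` from
#' `input_dir`; spatial stages then require per-sample cell tables under
#' `cells/` plus a `geometry.json` nest-polygon file and are skipped (with a
#' manifest note) when absent.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed.
#' @param simulate generate the cohort (`TRUE`) or ingest `input_dir`.
#' @param input_dir input directory for `simulate = FALSE`.
#' @param config an [analysis_config()].
#' @param spatial,expr,surv generator parameter objects (simulate mode).
#' @param n_pos,n_neg,n_fields cohort dimensions (simulate mode).
#' @return the run manifest (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(out_dir, seed, simulate = TRUE, input_dir = NULL,
                         config = analysis_config(),
                         spatial = default_calibration(),
                         expr = expression_params(),
                         surv = survival_params(),
                         n_pos = 24L, n_neg = 15L, n_fields = 20L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  manifest <- list(tool = "mifquant", version = as.character(utils::packageVersion("mifquant")),
                   seed = seed, config = unclass(config), files = list(),
                   notes = character(0))
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  # ---- inputs ----
  if (simulate) {
    cohort <- generate_cohort(spatial, expr, surv, n_fields_per_lesion = n_fields,
                              seed = seed, n_pos = n_pos, n_neg = n_neg)
    patients <- cohort$patients
    lesions <- cohort$lesions
    em_raw <- cohort$expression
  } else {
    if (is.null(input_dir)) .err("supply 'input_dir' when simulate = FALSE")
    need <- c("patients.csv", "expression.csv", "housekeeping.txt")
    for (f in need) {
      if (!file.exists(file.path(input_dir, f))) {
        .err("required input file missing: %s", file.path(input_dir, f))
      }
    }
    patients <- utils::read.csv(file.path(input_dir, "patients.csv"),
                                stringsAsFactors = FALSE)
    em_raw <- read_expression_matrix(file.path(input_dir, "expression.csv"),
                                     file.path(input_dir, "housekeeping.txt"))
    lesions <- NULL
    geo_path <- file.path(input_dir, "geometry.json")
    cells_dir <- file.path(input_dir, "cells")
    if (file.exists(geo_path) && dir.exists(cells_dir)) {
      geo <- jsonlite::read_json(geo_path, simplifyVector = FALSE)
      panel <- marker_panel("9-color")
      lesions <- list()
      for (sid in names(geo)) {
        g <- geo[[sid]]
        fields <- lapply(g$fields, function(f) {
          nests <- lapply(f$nests, function(p) do.call(rbind, lapply(p, unlist)))
          field_geometry(f$field_id, f$width, f$height, nests)
        })
        cells <- read_cell_table(file.path(cells_dir, paste0(sid, ".csv")), panel)
        lesions[[sid]] <- lesion_sample(sid, g$patient_id, g$lesion_type,
                                        fields, cells)
      }
    } else {
      manifest$notes <- c(manifest$notes,
                          "no cell tables/geometry supplied; spatial stages skipped")
    }
  }
  manifest <- .pipe_write(patients, out_dir, "patients.csv", manifest)

  # ---- spatial stages ----
  features <- NULL
  if (!is.null(lesions)) {
    rules <- default_phenotype_rules(marker_panel("9-color"))
    dens_all <- list(); prox_all <- list(); counts_all <- list()
    for (sid in names(lesions)) {
      les <- lesions[[sid]]
      les$cells <- collect(assign_phenotypes(les$cells, rules))
      lesions[[sid]] <- les
      counts_all[[sid]] <- data.frame(sample_id = sid, phenotype_counts(les))
      dens_all[[sid]] <- density_profile(les)
      prox_all[[sid]] <- collect(proximity_panel(les, config = config))
    }
    densities <- do.call(rbind, dens_all)
    proximity <- do.call(rbind, prox_all)
    manifest <- .pipe_write(do.call(rbind, counts_all), out_dir, "phenotype_counts.csv", manifest)
    manifest <- .pipe_write(densities, out_dir, "densities.csv", manifest)
    manifest <- .pipe_write(proximity, out_dir, "proximity.csv", manifest)
    # patient-level immune features from the primary lesions
    prim <- names(lesions)[vapply(lesions, function(l) l$lesion_type == "primary", logical(1))]
    feat_rows <- lapply(prim, function(sid) {
      les <- lesions[[sid]]
      data.frame(
        patient_id = les$patient_id,
        cd8_tumor_density = cell_density(les, "CTL", "tumor"),
        cd8_stroma_density = cell_density(les, "CTL", "stroma"),
        m2_stroma_density = cell_density(les, "M2-TAM", "stroma"),
        treg_tumor_density = cell_density(les, "Treg", "tumor"),
        pct_tumor_near_ctl = as.numeric(
          pct_within_radius(les, "tumor", "CTL", config$proximity_radius)),
        stringsAsFactors = FALSE)
    })
    features <- do.call(rbind, feat_rows)
    rownames(features) <- features$patient_id
    manifest <- .pipe_write(features, out_dir, "patient_features.csv", manifest)
  }

  # ---- expression stages ----
  em_log2 <- log2_transform(collect(normalize_housekeeping(em_raw)))
  groups <- stats::setNames(patients$hpv_status, patients$patient_id)
  de <- collect(differential_expression(em_log2, groups,
                                        lfc_threshold = config$deg_log2fc_threshold,
                                        alpha = config$deg_alpha))
  manifest <- .pipe_write(de, out_dir, "de_results.csv", manifest)
  endo <- setdiff(rownames(em_log2$values), em_log2$housekeeping)
  sig_seed <- derive_seeds(seed, 4L)[4L]
  set.seed(sig_seed)
  sigs <- list(
    top_up = signature_set("top_up", "cell_type",
                           de$gene[order(-de$log2_fold_change)][1:10]),
    top_down = signature_set("top_down", "cell_type",
                             de$gene[order(de$log2_fold_change)][1:10]),
    random = signature_set("random", "pathway", sample(endo, 10))
  )
  scores <- signature_scores(em_log2, sigs)
  manifest <- .pipe_write(data.frame(patient_id = rownames(scores), scores),
                          out_dir, "signature_scores.csv", manifest)

  # ---- group comparisons ----
  cmp_feats <- as.data.frame(scores)
  if (!is.null(features)) {
    cmp_feats <- cbind(cmp_feats,
                       features[rownames(scores), setdiff(names(features), "patient_id")])
  }
  comparisons <- collect(compare_feature_by_group(
    cmp_feats, groups[rownames(cmp_feats)]))
  manifest <- .pipe_write(comparisons, out_dir, "comparisons.csv", manifest)

  # ---- survival screen ----
  screen <- NULL
  if (all(c("dfs_time", "dfs_event") %in% names(patients))) {
    surv_feats <- cmp_feats
    screen <- collect(survival_screen(surv_feats,
                                      patients[c("patient_id", "dfs_time", "dfs_event")],
                                      config = config))
    manifest <- .pipe_write(screen, out_dir, "survival_screen.csv", manifest)
  } else {
    manifest$notes <- c(manifest$notes, "no dfs_time/dfs_event; survival screen skipped")
  }

  manifest$warnings <- warnings_log
  manifest$summary <- list(
    n_patients = nrow(patients),
    n_lesions = if (is.null(lesions)) 0L else length(lesions),
    n_deg = sum(de$is_deg, na.rm = TRUE),
    n_screen_hits = if (is.null(screen)) NA_integer_ else sum(screen$logrank_p < 0.05, na.rm = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
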