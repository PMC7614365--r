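## End-to-end orchestration: simulate -> preprocess -> lineage space ->
## static/dynamic spatial maps -> ternary coordinates -> JSON report, driven
## by one YAML-able config with per-stage seeds derived from a master seed.

#' Derive a per-stage seed from a master seed
#'
#' Deterministic 31-bit hash of the master seed and stage name so every stage
#' consumes its own reproducible stream and partial reruns stay stable.
#'
#' @param master integer master seed
#' @param stage stage name
#' @return integer seed below 2^31
#' @export
stage_seed <- function(master, stage) {
  h <- as.numeric(master) %% 2147483647
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Default synthetic run configuration
#'
#' A fully synthetic end-to-end run: one CS6-like embryo reference, four
#' control spheroid conditions (one per region archetype) and one
#' amnion-shift perturbation against the anterior-disc control.
#'
#' @param out_dir output directory
#' @param seed master seed
#' @return a \code{run_config} list, already valid
#' @export
default_run_config <- function(out_dir = tempfile("spheromap_run_"), seed = 1L) {
  conditions <- data.frame(
    name = c("EmDisc_anterior_ctrl", "EmDisc_posterior_ctrl",
             "Am_proximal_ctrl", "Am_distal_ctrl", "BMP4_like"),
    source_region = c(embryo_regions(), "EmDisc_anterior"),
    target_region = c(embryo_regions(), "Am_distal"),
    lambda = c(0, 0, 0, 0, 0.8),
    control = c(NA, NA, NA, NA, "EmDisc_anterior_ctrl"),
    mef = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  list(out_dir = out_dir,
       seed = as.integer(seed),
       mesh_path = NULL,           # NULL => simulate the mesh
       counts_path = NULL,         # NULL => simulate the spheroid counts
       n_vertices = 400,
       radius_um = 100,
       n_background = 600,
       n_smooth = 100,
       samples_per_region = 8,
       cells_per_condition = 100,
       gene_set_mode = "cca",      # "cca" or "hvg"
       n_hvg = 500,
       cca_components = 2,
       cca_top_k = 300,
       svm_cost = 1,
       gp = list(ell = NULL, sf2 = NULL, sn2 = 0.01, optimize = FALSE),
       qc = list(min_genes_detected = 100, min_total_counts = 1000),
       ternary_markers = c("SOX2", "TFAP2A", "VTCN1"),
       conditions = conditions)
}

#' Validate a run configuration
#'
#' Accepts a YAML path or a config list; returns the typed config or throws
#' one error carrying the complete list of violations (not first-failure),
#' also available via the \code{violations} attribute of the condition.
#'
#' @param config YAML file path or config list
#' @return validated \code{run_config} list
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file does not exist: ", config)
    cfg <- yaml::read_yaml(config)
    if (!is.null(cfg$conditions))
      cfg$conditions <- as.data.frame(do.call(rbind, lapply(cfg$conditions, function(r) {
        r$control <- if (is.null(r$control)) NA_character_ else r$control
        as.data.frame(r, stringsAsFactors = FALSE)
      })))
  } else cfg <- config
  errs <- character()
  req <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  req(!is.null(cfg$out_dir) && nzchar(cfg$out_dir), "out_dir missing")
  req(is.numeric(cfg$seed), "seed must be numeric")
  req(is.numeric(cfg$n_vertices) && cfg$n_vertices >= 50,
      "n_vertices must be >= 50")
  req(!is.null(cfg$qc) && is.numeric(cfg$qc$min_genes_detected) &&
        cfg$qc$min_genes_detected >= 0, "qc min_genes_detected must be >= 0")
  req(!is.null(cfg$qc) && is.numeric(cfg$qc$min_total_counts) &&
        cfg$qc$min_total_counts >= 0, "qc min_total_counts must be >= 0")
  req(cfg$gene_set_mode %in% c("cca", "hvg"),
      "gene_set_mode must be 'cca' or 'hvg'")
  if (!is.null(cfg$mesh_path))
    req(file.exists(cfg$mesh_path),
        paste("mesh_path does not exist:", cfg$mesh_path))
  cond <- cfg$conditions
  if (is.null(cond) || nrow(cond) == 0) {
    errs <- c(errs, "conditions table missing or empty")
  } else {
    req(!anyDuplicated(cond$name), "condition names must be unique")
    for (i in seq_len(nrow(cond))) {
      if (!cond$source_region[i] %in% embryo_regions())
        errs <- c(errs, paste0("condition ", cond$name[i],
                               ": unknown source_region ", cond$source_region[i]))
      if (!cond$target_region[i] %in% embryo_regions())
        errs <- c(errs, paste0("condition ", cond$name[i],
                               ": unknown target_region ", cond$target_region[i]))
      if (is.na(cond$lambda[i]) || cond$lambda[i] < 0 || cond$lambda[i] > 1)
        errs <- c(errs, paste0("condition ", cond$name[i],
                               ": lambda must be in [0, 1]"))
      if (!is.na(cond$control[i]) && !cond$control[i] %in% cond$name)
        errs <- c(errs, paste0("condition ", cond$name[i],
                               ": control '", cond$control[i],
                               "' names no condition"))
    }
  }
  if (length(errs)) {
    e <- simpleError(paste0("invalid run config (", length(errs),
                            " violation(s)):\n  - ",
                            paste(errs, collapse = "\n  - ")))
    attr(e, "violations") <- errs
    stop(e)
  }
  cfg
}

#' Write a run configuration as YAML
#' @param cfg a run config list
#' @param path output YAML path
#' @export
write_run_config <- function(cfg, path) {
  out <- cfg
  out$conditions <- lapply(seq_len(nrow(cfg$conditions)), function(i)
    as.list(cfg$conditions[i, ]))
  yaml::write_yaml(out, path)
  invisible(path)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_run_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' simulate (mesh, fields, anchored reference, per-condition spheroid cells)
#' -> preprocess (QC, normalisation, pseudo-bulk) -> lineage space (CCA gene
#' selection, PCA, SVM boundary, stage assignment) -> static spatial identity
#' map per condition -> dynamic maps for perturbed conditions -> ternary
#' marker coordinates -> JSON report + manifest under \code{out_dir}.
#' Re-running an identical config reproduces an identical report; with
#' \code{resume = TRUE} a completed run (matching config hash) is returned
#' without recomputation.
#'
#' @param config run config (list or YAML path); see
#'   \code{\link{default_run_config}}
#' @param resume skip recomputation when the output dir already holds a
#'   completed run of this exact config
#' @return the report list (also written as \code{report.json})
#' @export
run_all <- function(config = default_run_config(), resume = FALSE) {
  cfg <- validate_config(config)
  out <- cfg$out_dir
  hash <- config_hash(cfg)
  report_path <- file.path(out, "report.json")
  manifest_path <- file.path(out, "manifest.json")
  if (resume && file.exists(report_path) && file.exists(manifest_path)) {
    man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    if (identical(man$config_hash, hash)) {
      files <- file.path(out, names(man$md5))
      ok <- file.exists(files) &
        unname(tools::md5sum(files)) == unlist(man$md5)
      if (all(ok))
        return(jsonlite::read_json(report_path, simplifyVector = FALSE))
    }
  }
  for (d in c("", "simulate", "preprocess", "lineage", "map", "dynamic",
              "ternary"))
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  log_line <- function(stage, msg)
    cat(sprintf("[%s] %s\n", stage, msg),
        file = file.path(out, "run.log"), append = TRUE)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  ## --- simulate -----------------------------------------------------------
  seeds <- list(mesh = stage_seed(cfg$seed, "mesh"),
                fields = stage_seed(cfg$seed, "fields"),
                reference = stage_seed(cfg$seed, "reference"),
                cells = stage_seed(cfg$seed, "cells"),
                stages = stage_seed(cfg$seed, "stages"))
  sim <- run_stage("simulate", {
    mesh <- if (!is.null(cfg$mesh_path)) read_mesh_ply(cfg$mesh_path)
            else make_embryo_mesh(cfg$n_vertices, cfg$radius_um,
                                  seed = seeds$mesh)
    fields <- make_expression_fields(mesh,
                                     panel = default_marker_panel(cfg$radius_um),
                                     n_background = cfg$n_background,
                                     n_smooth = cfg$n_smooth,
                                     seed = seeds$fields)
    ref <- sample_reference_profiles(fields, mesh, cfg$samples_per_region,
                                     sim_config(seed = seeds$reference))
    mats <- list()
    for (i in seq_len(nrow(cfg$conditions))) {
      ci <- cfg$conditions[i, ]
      mats[[ci$name]] <- sample_spheroid_cells(
        fields, mesh, ci$source_region, ci$target_region, ci$lambda,
        sim_config(seed = stage_seed(seeds$cells, ci$name),
                   cells_per_spheroid = cfg$cells_per_condition),
        condition = ci$name)
    }
    stage_pb <- simulate_stage_references(fields, mesh,
                                          cfg = sim_config(seed = seeds$stages))
    write_mesh_ply(mesh, file.path(out, "simulate", "mesh.ply"))
    list(mesh = mesh, fields = fields, ref = ref, mats = mats,
         stage_pb = stage_pb)
  })
  log_line("simulate", sprintf("%d vertices, %d genes, %d conditions",
                               nrow(sim$mesh$vertices), nrow(sim$fields$mu),
                               length(sim$mats)))

  ## --- preprocess ---------------------------------------------------------
  pp <- run_stage("preprocess", {
    combined <- do.call(cbind, lapply(sim$mats, function(m) m$counts))
    meta <- do.call(rbind, unname(lapply(sim$mats, function(m) m$meta)))
    m <- gene_expr(combined, meta)
    m <- qc_filter(m, cfg$qc$min_genes_detected, cfg$qc$min_total_counts)
    m <- normalize_counts(m)
    pb <- pseudo_bulk(m, "condition")
    write_counts(m, file.path(out, "preprocess", "counts"), format = "mtx")
    list(m = m, pb = pb)
  })
  log_line("preprocess", sprintf("%d/%d cells pass QC",
                                 sum(pp$m$meta$qc_pass), ncol(pp$m$counts)))

  ## --- lineage space ------------------------------------------------------
  lin <- run_stage("lineage", {
    ref_lineage2 <- ifelse(grepl("^EmDisc", sim$ref$lineage), "EmDisc", "Am")
    genes <- if (cfg$gene_set_mode == "cca") {
      sel <- cca_select_genes(sim$ref$profiles, pp$pb$profiles,
                              n_components = cfg$cca_components,
                              top_k = cfg$cca_top_k)
      sel$genes
    } else select_hvg(pp$m, cfg$n_hvg)
    model <- fit_pca(sim$ref$profiles, genes, n_pcs = 2)
    model <- fit_lineage_boundary(model, ref_lineage2, C = cfg$svm_cost)
    cls <- classify_profile(model, pp$pb)
    stages <- lapply(colnames(pp$pb$profiles), function(cn)
      assign_stage(pb_profile(pp$pb, cn), sim$stage_pb))
    names(stages) <- colnames(pp$pb$profiles)
    write_lineage_model(model, file.path(out, "lineage", "model.json"))
    utils::write.table(cls, file.path(out, "lineage", "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(model = model, genes = genes, cls = cls, stages = stages)
  })
  log_line("lineage", sprintf("%d genes; boundary accuracy %.2f",
                              length(lin$genes),
                              lin$model$boundary$train_accuracy))

  ## --- static maps --------------------------------------------------------
  maps <- run_stage("map", {
    gp_hyper <- NULL
    if (!is.null(cfg$gp$ell))
      gp_hyper <- list(ell = cfg$gp$ell, sf2 = cfg$gp$sf2 %||% 0.05,
                       sn2 = cfg$gp$sn2 %||% 0.01)
    fields_out <- list()
    for (cn in colnames(pp$pb$profiles)) {
      proj <- project_similarity(pb_profile(pp$pb, cn), sim$ref, lin$genes)
      gp <- fit_gp(proj$anchored, sim$mesh, hyper = gp_hyper,
                   optimize = isTRUE(cfg$gp$optimize))
      fld <- gp_predict(gp, sim$mesh, query_id = cn)
      write_field_csv(fld, file.path(out, "map", paste0(cn, ".csv")))
      write_field_ply(fld, sim$mesh, file.path(out, "map", paste0(cn, ".ply")))
      fields_out[[cn]] <- fld
    }
    fields_out
  })
  log_line("map", sprintf("%d static fields", length(maps)))

  ## --- dynamic maps -------------------------------------------------------
  dyn <- run_stage("dynamic", {
    res <- list()
    for (i in seq_len(nrow(cfg$conditions))) {
      ci <- cfg$conditions[i, ]
      if (is.na(ci$control)) next
      dfld <- dynamic_map(maps[[ci$name]], maps[[ci$control]])
      write_field_csv(dfld, file.path(out, "dynamic", paste0(ci$name, ".csv")))
      res[[ci$name]] <- dfld
    }
    res
  })

  ## --- ternary ------------------------------------------------------------
  tern <- run_stage("ternary", {
    mk <- cfg$ternary_markers
    missing <- setdiff(mk, rownames(pp$pb$profiles))
    if (length(missing)) stop("ternary markers absent from the matrix: ",
                              paste(missing, collapse = ", "))
    pts <- lapply(colnames(pp$pb$profiles), function(cn)
      ternary_coords(pb_profile(pp$pb, cn)[mk]))
    names(pts) <- colnames(pp$pb$profiles)
    arrows <- list()
    for (i in seq_len(nrow(cfg$conditions))) {
      ci <- cfg$conditions[i, ]
      if (is.na(ci$control)) next
      arrows[[ci$name]] <- ternary_arrow(pb_profile(pp$pb, ci$control)[mk],
                                         pb_profile(pp$pb, ci$name)[mk])
    }
    tab <- do.call(rbind, lapply(names(pts), function(cn)
      data.frame(condition = cn, marker = pts[[cn]]$labels,
                 p = pts[[cn]]$p)))
    utils::write.table(tab, file.path(out, "ternary", "ternary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(points = pts, arrows = arrows)
  })

  ## --- report -------------------------------------------------------------
  per_condition <- lapply(seq_len(nrow(cfg$conditions)), function(i) {
    ci <- cfg$conditions[i, ]
    cn <- ci$name
    cls_row <- lin$cls[lin$cls$profile == cn, ]
    ssum <- field_region_summary(maps[[cn]], sim$mesh)
    entry <- list(condition = cn,
                  stage = lin$stages[[cn]]$stage,
                  label = cls_row$label,
                  decision_value = cls_row$decision,
                  static_argmax_vertex = ssum$argmax_vertex,
                  static_argmax_region = ssum$argmax_region,
                  static_region_means = as.list(ssum$region_means),
                  ternary = as.list(tern$points[[cn]]$p))
    if (!is.na(ci$control)) {
      dsum <- field_region_summary(dyn[[cn]], sim$mesh)
      entry$dynamic_region_means <- as.list(dsum$region_means)
      entry$control <- ci$control
    }
    entry
  })
  report <- list(schema_version = "1.0",
                 package_version = as.character(utils::packageVersion("spheromap")),
                 config_hash = hash,
                 seeds = seeds,
                 gene_set_mode = cfg$gene_set_mode,
                 n_genes_selected = length(lin$genes),
                 boundary_train_accuracy = lin$model$boundary$train_accuracy,
                 conditions = per_condition)
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- setdiff(list.files(out, recursive = TRUE),
                   c("manifest.json", "run.log"))
  manifest <- list(config_hash = hash,
                   md5 = as.list(stats::setNames(
                     unname(tools::md5sum(file.path(out, files))), files)))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  log_line("report", "run complete")
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
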