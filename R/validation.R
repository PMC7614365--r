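## Ground-truth recovery experiments on fully synthetic data. These drive the
## package's own validation (tests and the acceptance script) but are exported
## so users can rerun them at other settings.

#' Build the default synthetic atlas
#'
#' One embryo mesh with the default marker panel and gene complement, an
#' anchored reference sample set, and the CCA-selected similarity gene set
#' computed against pseudo-bulks of the four archetype control conditions.
#'
#' @param seed master seed
#' @param n_vertices,radius_um mesh size
#' @param n_background,n_smooth gene complement around the marker panel
#' @param samples_per_region anchored reference samples per region
#' @param cca_top_k similarity gene-set size
#' @param cells_per_archetype cells per archetype condition used for the CCA
#' @return list: mesh, fields, ref, gene_set, archetype_pb
#' @export
build_synthetic_atlas <- function(seed = 1L, n_vertices = 500, radius_um = 100,
                                  n_background = 1990, n_smooth = 300,
                                  samples_per_region = 12,
                                  cca_top_k = 300,
                                  cells_per_archetype = 200) {
  mesh <- make_embryo_mesh(n_vertices, radius_um, seed = stage_seed(seed, "mesh"))
  fields <- make_expression_fields(mesh, default_marker_panel(radius_um),
                                   n_background = n_background,
                                   n_smooth = n_smooth,
                                   seed = stage_seed(seed, "fields"))
  ref <- sample_reference_profiles(fields, mesh, samples_per_region,
                                   sim_config(seed = stage_seed(seed, "reference")))
  mats <- lapply(embryo_regions(), function(r)
    sample_spheroid_cells(fields, mesh, r, r, 0,
                          sim_config(seed = stage_seed(seed, paste0("arch_", r)),
                                     cells_per_spheroid = cells_per_archetype)))
  counts <- do.call(cbind, lapply(mats, function(m) m$counts))
  meta <- do.call(rbind, unname(lapply(mats, function(m) m$meta)))
  m <- normalize_counts(qc_filter(gene_expr(counts, meta),
                                  min_genes_detected = 100,
                                  min_total_counts = 1000))
  pb <- pseudo_bulk(m, "condition")
  sel <- cca_select_genes(ref$profiles, pb$profiles, n_components = 2,
                          top_k = cca_top_k)
  list(mesh = mesh, fields = fields, ref = ref, gene_set = sel$genes,
       archetype_pb = pb, cca = sel$cca)
}

## one query -> static field, shared by the experiments below
static_field_for_query <- function(atlas, source_region, target_region,
                                   lambda, seed, cells = 200,
                                   optimize = FALSE) {
  m <- sample_spheroid_cells(atlas$fields, atlas$mesh, source_region,
                             target_region, lambda,
                             sim_config(seed = seed, cells_per_spheroid = cells),
                             condition = "query")
  pb <- pseudo_bulk(normalize_counts(qc_filter(m, 0, 1)), "condition")
  proj <- project_similarity(pb_profile(pb, "query"), atlas$ref,
                             atlas$gene_set)
  gp <- fit_gp(proj$anchored, atlas$mesh, optimize = optimize)
  gp_predict(gp, atlas$mesh, query_id = "query")
}

#' Region recovery experiment
#'
#' For each region, simulates \code{n_seeds} independent archetype queries of
#' \code{cells} cells, maps each statically, and records whether the field's
#' argmax vertex falls inside the generating region.
#'
#' @param atlas from \code{\link{build_synthetic_atlas}}
#' @param n_seeds seeded runs per region
#' @param cells cells per query
#' @param seed0 base seed for the query streams
#' @return data.frame: region, hits, n, rate
#' @export
region_recovery_experiment <- function(atlas = build_synthetic_atlas(),
                                       n_seeds = 100, cells = 200,
                                       seed0 = 1000L) {
  res <- lapply(embryo_regions(), function(r) {
    hits <- 0L
    for (s in seq_len(n_seeds)) {
      fld <- static_field_for_query(atlas, r, r, 0,
                                    seed = seed0 + s + 7919L * match(r, embryo_regions()),
                                    cells = cells)
      if (field_region_summary(fld, atlas$mesh)$argmax_region == r)
        hits <- hits + 1L
    }
    data.frame(region = r, hits = hits, n = n_seeds, rate = hits / n_seeds)
  })
  do.call(rbind, res)
}

#' Dynamic-map null and signal experiment
#'
#' Null: pairs of independent control (\code{lambda = 0}) replicates from the
#' same region are differenced; their mean |delta| is compared to the
#' Monte-Carlo standard error estimated from the replicate pairs. Signal:
#' paired control and \code{lambda}-shifted queries are differenced and the
#' sign pattern of the region means (positive over the target lineage,
#' negative over the source) is recorded per seed.
#'
#' @param atlas from \code{\link{build_synthetic_atlas}}
#' @param n_null_pairs replicate pairs for the null
#' @param n_signal_seeds seeded shift runs
#' @param source_region,target_region shift endpoints
#' @param lambda shift magnitude
#' @param cells cells per query
#' @param seed0 base seed
#' @return list: null_mean_abs and null_signed_means (per pair),
#'   null_mc_se (sd of the signed means across pairs), signal_correct
#'   (logical per seed), signal_rate, delta_target_mean, delta_source_mean
#' @export
dynamic_map_experiment <- function(atlas = build_synthetic_atlas(),
                                   n_null_pairs = 20, n_signal_seeds = 100,
                                   source_region = "EmDisc_anterior",
                                   target_region = "Am_distal",
                                   lambda = 0.8, cells = 200,
                                   seed0 = 5000L) {
  reg <- atlas$mesh$region
  is_src <- grepl("^EmDisc", reg)
  is_tgt <- grepl("^Am", reg)
  null_stats <- vapply(seq_len(n_null_pairs), function(i) {
    f1 <- static_field_for_query(atlas, source_region, source_region, 0,
                                 seed = seed0 + 2 * i, cells = cells)
    f2 <- static_field_for_query(atlas, source_region, source_region, 0,
                                 seed = seed0 + 2 * i + 1, cells = cells)
    d <- dynamic_map(f1, f2)$values
    c(mean_abs = mean(abs(d)), mean_signed = mean(d))
  }, numeric(2))
  null_mean_abs <- null_stats["mean_abs", ]
  null_signed_means <- null_stats["mean_signed", ]
  null_mc_se <- stats::sd(null_signed_means)
  dt <- ds <- numeric(n_signal_seeds)
  correct <- logical(n_signal_seeds)
  for (s in seq_len(n_signal_seeds)) {
    ctrl <- static_field_for_query(atlas, source_region, source_region, 0,
                                   seed = seed0 + 10000L + s, cells = cells)
    pert <- static_field_for_query(atlas, source_region, target_region,
                                   lambda, seed = seed0 + 20000L + s,
                                   cells = cells)
    d <- dynamic_map(pert, ctrl)
    dt[s] <- mean(d$values[is_tgt])
    ds[s] <- mean(d$values[is_src])
    correct[s] <- dt[s] > 0 && ds[s] < 0
  }
  list(null_mean_abs = null_mean_abs,
       null_signed_means = null_signed_means, null_mc_se = null_mc_se,
       signal_correct = correct, signal_rate = mean(correct),
       delta_target_mean = mean(dt), delta_source_mean = mean(ds))
}

#' Stage recovery experiment
#'
#' Simulates stage-graded references and nominal-stage queries, and records
#' how often \code{\link{assign_stage}} recovers the generating stage.
#'
#' @param atlas from \code{\link{build_synthetic_atlas}}
#' @param n_seeds seeded runs
#' @param cells cells per query
#' @param seed0 base seed
#' @return list: hits, n, rate
#' @export
stage_recovery_experiment <- function(atlas = build_synthetic_atlas(),
                                      n_seeds = 100, cells = 50,
                                      seed0 = 9000L) {
  stage_pb <- simulate_stage_references(atlas$fields, atlas$mesh,
                                        cfg = sim_config(seed = stage_seed(1, "stages")))
  hits <- 0L
  for (s in seq_len(n_seeds)) {
    m <- sample_spheroid_cells(atlas$fields, atlas$mesh, "EmDisc_anterior",
                               "EmDisc_anterior", 0,
                               sim_config(seed = seed0 + s,
                                          cells_per_spheroid = cells),
                               condition = "query")
    pb <- pseudo_bulk(normalize_counts(qc_filter(m, 0, 1)), "condition")
    res <- assign_stage(pb_profile(pb, "query"), stage_pb)
    if (res$stage == "CS6") hits <- hits + 1L
  }
  list(hits = hits, n = n_seeds, rate = hits / n_seeds)
}

#' Lineage boundary crossing experiment
#'
#' Sweeps the archetype mixture weight lambda from 0 (source) to 1 (target),
#' classifies each pseudo-bulk in a lineage space fitted on the reference,
#' and counts sign changes of the decision value — the binary readout should
#' flip exactly once.
#'
#' @param atlas from \code{\link{build_synthetic_atlas}}
#' @param lambdas sweep grid
#' @param cells cells per condition
#' @param seed seed for the sweep's count draws
#' @return list: lambdas, decisions, crossings
#' @export
lambda_sweep_experiment <- function(atlas = build_synthetic_atlas(),
                                    lambdas = seq(0, 1, by = 0.1),
                                    cells = 200, seed = 77L) {
  ref_lineage2 <- ifelse(grepl("^EmDisc", atlas$ref$lineage), "EmDisc", "Am")
  model <- fit_pca(atlas$ref$profiles, atlas$gene_set, n_pcs = 2)
  model <- fit_lineage_boundary(model, ref_lineage2, C = 1)
  decisions <- vapply(lambdas, function(l) {
    m <- sample_spheroid_cells(atlas$fields, atlas$mesh, "EmDisc_anterior",
                               "Am_distal", l,
                               sim_config(seed = seed,
                                          cells_per_spheroid = cells),
                               condition = "sweep")
    pb <- pseudo_bulk(normalize_counts(qc_filter(m, 0, 1)), "condition")
    classify_profile(model, pb_profile(pb, "sweep"))$decision
  }, numeric(1))
  crossings <- sum(diff(sign(decisions)) != 0)
  list(lambdas = lambdas, decisions = decisions, crossings = crossings,
       model = model)
}
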