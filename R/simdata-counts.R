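#' Simulation configuration
#'
#' Bundles every stochastic-model parameter of the count simulators so that an
#' identical configuration reproduces bit-identical outputs.
#'
#' Counts are negative-binomial with \code{Var = m + m^2/theta} at mean
#' \code{m}; per-cell/sample depth factors are lognormal with unit mean
#' (log-mean \code{lib_log_mean} sets the nominal depth scale used when
#' absolute library sizes are requested; the mean-one factor keeps expected
#' counts equal to the field means).
#'
#' @param seed master integer seed
#' @param nb_theta negative-binomial dispersion (> 0)
#' @param lib_log_mean,lib_log_sd lognormal library-size parameters
#' @param lambda archetype mixture weight in [0, 1]
#' @param cells_per_spheroid cells simulated per spheroid condition
#' @return object of class \code{sim_config}
#' @export
sim_config <- function(seed = 1L, nb_theta = 10, lib_log_mean = 9.2,
                       lib_log_sd = 0.3, lambda = 0, cells_per_spheroid = 200L) {
  if (!is.numeric(nb_theta) || nb_theta <= 0) stop("nb_theta must be > 0")
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must be in [0, 1]")
  stopifnot(cells_per_spheroid >= 1, lib_log_sd >= 0)
  structure(list(seed = as.integer(seed), nb_theta = nb_theta,
                 lib_log_mean = lib_log_mean, lib_log_sd = lib_log_sd,
                 lambda = lambda,
                 cells_per_spheroid = as.integer(cells_per_spheroid)),
            class = "sim_config")
}

## lognormal depth factors with expectation exactly 1
depth_factors <- function(n, cfg) {
  stats::rlnorm(n, meanlog = -cfg$lib_log_sd^2 / 2, sdlog = cfg$lib_log_sd)
}

nb_draw <- function(mu, theta) {
  ## rnbinom(mu=0) is a point mass at 0 but guard against negative rounding
  stats::rnbinom(length(mu), size = theta, mu = pmax(mu, 0))
}

#' Sample anchored in-vivo reference profiles
#'
#' Draws \code{samples_per_region} spatially anchored reference samples per
#' region: each sample picks an anchor vertex in its region, then draws
#' negative-binomial counts with mean \code{mu_g(anchor)} scaled by a
#' lognormal depth factor. Lineage labels come from the anchor's region and
#' the stage from the mesh.
#'
#' @param fields an \code{expression_fields}
#' @param mesh the generating \code{embryo_mesh}
#' @param samples_per_region samples per region (>= 1)
#' @param cfg a \code{\link{sim_config}}
#' @return object of class \code{spatial_reference}: mesh, per-sample raw
#'   \code{counts} (genes x samples), CP10K-log1p \code{profiles}, anchor
#'   vertex indices, lineage and stage labels.
#' @export
sample_reference_profiles <- function(fields, mesh, samples_per_region = 12L,
                                      cfg = sim_config()) {
  if (is.null(fields$mu) || nrow(fields$mu) == 0) stop("empty field list")
  if (samples_per_region < 1) stop("samples_per_region must be >= 1")
  regions <- embryo_regions()
  withr::with_seed(cfg$seed, {
    anchors <- unlist(lapply(regions, function(r) {
      cand <- which(mesh$region == r)
      sample(cand, samples_per_region, replace = samples_per_region > length(cand))
    }))
    n_s <- length(anchors)
    depth <- depth_factors(n_s, cfg)
    counts <- vapply(seq_len(n_s), function(i)
      nb_draw(fields$mu[, anchors[i]] * depth[i], cfg$nb_theta),
      numeric(nrow(fields$mu)))
  })
  rownames(counts) <- rownames(fields$mu)
  colnames(counts) <- sprintf("ref_%s_%02d",
                              rep(regions, each = samples_per_region),
                              rep(seq_len(samples_per_region), length(regions)))
  profiles <- cp10k_log1p(counts)
  structure(list(mesh = mesh, counts = counts, profiles = profiles,
                 anchors = anchors,
                 lineage = rep(regions, each = samples_per_region),
                 stage = rep(mesh$stage, n_s)),
            class = "spatial_reference")
}

#' @export
print.spatial_reference <- function(x, ...) {
  cat("spatial_reference:", ncol(x$counts), "samples x", nrow(x$counts),
      "genes on", nrow(x$mesh$vertices), "vertices\n")
  print(table(x$lineage, x$stage))
  invisible(x)
}

#' Simulate single cells of a spheroid condition
#'
#' Cell expression means are the convex mixture
#' \code{(1 - lambda) * archetype(source) + lambda * archetype(target)} of two
#' region archetypes (field means over the region's vertices); counts are
#' negative-binomial per cell with lognormal (unit-mean) depth factors, so the
#' expected raw count of a gene equals its mixed archetype mean.
#'
#' @param fields,mesh generator outputs (see \code{\link{make_expression_fields}})
#' @param source_region,target_region region names (see \code{\link{embryo_regions}})
#' @param lambda mixture weight in [0, 1]; overrides \code{cfg$lambda}
#' @param cfg a \code{\link{sim_config}}
#' @param condition condition label recorded in cell metadata
#' @return a \code{gene_expr} matrix with cell metadata columns
#'   \code{condition, cell_line, lambda, source_region, target_region, seed}
#' @export
sample_spheroid_cells <- function(fields, mesh, source_region, target_region,
                                  lambda = cfg$lambda, cfg = sim_config(),
                                  condition = NULL) {
  arc <- region_archetypes(fields, mesh,
                           regions = unique(c(source_region, target_region)))
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  base <- (1 - lambda) * arc[, source_region] + lambda * arc[, target_region]
  n_c <- cfg$cells_per_spheroid
  withr::with_seed(cfg$seed, {
    depth <- depth_factors(n_c, cfg)
    counts <- vapply(seq_len(n_c), function(i)
      nb_draw(base * depth[i], cfg$nb_theta), numeric(length(base)))
  })
  rownames(counts) <- rownames(fields$mu)
  if (is.null(condition))
    condition <- if (lambda == 0) source_region else
      sprintf("%s_to_%s_l%.2f", source_region, target_region, lambda)
  colnames(counts) <- sprintf("%s_c%03d", condition, seq_len(n_c))
  meta <- data.frame(condition = rep(condition, n_c), cell_line = "sim1",
                     lambda = lambda, source_region = source_region,
                     target_region = target_region, seed = cfg$seed,
                     row.names = colnames(counts),
                     stringsAsFactors = FALSE)
  gene_expr(counts, meta)
}

#' Stage-graded reference pseudo-bulk profiles
#'
#' Emulates developmental staging: the middle stage (CS6) mean is the
#' unmodified region archetype; every other stage additionally up-regulates
#' its own disjoint block of stage-signature genes (drawn deterministically
#' from the background panel) and scales the lineage-marker block by a
#' stage grade. A query simulated from the unmodified fields therefore
#' correlates best with the nominal stage. Returns one pseudo-bulk profile
#' per stage, built from NB-sampled cells of the given region.
#'
#' @param fields,mesh generator outputs
#' @param region region whose staged archetypes are produced
#' @param stages stage labels, ordered
#' @param grades marker-amplitude multipliers, one per stage (1 = nominal)
#' @param signature_genes background genes per non-nominal stage signature
#' @param signature_fold fold-change applied to signature genes
#' @param cells cells per stage
#' @param cfg a \code{\link{sim_config}}
#' @return \code{pb_set} of one normalized profile per stage
#' @export
simulate_stage_references <- function(fields, mesh, region = "EmDisc_anterior",
                                      stages = c("CS5", "CS6", "CS7"),
                                      grades = c(0.7, 1, 1.3),
                                      signature_genes = 30L,
                                      signature_fold = 6, cells = 50L,
                                      cfg = sim_config()) {
  stopifnot(length(stages) == length(grades))
  arc <- region_archetypes(fields, mesh, regions = region)[, 1]
  is_marker <- fields$kind == "marker-gradient"
  base_marker <- arc[is_marker]
  bg_idx <- which(fields$kind == "background")
  nominal <- which(grades == 1)[1]
  if (is.na(nominal)) nominal <- ceiling(length(stages) / 2)
  off_stages <- setdiff(seq_along(stages), nominal)
  if (length(off_stages) * signature_genes > length(bg_idx))
    stop("not enough background genes for the stage signatures")
  counts <- NULL
  for (i in seq_along(stages)) {
    mu <- arc
    mu[is_marker] <- base_marker * grades[i]
    pos <- match(i, off_stages)
    if (!is.na(pos)) {
      sig <- bg_idx[(pos - 1) * signature_genes + seq_len(signature_genes)]
      mu[sig] <- mu[sig] * signature_fold
    }
    withr::with_seed(cfg$seed + i, {
      depth <- depth_factors(cells, cfg)
      cc <- vapply(seq_len(cells), function(j)
        nb_draw(mu * depth[j], cfg$nb_theta), numeric(length(mu)))
    })
    colnames(cc) <- sprintf("%s_c%03d", stages[i], seq_len(cells))
    counts <- cbind(counts, cc)
  }
  rownames(counts) <- rownames(fields$mu)
  meta <- data.frame(condition = rep(stages, each = cells),
                     cell_line = "sim1", row.names = colnames(counts),
                     stringsAsFactors = FALSE)
  m <- gene_expr(counts, meta)
  m <- qc_filter(m, min_genes_detected = 0, min_total_counts = 1)
  m <- normalize_counts(m)
  pseudo_bulk(m, "condition")
}
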