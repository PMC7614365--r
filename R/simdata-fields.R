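#' Default lineage marker panel
#'
#' Twelve marker genes with region-structured smooth expression fields
#' emulating the canonical postimplantation marker geography: POU5F1 broadly
#' high over the embryonic disc, SOX2/NANOG graded towards the anterior disc,
#' TBXT/MIXL1/WNT8A confined to the posterior disc, TFAP2A/TFAP2C pan-amnion,
#' VTCN1/GABRP/HAND1 graded towards the distal (mature) amnion, ISL1 low and
#' broad over the amnion. Every region is thereby identifiable by several
#' genes, as required for correlation-based mapping.
#'
#' Each entry defines a logistic gradient of one vertex axis coordinate:
#' \code{axis} one of "z" (apical-basal/disc-amnion), "x" (anterior-posterior)
#' or "polar" (angle from the amnion pole); \code{direction} +1 increases with
#' the coordinate, -1 decreases; \code{midpoint}/\code{steepness} place and
#' sharpen the transition; optional \code{regions} gates the gradient to a
#' subset of regions (baseline elsewhere).
#'
#' @param radius_um rim radius used to scale steepness to mesh units.
#' @return list of marker specs consumed by \code{\link{make_expression_fields}}.
#' @export
default_marker_panel <- function(radius_um = 100) {
  s <- 8 / radius_um   # logistic steepness per micrometre
  disc <- c("EmDisc_anterior", "EmDisc_posterior")
  list(
    list(gene = "SOX2",   axis = "x", direction = +1, baseline = 0.5,
         amplitude = 30, midpoint = 0, steepness = s, regions = disc),
    list(gene = "POU5F1", axis = "z", direction = -1, baseline = 5,
         amplitude = 25, midpoint = 0, steepness = s, regions = NULL),
    list(gene = "NANOG",  axis = "x", direction = +1, baseline = 0.5,
         amplitude = 20, midpoint = 0, steepness = s, regions = disc),
    list(gene = "TBXT",   axis = "x", direction = -1, baseline = 0.2,
         amplitude = 25, midpoint = 0, steepness = s, regions = disc),
    list(gene = "MIXL1",  axis = "x", direction = -1, baseline = 0.2,
         amplitude = 18, midpoint = 0, steepness = s, regions = disc),
    list(gene = "WNT8A",  axis = "x", direction = -1, baseline = 0.2,
         amplitude = 12, midpoint = 0, steepness = s, regions = disc),
    list(gene = "TFAP2A", axis = "z", direction = +1, baseline = 0.5,
         amplitude = 30, midpoint = 0, steepness = s, regions = NULL),
    list(gene = "TFAP2C", axis = "z", direction = +1, baseline = 0.5,
         amplitude = 25, midpoint = 0, steepness = s, regions = NULL),
    list(gene = "VTCN1",  axis = "polar", direction = -1, baseline = 0.2,
         amplitude = 25, midpoint = pi / 4, steepness = 6,
         regions = c("Am_proximal", "Am_distal")),
    list(gene = "GABRP",  axis = "polar", direction = -1, baseline = 0.2,
         amplitude = 20, midpoint = pi / 4, steepness = 6,
         regions = c("Am_proximal", "Am_distal")),
    list(gene = "HAND1",  axis = "polar", direction = -1, baseline = 0.2,
         amplitude = 15, midpoint = pi / 4, steepness = 6,
         regions = c("Am_proximal", "Am_distal")),
    ## low, heterogeneous over the amnion, biased towards the rim-adjacent
    ## (streak-facing) proximal amnion
    list(gene = "ISL1",   axis = "polar", direction = +1, baseline = 0.5,
         amplitude = 6, midpoint = pi / 4, steepness = 4,
         regions = c("Am_proximal", "Am_distal"))
  )
}

axis_coordinate <- function(mesh, axis) {
  switch(axis,
         x = mesh$vertices[, 1],
         y = mesh$vertices[, 2],
         z = mesh$vertices[, 3],
         polar = mesh$polar,
         stop("unknown axis: ", axis))
}

#' Generate per-vertex expression fields
#'
#' Produces one non-negative mean-expression field per gene on the mesh:
#' marker genes as logistic gradients along a stated axis (optionally gated to
#' named regions), background genes as region-independent constants, and
#' random-smooth genes as exponentiated Gaussian-process samples adding
#' realistic spatial autocorrelation.
#'
#' @param mesh an \code{embryo_mesh}
#' @param panel list of marker specs (see \code{\link{default_marker_panel}})
#' @param n_background number of region-independent constant genes
#' @param n_smooth number of random-smooth (GP-sampled) genes
#' @param seed integer seed
#' @param smooth_ell length-scale of the random-smooth sampler (micrometres);
#'   defaults to half the mesh "radius" (max distance from centroid).
#' @return object of class \code{expression_fields}: list with \code{mu}
#'   (genes x vertices matrix of means), \code{kind} (per gene:
#'   marker-gradient/background/random-smooth) and \code{panel}.
#' @export
make_expression_fields <- function(mesh, panel = default_marker_panel(),
                                   n_background = 1990, n_smooth = 300,
                                   seed = 1L, smooth_ell = NULL) {
  genes <- vapply(panel, `[[`, "", "gene")
  if (anyDuplicated(genes)) stop("panel gene names must be unique")
  known <- embryo_regions()
  for (p in panel)
    if (!is.null(p$regions) && !all(p$regions %in% known))
      stop("unknown region name in marker spec for gene ", p$gene, ": ",
           paste(setdiff(p$regions, known), collapse = ", "))

  n_v <- nrow(mesh$vertices)
  marker_mu <- t(vapply(panel, function(p) {
    t_coord <- axis_coordinate(mesh, p$axis)
    grad <- p$baseline + p$amplitude /
      (1 + exp(-p$direction * p$steepness * (t_coord - p$midpoint)))
    if (!is.null(p$regions)) {
      out <- rep(p$baseline, n_v)
      inside <- mesh$region %in% p$regions
      out[inside] <- grad[inside]
      out
    } else grad
  }, numeric(n_v)))

  withr::with_seed(as.integer(seed), {
    bg_levels <- stats::rlnorm(n_background, meanlog = log(2), sdlog = 1)
    bg_mu <- if (n_background > 0)
      matrix(rep(bg_levels, n_v), nrow = n_background) else NULL
    sm_mu <- NULL
    if (n_smooth > 0) {
      if (is.null(smooth_ell)) {
        ctr <- colMeans(mesh$vertices)
        smooth_ell <- 0.5 * max(sqrt(rowSums(sweep(mesh$vertices, 2, ctr)^2)))
      }
      d2 <- as.matrix(stats::dist(mesh$vertices))^2
      K <- 0.5 * exp(-d2 / (2 * smooth_ell^2))
      L <- t(chol(K + diag(1e-8, n_v)))
      sm_base <- stats::rlnorm(n_smooth, meanlog = log(1.5), sdlog = 0.8)
      Z <- matrix(stats::rnorm(n_smooth * n_v), nrow = n_v)
      sm_mu <- t(L %*% Z)          # GP samples, rows = genes
      sm_mu <- sm_base * exp(sm_mu)
    }
  })

  mu <- rbind(marker_mu, bg_mu, sm_mu)
  rownames(mu) <- c(genes,
                    sprintf("BG%04d", seq_len(n_background)),
                    if (n_smooth > 0) sprintf("SM%04d", seq_len(n_smooth)))
  kind <- c(rep("marker-gradient", length(genes)),
            rep("background", n_background),
            rep("random-smooth", n_smooth))
  structure(list(mu = mu, kind = kind, panel = panel),
            class = "expression_fields")
}

#' @export
print.expression_fields <- function(x, ...) {
  cat("expression_fields:", nrow(x$mu), "genes x", ncol(x$mu), "vertices\n")
  print(table(x$kind))
  invisible(x)
}

#' Region archetype profiles
#'
#' The archetype of a region is the mean of every gene's field over that
#' region's vertices — the expression identity cells of that lineage emulate.
#'
#' @param fields an \code{expression_fields}
#' @param mesh the mesh the fields were generated on
#' @param regions regions to compute (default all four)
#' @return genes x regions matrix
#' @export
region_archetypes <- function(fields, mesh, regions = embryo_regions()) {
  bad <- setdiff(regions, unique(mesh$region))
  if (length(bad)) stop("unknown region: ", paste(bad, collapse = ", "))
  vapply(regions,
         function(r) rowMeans(fields$mu[, mesh$region == r, drop = FALSE]),
         numeric(nrow(fields$mu)))
}
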