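## Spatial identity mapping: Pearson similarity of a query pseudo-bulk to
## spatially anchored reference samples, interpolated over the whole embryo
## surface by Gaussian process regression; dynamic maps are signed
## perturbed-minus-control differences of static maps.

#' Pearson similarity between two profiles
#'
#' Sample Pearson correlation on a gene set; constant vectors are an error
#' (correlation undefined), naming the offending profile.
#'
#' @param query,reference named numeric profiles
#' @param gene_set gene ids (must be present in both)
#' @param method "pearson" (default) or "spearman"
#' @return correlation in [-1, 1]
#' @export
pearson_similarity <- function(query, reference, gene_set = NULL,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.null(gene_set)) gene_set <- intersect(names(query), names(reference))
  missing_q <- setdiff(gene_set, names(query))
  missing_r <- setdiff(gene_set, names(reference))
  if (length(missing_q) || length(missing_r))
    stop("gene_set not covered by both profiles")
  q <- as.numeric(query[gene_set]); r <- as.numeric(reference[gene_set])
  if (stats::sd(q) == 0) stop("query profile is constant on the gene set")
  if (stats::sd(r) == 0) stop("reference profile is constant on the gene set")
  stats::cor(q, r, method = method)
}

#' Project query similarity onto reference anchors
#'
#' One correlation per reference sample, attached to its anchor vertex;
#' multiple samples anchored at the same vertex are averaged (the training
#' set of the GP must have one value per location).
#'
#' @param query named numeric profile (pseudo-bulk of the query condition)
#' @param ref a \code{spatial_reference}
#' @param gene_set gene ids to correlate on
#' @param method correlation flavour, see \code{\link{pearson_similarity}}
#' @return list: \code{anchored} data.frame (vertex, value) with one row per
#'   distinct anchor vertex, and \code{per_sample} data.frame
#'   (sample, vertex, lineage, r)
#' @export
project_similarity <- function(query, ref, gene_set = NULL,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!inherits(ref, "spatial_reference") || ncol(ref$profiles) == 0)
    stop("reference is empty")
  r <- vapply(seq_len(ncol(ref$profiles)), function(j)
    pearson_similarity(query, ref$profiles[, j], gene_set, method),
    numeric(1))
  per_sample <- data.frame(sample = colnames(ref$profiles),
                           vertex = ref$anchors, lineage = ref$lineage,
                           r = r, stringsAsFactors = FALSE)
  agg <- tapply(per_sample$r, per_sample$vertex, mean)
  anchored <- data.frame(vertex = as.integer(names(agg)),
                         value = as.numeric(agg))
  list(anchored = anchored, per_sample = per_sample, metric = method)
}

sqexp_kernel <- function(X1, X2, ell, sf2) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  sf2 * exp(-pmax(d2, 0) / (2 * ell^2))
}

chol_with_jitter <- function(K) {
  jit <- 0
  repeat {
    L <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jit))
    jit <- if (jit == 0) 1e-8 else jit * 10
    if (jit > 1e-4)
      stop("kernel matrix not positive definite after jitter escalation")
  }
}

gp_neg_loglik <- function(par, X, y) {
  ell <- exp(par[1]); sf2 <- exp(par[2]); sn2 <- exp(par[3])
  n <- length(y)
  K <- sqexp_kernel(X, X, ell, sf2) + diag(sn2, n)
  cj <- tryCatch(chol_with_jitter(K), error = function(e) NULL)
  if (is.null(cj)) return(list(value = 1e10, gradient = c(0, 0, 0)))
  L <- cj$L
  alpha <- backsolve(L, forwardsolve(t(L), y))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  ## gradients: dL/dtheta = -0.5 tr((alpha alpha' - K^-1) dK/dtheta)
  Kinv <- chol2inv(L)
  A <- tcrossprod(alpha) - Kinv
  D2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * tcrossprod(X)
  Kse <- K - diag(sn2, n)
  dK_dlogell <- Kse * pmax(D2, 0) / ell^2
  g <- c(-0.5 * sum(A * dK_dlogell),
         -0.5 * sum(A * Kse),
         -0.5 * sum(diag(A)) * sn2)
  list(value = nll, gradient = g)
}

#' Fit a Gaussian process to anchored similarity values
#'
#' Squared-exponential kernel on 3D vertex coordinates:
#' \code{k(u, v) = sf2 * exp(-||x_u - x_v||^2 / (2 ell^2))} plus noise
#' variance \code{sn2} on the diagonal. With \code{optimize = TRUE} the
#' hyperparameters maximize the log marginal likelihood by multi-start
#' L-BFGS-B (5 deterministic starts) with bounds
#' \code{ell in [min edge length, mesh diameter]} and \code{sn2 >= 1e-6}.
#'
#' @param anchored data.frame (vertex, value) — e.g.
#'   \code{project_similarity()$anchored}
#' @param mesh the \code{embryo_mesh} carrying vertex coordinates
#' @param hyper list(ell, sf2, sn2) — initial (or fixed) hyperparameters;
#'   defaults: ell = a sixth of the mesh diameter, sf2 = var(values),
#'   sn2 = var(values) / 10
#' @param optimize maximize the marginal likelihood
#' @param mean prior mean: "constant" subtracts the mean of the training
#'   values before fitting and adds it back on prediction (the default;
#'   correlation fields fluctuate around a non-zero level), "zero" fits the
#'   raw values
#' @return object of class \code{gp_model}
#' @export
fit_gp <- function(anchored, mesh, hyper = NULL, optimize = FALSE,
                   mean = c("constant", "zero")) {
  mean <- match.arg(mean)
  if (nrow(anchored) < 2) stop("need at least 2 anchors to fit a GP")
  X <- mesh$vertices[anchored$vertex, , drop = FALSE]
  mean_y <- if (mean == "constant") base::mean(anchored$value) else 0
  y <- anchored$value - mean_y
  diam <- mesh_diameter(mesh)
  if (is.null(hyper)) {
    ## defaults calibrated for mapping: a length-scale of a sixth of the mesh
    ## diameter follows sub-lineage structure without inter-anchor overshoot;
    ## the noise floor scales with the anchored-value variance so smoothing
    ## is proportionate to the observed signal
    v <- max(stats::var(y), 1e-6)
    hyper <- list(ell = diam / 6, sf2 = v, sn2 = 0.1 * v)
  }
  stopifnot(hyper$ell > 0, hyper$sf2 > 0, hyper$sn2 >= 0)
  if (optimize) {
    lo_ell <- max(min(mesh_edge_lengths(mesh)), 1e-6)
    lower <- log(c(lo_ell, 1e-6, 1e-6))
    upper <- log(c(diam, 1e3, 1e2))
    ## deterministic multi-start grid across the ell range
    ell_starts <- exp(seq(log(lo_ell * 1.5), log(diam / 1.5), length.out = 5))
    best <- NULL
    for (e0 in ell_starts) {
      par0 <- log(c(e0, max(stats::var(y), 1e-4), max(hyper$sn2, 1e-4)))
      fit <- tryCatch(
        stats::optim(par0,
                     fn = function(p) gp_neg_loglik(p, X, y)$value,
                     gr = function(p) gp_neg_loglik(p, X, y)$gradient,
                     method = "L-BFGS-B", lower = lower, upper = upper),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) stop("GP hyperparameter optimization failed")
    hyper <- list(ell = exp(best$par[1]), sf2 = exp(best$par[2]),
                  sn2 = exp(best$par[3]))
  }
  K <- sqexp_kernel(X, X, hyper$ell, hyper$sf2) + diag(hyper$sn2, nrow(X))
  cj <- chol_with_jitter(K)
  alpha <- backsolve(cj$L, forwardsolve(t(cj$L), y))
  lml <- -(0.5 * sum(y * alpha) + sum(log(diag(cj$L))) +
           0.5 * length(y) * log(2 * pi))
  structure(list(kernel = "squared-exponential",
                 ell = hyper$ell, sf2 = hyper$sf2, sn2 = hyper$sn2,
                 X = X, y = y, mean_y = mean_y, anchors = anchored$vertex,
                 L = cj$L, alpha = alpha, jitter = cj$jitter,
                 log_marginal_likelihood = lml),
            class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf("gp_model (%s): ell = %.3g um, sf2 = %.3g, sn2 = %.3g, %d anchors, lml = %.3f\n",
              x$kernel, x$ell, x$sf2, x$sn2, length(x$y),
              x$log_marginal_likelihood))
  invisible(x)
}

#' Predict a static identity field over the mesh
#'
#' Posterior mean at every vertex, clipped to the correlation range [-1, 1]
#' (GP means can overshoot); the posterior standard deviation is attached
#' when \code{with_sd = TRUE}.
#'
#' @param model a fitted \code{gp_model}
#' @param mesh the target \code{embryo_mesh}
#' @param clip range to clip to (NULL disables)
#' @param with_sd compute the posterior sd per vertex
#' @param query_id,metric provenance strings stored in the field
#' @return object of class \code{identity_field}
#' @export
gp_predict <- function(model, mesh, clip = c(-1, 1), with_sd = FALSE,
                       query_id = "query", metric = "pearson") {
  if (!inherits(model, "gp_model")) stop("model is not a fitted gp_model")
  Ks <- sqexp_kernel(mesh$vertices, model$X, model$ell, model$sf2)
  mu <- drop(Ks %*% model$alpha) + model$mean_y
  sd <- NULL
  if (with_sd) {
    V <- forwardsolve(t(model$L), t(Ks))
    var <- pmax(model$sf2 - colSums(V^2), 0)
    sd <- sqrt(var)
  }
  raw_range <- range(mu)
  if (!is.null(clip)) mu <- pmin(pmax(mu, clip[1]), clip[2])
  structure(list(values = mu, sd = sd, kind = "static",
                 query_id = query_id, metric = metric,
                 hyper = list(ell = model$ell, sf2 = model$sf2,
                              sn2 = model$sn2),
                 clip = clip, raw_range = raw_range,
                 n_vertices = nrow(mesh$vertices)),
            class = "identity_field")
}

#' @export
print.identity_field <- function(x, ...) {
  cat(sprintf("identity_field (%s, %s): %d vertices, range [%.3f, %.3f]\n",
              x$kind, x$query_id, x$n_vertices, min(x$values), max(x$values)))
  invisible(x)
}

#' Dynamic spatial identity map
#'
#' Per-vertex signed difference (perturbed - control) of two static fields on
#' the same mesh — the embryo regions gaining identity under the perturbation
#' are positive, those losing it negative.
#'
#' @param perturbed,control static \code{identity_field}s on the same mesh,
#'   computed with the same similarity metric
#' @return an \code{identity_field} with \code{kind = "dynamic"}
#' @export
dynamic_map <- function(perturbed, control) {
  if (perturbed$n_vertices != control$n_vertices)
    stop("mesh mismatch: fields have different vertex counts")
  if (!identical(perturbed$metric, control$metric))
    stop("metric mismatch between the two fields")
  structure(list(values = perturbed$values - control$values, sd = NULL,
                 kind = "dynamic",
                 query_id = paste0(perturbed$query_id, "-", control$query_id),
                 metric = perturbed$metric, hyper = perturbed$hyper,
                 clip = NULL, raw_range = range(perturbed$values - control$values),
                 n_vertices = perturbed$n_vertices),
            class = "identity_field")
}

#' Summarise a field by mesh region
#' @param field an \code{identity_field}
#' @param mesh the mesh it lives on
#' @return list: \code{region_means} (named), \code{argmax_vertex},
#'   \code{argmax_region}
#' @export
field_region_summary <- function(field, mesh) {
  stopifnot(field$n_vertices == nrow(mesh$vertices))
  means <- tapply(field$values, mesh$region, mean)
  i <- which.max(field$values)
  list(region_means = means[embryo_regions()],
       argmax_vertex = i, argmax_region = mesh$region[i])
}

#' Barycentric ternary coordinates of three marker levels
#'
#' \code{p_i = m_i / sum(m)}; at least one marker must be positive and none
#' negative.
#'
#' @param markers numeric length-3 (optionally named) non-negative levels
#' @return object of class \code{ternary_point}: \code{p} (barycentric,
#'   sums to 1), \code{labels}, \code{xy} (Cartesian embedding with vertices
#'   (0,0), (1,0), (1/2, sqrt(3)/2))
#' @export
ternary_coords <- function(markers) {
  if (length(markers) != 3) stop("exactly three marker levels required")
  if (any(markers < 0)) stop("marker levels must be non-negative")
  s <- sum(markers)
  if (s == 0) stop("all three marker levels are zero")
  p <- as.numeric(markers) / s
  labels <- names(markers)
  if (is.null(labels)) labels <- paste0("m", 1:3)
  corners <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  xy <- drop(p %*% corners)
  structure(list(p = stats::setNames(p, labels), labels = labels, xy = xy),
            class = "ternary_point")
}

#' @export
print.ternary_point <- function(x, ...) {
  cat("ternary_point:", paste(sprintf("%s = %.3f", x$labels, x$p),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Perturbation arrow in ternary space
#'
#' Origin at the control marker proportions, endpoint at the perturbed ones.
#'
#' @param control,perturbed length-3 non-negative marker levels
#' @return list of class \code{ternary_arrow}: \code{origin}, \code{endpoint}
#'   (both \code{ternary_point}), \code{length} (Euclidean in the Cartesian
#'   embedding)
#' @export
ternary_arrow <- function(control, perturbed) {
  o <- ternary_coords(control)
  e <- ternary_coords(perturbed)
  structure(list(origin = o, endpoint = e,
                 length = sqrt(sum((e$xy - o$xy)^2))),
            class = "ternary_arrow")
}

#' Export a field as CSV
#' @param field an \code{identity_field}
#' @param path output CSV (columns vertex_id, value, posterior_sd)
#' @export
write_field_csv <- function(field, path) {
  out <- data.frame(vertex_id = seq_len(field$n_vertices),
                    value = field$values,
                    posterior_sd = if (is.null(field$sd)) NA_real_ else field$sd)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## diverging blue-white-red colormap over a fixed range
field_colormap <- function(values, range) {
  ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
  t <- (pmin(pmax(values, range[1]), range[2]) - range[1]) / diff(range)
  round(ramp(t))
}

#' Export a field as coloured PLY
#'
#' Per-vertex values mapped through a fixed-range diverging colormap:
#' static fields over [-1, 1], dynamic fields symmetric about 0.
#'
#' @param field an \code{identity_field}
#' @param mesh the mesh it lives on
#' @param path output PLY path
#' @param binary write binary little-endian
#' @export
write_field_ply <- function(field, mesh, path, binary = FALSE) {
  rng <- if (field$kind == "static") c(-1, 1)
  else c(-1, 1) * max(abs(field$values), 1e-12)
  rgb <- field_colormap(field$values, rng)
  write_mesh_ply(mesh, path, binary = binary, value = field$values, rgb = rgb)
}
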