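## Lineage coordinate system: CCA gene selection across in-vivo / in-vitro
## pseudo-bulk sets, PCA of the selected genes, and a linear support-vector
## boundary separating embryonic disc from amnion in the PC1/PC2 plane.

as_profile_matrix <- function(x) {
  if (inherits(x, "pb_set")) x$profiles else as.matrix(x)
}

## symmetric inverse square root of S + gamma*I via eigen (p x p, p small)
inv_sqrt <- function(S, gamma) {
  e <- eigen(S + diag(gamma, nrow(S)), symmetric = TRUE)
  vals <- pmax(e$values, 1e-12)
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

#' Canonical correlation gene selection
#'
#' Runs (ridge-regularized) canonical correlation analysis between two
#' pseudo-bulk sets over their shared genes, treating genes as observations
#' and profiles as variables (the cross-dataset convention of single-cell
#' integration tools). Per-gene scores are the absolute canonical-variate
#' coordinates, averaged over the two datasets; the \code{top_k} genes by the
#' maximum score across the first \code{n_components} pairs are returned.
#'
#' @param pb_x,pb_y \code{pb_set} objects (or genes x profiles matrices)
#' @param n_components canonical pairs to score genes on
#' @param top_k genes to return
#' @param gamma ridge added to both profile covariance matrices; needed when
#'   the problem is ill-posed (few genes, collinear profiles), harmless
#'   otherwise. Set 0 for exact CCA.
#' @return list: \code{genes} (selected ids), \code{cca}
#'   (class \code{cca_result}: \code{rho} canonical correlations,
#'   \code{scores} per-gene loading magnitudes, \code{x_coef}/\code{y_coef}
#'   profile-space weights)
#' @export
cca_select_genes <- function(pb_x, pb_y, n_components = 2, top_k = 500,
                             gamma = 1e-3) {
  X <- as_profile_matrix(pb_x); Y <- as_profile_matrix(pb_y)
  shared <- intersect(rownames(X), rownames(Y))
  if (length(shared) == 0) stop("no shared genes between the two datasets")
  if (top_k > length(shared)) stop("top_k exceeds the shared gene universe")
  Xg <- t(X[shared, , drop = FALSE])   # profiles x genes -> transpose below
  Yg <- t(Y[shared, , drop = FALSE])
  ## observations = genes, variables = profiles
  Xc <- scale(t(Xg), center = TRUE, scale = FALSE)
  Yc <- scale(t(Yg), center = TRUE, scale = FALSE)
  n <- nrow(Xc)
  if (ncol(Xc) < n_components + 0 || ncol(Yc) < n_components)
    stop("each dataset needs at least n_components profiles")
  Sxx <- crossprod(Xc) / (n - 1)
  Syy <- crossprod(Yc) / (n - 1)
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  Wx <- inv_sqrt(Sxx, gamma)
  Wy <- inv_sqrt(Syy, gamma)
  sv <- svd(Wx %*% Sxy %*% Wy)
  d <- min(ncol(Xc), ncol(Yc))
  rho <- pmin(pmax(sv$d[seq_len(d)], 0), 1)
  a <- Wx %*% sv$u[, seq_len(d), drop = FALSE]   # profile-space weights
  b <- Wy %*% sv$v[, seq_len(d), drop = FALSE]
  U <- Xc %*% a                                  # gene-level variates
  V <- Yc %*% b
  U <- scale(U, center = FALSE, scale = sqrt(colSums(U^2)) + 1e-300)
  V <- scale(V, center = FALSE, scale = sqrt(colSums(V^2)) + 1e-300)
  nc <- min(n_components, d)
  scores_mat <- (abs(U[, seq_len(nc), drop = FALSE]) +
                 abs(V[, seq_len(nc), drop = FALSE])) / 2
  score <- apply(scores_mat, 1, max)
  ord <- order(-score, seq_along(score))         # stable tie-break: gene order
  genes <- shared[ord[seq_len(top_k)]]
  cca <- structure(list(rho = rho, scores = stats::setNames(score, shared),
                        x_coef = a, y_coef = b, gamma = gamma),
                   class = "cca_result")
  list(genes = genes, cca = cca)
}

#' @export
print.cca_result <- function(x, ...) {
  cat("cca_result: rho =", paste(sprintf("%.4f", utils::head(x$rho, 5)),
                                 collapse = ", "),
      if (length(x$rho) > 5) "..." else "", "\n")
  invisible(x)
}

#' Fit the PCA part of the lineage space
#'
#' Principal components of the selected genes across profiles: genes are
#' centered (optionally unit-scaled); loadings are the top right-singular
#' vectors with signs fixed so each component's largest-magnitude loading is
#' positive.
#'
#' @param pb a \code{pb_set} (or genes x profiles matrix) of training profiles
#' @param genes gene ids spanning the space (e.g. CCA-selected)
#' @param n_pcs number of components (must not exceed the data rank)
#' @param scale. unit-scale genes before PCA
#' @return object of class \code{lineage_space}: gene list, centering/scaling
#'   vectors, loadings, explained-variance fractions, training scores/labels
#' @export
fit_pca <- function(pb, genes, n_pcs = 2, scale. = FALSE) {
  P <- as_profile_matrix(pb)
  missing <- setdiff(genes, rownames(P))
  if (length(missing)) stop("profiles missing genes: ",
                            paste(utils::head(missing), collapse = ", "))
  X <- t(P[genes, , drop = FALSE])   # profiles x genes
  if (nrow(X) < n_pcs + 1) stop("need at least n_pcs + 1 profiles")
  pr <- stats::prcomp(X, center = TRUE, scale. = scale.)
  rank <- sum(pr$sdev > pr$sdev[1] * 1e-9)
  if (n_pcs > rank) stop(sprintf("n_pcs = %d exceeds data rank %d", n_pcs, rank))
  load <- pr$rotation[, seq_len(n_pcs), drop = FALSE]
  flip <- vapply(seq_len(n_pcs), function(j) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) -1 else 1
  }, numeric(1))
  load <- sweep(load, 2, flip, "*")
  evf <- pr$sdev^2 / sum(pr$sdev^2)
  ctr <- pr$center
  scl <- if (is.logical(pr$scale) && !pr$scale) rep(1, length(genes)) else pr$scale
  scores <- sweep(sweep(X, 2, ctr), 2, scl, "/") %*% load
  structure(list(genes = genes, center = ctr, scale = scl,
                 loadings = load, evf = evf[seq_len(n_pcs)],
                 train_scores = scores,
                 train_names = rownames(X),
                 boundary = NULL),
            class = "lineage_space")
}

#' @export
print.lineage_space <- function(x, ...) {
  cat("lineage_space:", length(x$genes), "genes,", ncol(x$loadings),
      "PCs (explained:", paste(sprintf("%.1f%%", 100 * x$evf), collapse = ", "),
      ");", if (is.null(x$boundary)) "no boundary" else "boundary fitted", "\n")
  invisible(x)
}

#' Project profiles into the lineage space
#'
#' Centers/scales the model's genes and multiplies by the loadings. Missing
#' genes are an error (named), never silently zeroed.
#'
#' @param model a \code{lineage_space}
#' @param profile named numeric vector, genes x k matrix, or \code{pb_set}
#' @return matrix of PC coordinates (one row per profile)
#' @export
project_profiles <- function(model, profile) {
  P <- if (is.numeric(profile) && is.null(dim(profile)))
    matrix(profile, ncol = 1, dimnames = list(names(profile), "query"))
  else as_profile_matrix(profile)
  missing <- setdiff(model$genes, rownames(P))
  if (length(missing))
    stop("profile missing model genes: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (+%d more)", length(missing) - 10))
  X <- t(P[model$genes, , drop = FALSE])
  sweep(sweep(X, 2, model$center), 2, model$scale, "/") %*% model$loadings
}

#' Fit a linear support-vector decision boundary in the PC1/PC2 plane
#'
#' Soft-margin linear SVM with cost \code{C}; the decision value is
#' \code{d(x) = w . x + b}, oriented so \code{d > 0} for the EmDisc class.
#'
#' @param scores n x 2 matrix of PC1/PC2 coordinates
#' @param labels factor/character with levels "EmDisc" and "Am"
#' @param C soft-margin cost
#' @return list of class \code{svm_boundary}: \code{w} (length 2), \code{b},
#'   \code{C}, training accuracy
#' @export
fit_decision_boundary <- function(scores, labels, C = 1) {
  scores <- as.matrix(scores)[, 1:2, drop = FALSE]
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("both classes (EmDisc, Am) must be present")
  y <- factor(labels, levels = c("Am", "EmDisc"))
  fit <- e1071::svm(x = scores, y = y, type = "C-classification",
                    kernel = "linear", cost = C, scale = FALSE,
                    tolerance = 1e-6)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  d <- drop(scores %*% w + b)
  if (mean(d[labels == "EmDisc"]) < mean(d[labels == "Am"])) {
    w <- -w; b <- -b; d <- -d
  }
  acc <- mean((d > 0) == (labels == "EmDisc"))
  structure(list(w = unname(w), b = unname(b), C = C, train_accuracy = acc),
            class = "svm_boundary")
}

#' Attach a decision boundary to a lineage space model
#' @param model a \code{lineage_space}
#' @param labels training profile labels ("EmDisc"/"Am"), in training order
#' @param C soft-margin cost
#' @return the model with \code{boundary} filled in
#' @export
fit_lineage_boundary <- function(model, labels, C = 1) {
  model$boundary <- fit_decision_boundary(model$train_scores[, 1:2], labels, C)
  model
}

#' Classify a profile as EmDisc or Am
#'
#' Projects into PC1/PC2 and evaluates the decision value; the label follows
#' its sign (\code{"boundary"} sentinel at exactly 0) and |d| serves as a
#' confidence proxy.
#'
#' @param model a \code{lineage_space} with a fitted boundary
#' @param profile named vector / matrix / \code{pb_set}
#' @return data.frame: profile, label, decision
#' @export
classify_profile <- function(model, profile) {
  if (is.null(model$boundary))
    stop("no decision boundary fitted; run fit_lineage_boundary() first")
  sc <- project_profiles(model, profile)[, 1:2, drop = FALSE]
  d <- drop(sc %*% model$boundary$w + model$boundary$b)
  lab <- ifelse(d > 0, "EmDisc", ifelse(d < 0, "Am", "boundary"))
  data.frame(profile = rownames(sc), label = lab, decision = d,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign the closest embryonic stage
#'
#' Pearson correlation of the query against each stage reference pseudo-bulk
#' over a gene set (e.g. highly variable genes); the argmax stage is returned
#' with the full correlation vector. Ties are broken by the fixed stage order
#' CS5 < CS6 < CS7 (then column order) and flagged.
#'
#' @param query named numeric profile
#' @param stage_pb \code{pb_set} (or genes x stages matrix), one column per stage
#' @param gene_set optional gene ids to correlate on (default: all shared)
#' @return list: \code{stage}, \code{correlations} (named), \code{tie} flag
#' @export
assign_stage <- function(query, stage_pb, gene_set = NULL) {
  R <- as_profile_matrix(stage_pb)
  if (ncol(R) < 2) stop("need at least 2 stage references")
  if (is.null(gene_set)) gene_set <- intersect(names(query), rownames(R))
  q <- query[gene_set]
  if (stats::sd(q) == 0) stop("query profile is constant on the gene set")
  r <- vapply(seq_len(ncol(R)), function(j) stats::cor(q, R[gene_set, j]),
              numeric(1))
  names(r) <- colnames(R)
  canonical <- c("CS5", "CS6", "CS7")
  ord <- order(match(colnames(R), canonical, nomatch = length(canonical) + 1))
  r_ord <- r[ord]
  best <- which(r_ord >= max(r_ord) - 1e-12)
  list(stage = names(r_ord)[best[1]], correlations = r,
       tie = length(best) > 1)
}

#' Serialize a lineage space model to JSON
#' @param model a \code{lineage_space}
#' @param path output path
#' @export
write_lineage_model <- function(model, path) {
  obj <- list(genes = model$genes,
              center = unname(model$center),
              scale = unname(model$scale),
              loadings = unname(model$loadings),   # row-major via jsonlite
              explained_variance = model$evf,
              boundary = if (!is.null(model$boundary))
                list(w = model$boundary$w, b = model$boundary$b,
                     C = model$boundary$C,
                     sign_convention = "d>0 => EmDisc"),
              conventions = list(center = "gene means over training profiles",
                                 loading_sign = "largest |loading| positive"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized lineage space model
#' @param path JSON path written by \code{\link{write_lineage_model}}
#' @return a \code{lineage_space} (without training scores)
#' @export
read_lineage_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  boundary <- NULL
  if (!is.null(obj$boundary))
    boundary <- structure(list(w = obj$boundary$w, b = obj$boundary$b,
                               C = obj$boundary$C, train_accuracy = NA),
                          class = "svm_boundary")
  L <- obj$loadings
  if (is.list(L)) L <- do.call(rbind, lapply(L, unlist))
  structure(list(genes = obj$genes,
                 center = stats::setNames(obj$center, obj$genes),
                 scale = stats::setNames(obj$scale, obj$genes),
                 loadings = as.matrix(L),
                 evf = obj$explained_variance,
                 train_scores = NULL, train_names = NULL,
                 boundary = boundary),
            class = "lineage_space")
}
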