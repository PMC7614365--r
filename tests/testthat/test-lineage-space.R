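# independent CCA oracle: generalized eigenproblem route
# rho^2 = eigenvalues of (Sxx + g I)^-1 Sxy (Syy + g I)^-1 Syx
cca_oracle_rho <- function(X, Y, gamma = 0) {
  Xc <- scale(X, center = TRUE, scale = FALSE)  # observations = genes (rows)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  n <- nrow(Xc)
  Sxx <- crossprod(Xc) / (n - 1) + diag(gamma, ncol(Xc))
  Syy <- crossprod(Yc) / (n - 1) + diag(gamma, ncol(Yc))
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  M <- solve(Sxx, Sxy) %*% solve(Syy, t(Sxy))
  ev <- sort(Re(eigen(M, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(pmax(ev, 0))
}

rand_pb <- function(n_genes, n_prof, seed, prefix = "p") {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_prof), n_genes, n_prof,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                paste0(prefix, seq_len(n_prof))))
  })
  m
}

test_that("a perfectly shared latent axis yields canonical correlation 1", {
  withr::with_seed(1, {
    f <- rnorm(200, sd = 40)                      # latent gene axis
    X <- outer(f, c(1, 0.5, 2)) + matrix(rnorm(600, sd = 1e-4), 200)
    Y <- outer(f, c(-1, 3)) + matrix(rnorm(400, sd = 1e-4), 200)
  })
  rownames(X) <- rownames(Y) <- sprintf("g%03d", 1:200)
  res <- cca_select_genes(X, Y, n_components = 1, top_k = 10, gamma = 0)
  expect_lt(abs(res$cca$rho[1] - 1), 1e-6)
})

test_that("canonical correlations match the generalized-eigen oracle", {
  X <- rand_pb(500, 10, seed = 2, prefix = "x")
  Y <- rand_pb(500, 10, seed = 3, prefix = "y")
  for (gamma in c(0, 1e-3)) {
    res <- cca_select_genes(X, Y, n_components = 2, top_k = 100, gamma = gamma)
    oracle <- cca_oracle_rho(X, Y, gamma)
    expect_equal(res$cca$rho, oracle[seq_along(res$cca$rho)],
                 tolerance = 1e-6)
  }
  # and against the base R implementation when unregularized
  cc <- cancor(X, Y)
  res0 <- cca_select_genes(X, Y, n_components = 2, top_k = 100, gamma = 0)
  expect_equal(res0$cca$rho, cc$cor, tolerance = 1e-6)
})

test_that("canonical correlations are invariant to per-dataset linear maps", {
  X <- rand_pb(120, 6, seed = 4, prefix = "x")
  Y <- rand_pb(120, 5, seed = 5, prefix = "y")
  withr::with_seed(6, {
    A <- matrix(rnorm(36), 6) + diag(2, 6)   # invertible
    B <- matrix(rnorm(25), 5) + diag(2, 5)
  })
  XA <- X %*% A; rownames(XA) <- rownames(X)
  YB <- Y %*% B; rownames(YB) <- rownames(Y)
  r1 <- cca_select_genes(X, Y, 2, 50, gamma = 0)$cca$rho
  r2 <- cca_select_genes(XA, YB, 2, 50, gamma = 0)$cca$rho
  expect_equal(r1, r2, tolerance = 1e-8)
})

test_that("top_k covering the shared universe returns every shared gene", {
  X <- rand_pb(40, 6, seed = 7, prefix = "x")
  Y <- rand_pb(40, 6, seed = 8, prefix = "y")
  res <- cca_select_genes(X, Y, 2, 40, gamma = 1e-3)
  expect_setequal(res$genes, rownames(X))
  rownames(Y) <- paste0("other", seq_len(40))
  expect_error(cca_select_genes(X, Y, 2, 10), "no shared genes")
})

test_that("PCA matches an eigen-decomposition oracle and explains rank-1 data", {
  # profiles on a line: PC1 explains everything
  withr::with_seed(9, {
    base <- rnorm(20); dir <- rnorm(20)
    P <- sapply(seq(-2, 2, length.out = 6), function(t) base + t * dir)
  })
  rownames(P) <- sprintf("g%02d", 1:20)
  colnames(P) <- paste0("p", 1:6)
  mod <- fit_pca(P, rownames(P), n_pcs = 1)
  expect_lt(abs(mod$evf[1] - 1), 1e-8)
  # random data: scores match covariance eigenvectors up to sign
  R <- rand_pb(20, 6, seed = 10)
  mod2 <- fit_pca(R, rownames(R), n_pcs = 2)
  X <- t(R) - colMeans(t(R))[col(t(R))]
  X <- scale(t(R), center = TRUE, scale = FALSE)
  ev <- eigen(cov(X), symmetric = TRUE)
  for (j in 1:2) {
    o <- X %*% ev$vectors[, j]
    s <- mod2$train_scores[, j]
    expect_true(max(abs(s - o)) < 1e-8 || max(abs(s + o)) < 1e-8)
  }
  # explained variance fractions are non-increasing and sum <= 1
  expect_true(all(diff(mod2$evf) <= 1e-12))
  expect_lte(sum(mod2$evf), 1 + 1e-12)
  # loadings orthonormal
  expect_equal(unname(crossprod(mod2$loadings)), diag(2), tolerance = 1e-10)
  # duplicating the profile set leaves loadings unchanged
  D <- cbind(R, R); colnames(D) <- paste0("p", 1:12)
  mod3 <- fit_pca(D, rownames(D), n_pcs = 2)
  expect_equal(mod3$loadings, mod2$loadings, tolerance = 1e-8)
  expect_error(fit_pca(P, rownames(P), n_pcs = 5), "rank")
})

test_that("PCA scores are invariant to gene-order permutation", {
  R <- rand_pb(30, 7, seed = 11)
  genes <- rownames(R)
  mod <- fit_pca(R, genes, 2)
  withr::with_seed(12, perm <- sample(30))
  modp <- fit_pca(R[perm, ], genes, 2)
  expect_equal(modp$train_scores, mod$train_scores, tolerance = 1e-10)
})

test_that("projection is the stated centred matrix product", {
  R <- rand_pb(25, 6, seed = 13)
  mod <- fit_pca(R, rownames(R), 2)
  # the mean in-vivo profile sits at the origin
  expect_lt(max(abs(project_profiles(mod, rowMeans(R)))), 1e-10)
  # a training profile reproduces its training score
  expect_equal(project_profiles(mod, R[, 3]),
               mod$train_scores[3, , drop = FALSE],
               tolerance = 1e-10, ignore_attr = TRUE)
  # arbitrary profile vs direct oracle
  withr::with_seed(14, q <- setNames(rnorm(25), rownames(R)))
  oracle <- drop((q[mod$genes] - mod$center) %*% mod$loadings)
  expect_equal(drop(project_profiles(mod, q)), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
  # missing genes are a named error, not silent zeros
  expect_error(project_profiles(mod, q[-3]), "missing model genes")
})

test_that("the SVM boundary is correct on symmetric and separable toys", {
  # symmetric pair -> boundary x1 = 0
  sc <- rbind(c(-1, 0), c(1, 0))
  b <- fit_decision_boundary(sc, c("Am", "EmDisc"), C = 1)
  expect_equal(b$w[2], 0, tolerance = 1e-6)
  expect_equal(b$b, 0, tolerance = 1e-6)
  expect_gt(b$w[1], 0)    # oriented so EmDisc side is positive
  # any separable toy: 100% training accuracy
  withr::with_seed(15, {
    em <- cbind(rnorm(10, 3), rnorm(10))
    am <- cbind(rnorm(10, -3), rnorm(10))
  })
  sep <- fit_decision_boundary(rbind(em, am),
                               rep(c("EmDisc", "Am"), each = 10), C = 10)
  expect_identical(sep$train_accuracy, 1)
  expect_error(fit_decision_boundary(em, rep("EmDisc", 10)), "both classes")
})

test_that("the SVM solution matches an independent dual QP", {
  skip_if_not_installed("kernlab")
  withr::with_seed(16, {
    X <- rbind(cbind(rnorm(10, 1.2, 1), rnorm(10, 0.5, 1)),
               cbind(rnorm(10, -1.2, 1), rnorm(10, -0.5, 1)))
  })
  labels <- rep(c("EmDisc", "Am"), each = 10)
  y <- ifelse(labels == "EmDisc", 1, -1)
  C <- 1
  fit <- fit_decision_boundary(X, labels, C = C)
  # dual: min 1/2 a' Q a - 1' a, 0 <= a <= C, y' a = 0
  Q <- (y %*% t(y)) * (X %*% t(X))
  sol <- kernlab::ipop(c = rep(-1, 20), H = Q,
                       A = matrix(y, 1), b = 0, r = 0,
                       l = rep(0, 20), u = rep(C, 20),
                       sigf = 12, maxiter = 200)
  a <- kernlab::primal(sol)
  w <- drop(t(a * y) %*% X)
  on_margin <- which(a > 1e-6 & a < C - 1e-6)
  b0 <- mean(y[on_margin] - X[on_margin, ] %*% w)
  expect_equal(fit$w, w, tolerance = 1e-4)
  expect_equal(fit$b, b0, tolerance = 1e-4)
})

test_that("decision values are affine-equivariant under translation", {
  withr::with_seed(17, {
    X <- rbind(cbind(rnorm(8, 2), rnorm(8)), cbind(rnorm(8, -2), rnorm(8)))
  })
  labels <- rep(c("EmDisc", "Am"), each = 8)
  f0 <- fit_decision_boundary(X, labels, C = 1)
  shift <- c(5, -3)
  f1 <- fit_decision_boundary(sweep(X, 2, -shift), labels, C = 1)
  expect_equal(f1$w, f0$w, tolerance = 1e-4)
  expect_equal(f1$b, f0$b - sum(f0$w * shift), tolerance = 1e-3)
  d0 <- X %*% f0$w + f0$b
  d1 <- sweep(X, 2, -shift) %*% f1$w + f1$b
  expect_identical(sign(d0), sign(d1))
})

test_that("classification labels follow the decision sign with a boundary sentinel", {
  R <- rand_pb(20, 8, seed = 18)
  mod <- fit_pca(R, rownames(R), 2)
  labs <- ifelse(mod$train_scores[, 1] > 0, "EmDisc", "Am")
  # force both classes
  labs[1] <- "EmDisc"; labs[2] <- "Am"
  mod <- fit_lineage_boundary(mod, labs, C = 100)
  expect_error(classify_profile(fit_pca(R, rownames(R), 2), R[, 1]),
               "no decision boundary")
  cls <- classify_profile(mod, R)
  expect_true(all(cls$label %in% c("EmDisc", "Am", "boundary")))
  expect_identical(cls$label[cls$decision > 0],
                   rep("EmDisc", sum(cls$decision > 0)))
  # a profile engineered to sit exactly on the boundary
  w <- mod$boundary$w
  x0 <- -mod$boundary$b / sum(w * w) * w     # point with w.x + b = 0
  # invert the projection for a profile mapping to x0 (use loadings directly)
  prof <- mod$center + drop(mod$loadings %*% x0)
  names(prof) <- mod$genes
  d <- classify_profile(mod, prof)
  expect_lt(abs(d$decision), 1e-8)
})

test_that("stage assignment recovers self-matches and breaks ties fixedly", {
  R <- rand_pb(50, 3, seed = 19, prefix = "CS")
  colnames(R) <- c("CS5", "CS6", "CS7")
  res <- assign_stage(R[, "CS6"], R)
  expect_identical(res$stage, "CS6")
  expect_equal(unname(res$correlations["CS6"]), 1, tolerance = 1e-12)
  # exactly symmetric query (reference and its own reversal have identical
  # variance): tie broken by stage order
  a <- R[, "CS5"]
  b <- setNames(rev(a), names(a))
  refs <- cbind(CS7 = b, CS5 = a)
  q <- (a + b) / 2
  res2 <- assign_stage(q, refs)
  expect_true(res2$tie)
  expect_identical(res2$stage, "CS5")
  expect_error(assign_stage(setNames(rep(1, 50), rownames(R)), R), "constant")
  expect_error(assign_stage(R[, 1], R[, 1, drop = FALSE]), "at least 2")
})

test_that("lineage models survive JSON serialization", {
  R <- rand_pb(15, 6, seed = 20)
  mod <- fit_pca(R, rownames(R), 2)
  labs <- rep(c("EmDisc", "Am"), 3)
  mod <- fit_lineage_boundary(mod, labs, C = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_lineage_model(mod, path)
  back <- read_lineage_model(path)
  expect_equal(back$loadings, unname(mod$loadings), tolerance = 1e-12)
  expect_equal(back$boundary$w, mod$boundary$w, tolerance = 1e-12)
  withr::with_seed(21, q <- setNames(rnorm(15), mod$genes))
  expect_equal(unname(classify_profile(back, q)$decision),
               unname(classify_profile(mod, q)$decision), tolerance = 1e-10)
})
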