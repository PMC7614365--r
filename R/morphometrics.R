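## Image-derived quantifications on label-mask inputs: per-frame channel
## intensities and ratios, line intensity profiles, 3D nuclear orientation,
## epithelial thickness, summed spheroid intensity, DAPI normalisation and
## the group-comparison statistics.

## physical voxel-centre coordinates (z, y, x in micrometres, centred array)
stack_axis_coords <- function(stack) {
  d <- dim(stack$labels)
  list(z = (seq_len(d[1]) - (d[1] + 1) / 2) * stack$voxel_um["z"],
       y = (seq_len(d[2]) - (d[2] + 1) / 2) * stack$voxel_um["y"],
       x = (seq_len(d[3]) - (d[3] + 1) / 2) * stack$voxel_um["x"])
}

#' Per-frame channel intensity on a mask
#'
#' For every z frame, the mean intensity of each channel over mask voxels
#' (default mask: the nucleus label volume), plus the ratio of the first to
#' the second requested channel with an \code{eps} guard. Frames with an
#' empty mask are omitted and listed in the \code{omitted_frames} attribute.
#'
#' @param stack a \code{spheroid_stack}
#' @param channels channel names to quantify (ratio = first / second)
#' @param mask logical array (z, y, x); default \code{labels > 0}
#' @param eps denominator guard for the ratio
#' @return data.frame: frame, one column per channel, ratio
#' @export
frame_intensity <- function(stack, channels = stack$channels, mask = NULL,
                            eps = 1e-6) {
  if (is.null(mask)) mask <- stack$labels > 0
  stopifnot(all(dim(mask) == dim(stack$labels)))
  ki <- match(channels, stack$channels)
  if (anyNA(ki)) stop("unknown channel(s): ",
                      paste(channels[is.na(ki)], collapse = ", "))
  nz <- dim(mask)[1]
  nvox <- vapply(seq_len(nz), function(z) sum(mask[z, , ]), numeric(1))
  keep <- which(nvox > 0)
  if (!length(keep)) stop("mask is empty on every frame")
  out <- data.frame(frame = keep)
  for (j in seq_along(channels)) {
    out[[channels[j]]] <- vapply(keep, function(z) {
      m <- mask[z, , ]
      mean(stack$voxels[z, , , ki[j]][m])
    }, numeric(1))
  }
  if (length(channels) >= 2)
    out$ratio <- out[[channels[1]]] / (out[[channels[2]]] + eps)
  attr(out, "omitted_frames") <- setdiff(seq_len(nz), keep)
  out
}

#' Intensity profile along a line
#'
#' Bilinear interpolation of a 2D image at \code{n_samples} equidistant
#' points between two endpoints (row/column coordinates, 1-based).
#'
#' @param img numeric matrix
#' @param p0,p1 endpoints c(row, col), inside the image
#' @param n_samples number of sample points (>= 2)
#' @return data.frame: t (0..1), row, col, intensity
#' @export
line_profile <- function(img, p0, p1, n_samples = 100) {
  stopifnot(is.matrix(img), n_samples >= 2)
  for (p in list(p0, p1))
    if (p[1] < 1 || p[1] > nrow(img) || p[2] < 1 || p[2] > ncol(img))
      stop("endpoint outside the image")
  if (all(p0 == p1)) stop("zero-length line")
  t <- seq(0, 1, length.out = n_samples)
  r <- p0[1] + t * (p1[1] - p0[1])
  c <- p0[2] + t * (p1[2] - p0[2])
  r0 <- pmin(floor(r), nrow(img) - 1); c0 <- pmin(floor(c), ncol(img) - 1)
  fr <- r - r0; fc <- c - c0
  v <- img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
       img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
       img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
       img[cbind(r0 + 1, c0 + 1)] * fr * fc
  data.frame(t = t, row = r, col = c, intensity = v)
}

#' Per-nucleus orientation and intensities
#'
#' For each nucleus label: the major axis is the principal eigenvector of the
#' voxel second-moment matrix in physical units; the orientation angle phi is
#' the angle between that axis and the radial direction (nucleus centroid to
#' spheroid centroid), folded to [0, 90] degrees. Near-isotropic nuclei
#' (largest/second eigenvalue ratio < \code{iso_ratio}) are flagged
#' degenerate; nuclei under \code{min_voxels} voxels are skipped with a
#' warning.
#'
#' @param stack a \code{spheroid_stack}
#' @param min_voxels minimum voxels per nucleus
#' @param iso_ratio eigenvalue-ratio threshold below which orientation is
#'   considered undefined by symmetry
#' @return data.frame of class \code{nucleus_morphometry}: nucleus, n_voxels,
#'   centroid (um), major-axis components, phi_deg, degenerate flag, mean
#'   intensity per channel
#' @export
nuclear_orientation <- function(stack, min_voxels = 5, iso_ratio = 1.1) {
  labs <- sort(unique(as.integer(stack$labels[stack$labels > 0])))
  if (!length(labs)) stop("no nucleus labels in the stack")
  ax <- stack_axis_coords(stack)
  ctr <- stack$centroid_um[c("z", "y", "x")]
  rows <- list(); skipped <- 0L
  for (l in labs) {
    idx <- which(stack$labels == l, arr.ind = TRUE)   # (z, y, x) indices
    if (nrow(idx) < min_voxels) { skipped <- skipped + 1L; next }
    P <- cbind(ax$z[idx[, 1]], ax$y[idx[, 2]], ax$x[idx[, 3]])
    cen <- colMeans(P)
    S <- stats::cov(P)
    e <- eigen(S, symmetric = TRUE)
    major <- e$vectors[, 1]
    degen <- e$values[1] / max(e$values[2], 1e-12) < iso_ratio
    radial <- cen - ctr
    radial <- radial / sqrt(sum(radial^2))
    cosang <- abs(sum(major * radial))
    phi <- acos(pmin(cosang, 1)) * 180 / pi          # folded to [0, 90]
    means <- vapply(seq_along(stack$channels), function(k)
      mean(stack$voxels[, , , k][stack$labels == l]), numeric(1))
    row <- data.frame(nucleus = l, n_voxels = nrow(idx),
                      cz = cen[1], cy = cen[2], cx = cen[3],
                      phi_deg = phi, degenerate = degen)
    for (k in seq_along(stack$channels)) row[[stack$channels[k]]] <- means[k]
    rows[[length(rows) + 1]] <- row
  }
  if (skipped > 0)
    warning(sprintf("%d nucleus/nuclei under %d voxels skipped", skipped,
                    min_voxels))
  if (!length(rows)) stop("all nuclei skipped (too few voxels)")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("nucleus_morphometry", "data.frame")
  out
}

#' Basolateral/apical nuclear orientation ratio
#'
#' Ratio of tangentially oriented (phi > threshold) to radially oriented
#' (phi <= threshold) non-degenerate nuclei; \code{Inf} when no nucleus is
#' radial.
#'
#' @param morphs a \code{nucleus_morphometry} table
#' @param threshold_deg fold threshold in degrees
#' @return scalar ratio (possibly \code{Inf})
#' @export
orientation_ratio <- function(morphs, threshold_deg = 45) {
  m <- morphs[!morphs$degenerate, , drop = FALSE]
  if (nrow(m) == 0) stop("no non-degenerate nuclei")
  tangential <- sum(m$phi_deg > threshold_deg)
  radial <- sum(m$phi_deg <= threshold_deg)
  if (radial == 0) Inf else tangential / radial
}

#' Epithelial thickness by radial ray casting
#'
#' Casts rays from the spheroid centroid along near-uniform directions and
#' measures, in physical units, the radial span of the epithelial shell mask
#' (first to last crossing). Rays that never cross the shell are skipped with
#' a warning.
#'
#' @param stack a \code{spheroid_stack} with a \code{shell_mask} (or supply
#'   \code{mask})
#' @param n_sectors number of ray directions
#' @param mask logical shell mask (z, y, x); default \code{stack$shell_mask}
#' @return data.frame: sector, direction components, r_inner, r_outer,
#'   thickness_um
#' @export
epithelial_thickness <- function(stack, n_sectors = 64, mask = NULL) {
  if (is.null(mask)) mask <- stack$shell_mask
  if (is.null(mask)) stop("no shell mask available")
  ax <- stack_axis_coords(stack)
  d <- dim(mask)
  dirs <- fibonacci_directions(n_sectors)   # columns x, y, z
  step <- min(stack$voxel_um) / 4
  r_max <- min(max(abs(ax$x)), max(abs(ax$y)), max(abs(ax$z)))
  rs <- seq(step, r_max, by = step)
  out <- list()
  for (s in seq_len(n_sectors)) {
    u <- dirs[s, ]
    px <- rs * u[1]; py <- rs * u[2]; pz <- rs * u[3]
    iz <- round((pz - ax$z[1]) / stack$voxel_um["z"]) + 1
    iy <- round((py - ax$y[1]) / stack$voxel_um["y"]) + 1
    ix <- round((px - ax$x[1]) / stack$voxel_um["x"]) + 1
    ok <- iz >= 1 & iz <= d[1] & iy >= 1 & iy <= d[2] & ix >= 1 & ix <= d[3]
    hit <- rep(FALSE, length(rs))
    hit[ok] <- mask[cbind(iz[ok], iy[ok], ix[ok])]
    if (!any(hit)) next
    r_in <- rs[which(hit)[1]]
    r_out <- rs[max(which(hit))]
    out[[length(out) + 1]] <- data.frame(sector = s, ux = u[1], uy = u[2],
                                         uz = u[3], r_inner = r_in,
                                         r_outer = r_out,
                                         thickness_um = r_out - r_in)
  }
  if (!length(out)) stop("no ray crossed the shell mask")
  if (length(out) < n_sectors)
    warning(sprintf("%d of %d sectors never crossed the shell",
                    n_sectors - length(out), n_sectors))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Total spheroid intensity (sum of slices)
#'
#' Sum of a channel over all mask voxels across every z slice.
#'
#' @param stack a \code{spheroid_stack}
#' @param channel channel name
#' @param mask logical array (z, y, x); default: nuclei or shell
#' @return scalar total intensity
#' @export
spheroid_intensity <- function(stack, channel, mask = NULL) {
  if (is.null(mask)) {
    mask <- stack$labels > 0
    if (!is.null(stack$shell_mask)) mask <- mask | stack$shell_mask
  }
  if (!any(mask)) stop("spheroid mask is empty")
  k <- match(channel, stack$channels)
  if (is.na(k)) stop("unknown channel: ", channel)
  sum(stack$voxels[, , , k][mask])
}

#' DAPI-normalized per-nucleus intensities
#'
#' Per-nucleus mean channel intensity divided by the nucleus' mean DAPI
#' intensity; zero-DAPI nuclei are dropped with a warning.
#'
#' @param morphs a \code{nucleus_morphometry} table
#' @param channel channel to normalise
#' @param dapi_channel name of the DNA counterstain column
#' @return data.frame: nucleus, value
#' @export
dapi_normalize <- function(morphs, channel, dapi_channel = "DAPI") {
  for (cc in c(channel, dapi_channel))
    if (!cc %in% colnames(morphs)) stop("no such channel column: ", cc)
  dapi <- morphs[[dapi_channel]]
  bad <- dapi <= 0
  if (any(bad))
    warning(sprintf("%d nucleus/nuclei with zero %s skipped", sum(bad),
                    dapi_channel))
  if (all(bad)) stop("every nucleus has zero ", dapi_channel)
  data.frame(nucleus = morphs$nucleus[!bad],
             value = morphs[[channel]][!bad] / dapi[!bad])
}

## Dunn's post-hoc test after Kruskal-Wallis (rank-sum z statistics with tie
## correction), pairwise two-sided p-values adjusted by Bonferroni
dunn_posthoc <- function(values_by_group) {
  g <- names(values_by_group)
  x <- unlist(values_by_group, use.names = FALSE)
  grp <- rep(g, lengths(values_by_group))
  N <- length(x)
  rk <- rank(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(rk, grp, mean)[g]
  n <- lengths(values_by_group)
  pairs <- utils::combn(g, 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[i] + 1 / n[j]))
    z <- (mean_rank[i] - mean_rank[j]) / se
    c(z = unname(z), p = unname(2 * stats::pnorm(-abs(z))))
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = res["z", ], p = res["p", ],
             p_adj = stats::p.adjust(res["p", ], "bonferroni"),
             row.names = NULL)
}

#' Group comparison statistics
#'
#' The statistical tests used for the morphometric readouts: two-sided
#' Mann-Whitney (exact where possible), Welch's t, Kruskal-Wallis followed by
#' Dunn's pairwise test (Bonferroni-adjusted), and the Shapiro-Wilk normality
#' test on a single group.
#'
#' @param values_by_group named list of numeric vectors (one per group;
#'   \code{shapiro_wilk} uses the first)
#' @param method one of "mann_whitney", "welch_t", "kruskal_dunn",
#'   "shapiro_wilk"
#' @return list of class \code{group_comparison}: method, statistic, p_value,
#'   group_sizes, and \code{posthoc} table for kruskal_dunn
#' @export
compare_groups <- function(values_by_group,
                           method = c("mann_whitney", "welch_t",
                                      "kruskal_dunn", "shapiro_wilk")) {
  method <- match.arg(method)
  sizes <- lengths(values_by_group)
  need2 <- c(mann_whitney = 2, welch_t = 2, kruskal_dunn = 2,
             shapiro_wilk = 1)
  if (length(values_by_group) < need2[method])
    stop(method, " requires at least ", need2[method], " group(s)")
  min_n <- if (method == "shapiro_wilk") 3 else 3
  if (any(sizes[seq_len(need2[method])] < min_n))
    stop(method, " requires >= ", min_n, " observations per group")
  posthoc <- NULL
  if (method == "mann_whitney") {
    if (length(values_by_group) != 2) stop("mann_whitney takes exactly 2 groups")
    ht <- suppressWarnings(stats::wilcox.test(values_by_group[[1]],
                                              values_by_group[[2]]))
    stat <- unname(ht$statistic); p <- ht$p.value
  } else if (method == "welch_t") {
    if (length(values_by_group) != 2) stop("welch_t takes exactly 2 groups")
    ht <- stats::t.test(values_by_group[[1]], values_by_group[[2]],
                        var.equal = FALSE)
    stat <- unname(ht$statistic); p <- ht$p.value
  } else if (method == "kruskal_dunn") {
    ht <- stats::kruskal.test(values_by_group)
    stat <- unname(ht$statistic); p <- ht$p.value
    posthoc <- dunn_posthoc(values_by_group)
  } else {
    ht <- stats::shapiro.test(values_by_group[[1]])
    stat <- unname(ht$statistic); p <- ht$p.value
  }
  structure(list(method = method, statistic = stat, p_value = p,
                 group_sizes = sizes, posthoc = posthoc),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p_value, paste(x$group_sizes, collapse = ", ")))
  if (!is.null(x$posthoc)) print(x$posthoc)
  invisible(x)
}
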