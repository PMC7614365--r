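## Synthetic 3D spheroid image stacks: an epithelial shell between two radii
## with ellipsoidal nuclei whose major axes are radial (columnar, "epi") or
## tangential (squamous, "am"), carrying ground-truth orientation, thickness
## and channel intensities for recovery tests.

## near-uniform directions on the sphere (golden-spiral), deterministic
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

## orthonormal tangent frame for a unit radial vector
tangent_frame <- function(u) {
  a <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- c(u[2] * a[3] - u[3] * a[2], u[3] * a[1] - u[1] * a[3],
          u[1] * a[2] - u[2] * a[1])
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(u[2] * t1[3] - u[3] * t1[2], u[3] * t1[1] - u[1] * t1[3],
          u[1] * t1[2] - u[2] * t1[1])
  list(t1 = t1, t2 = t2)
}

#' Default spheroid stack geometry
#'
#' Columnar ("epi") spheroids: a thick shell (tall epithelium) with radially
#' elongated nuclei; squamous ("am") spheroids: a thin shell with
#' tangentially flattened nuclei — the roughly order-of-magnitude thickness
#' contrast between the two culture morphologies.
#'
#' @param kind "epi" or "am"
#' @return list: outer_um, inner_um, n_nuclei, semi_axes_um
#'   (major, mid, minor)
#' @export
default_stack_geometry <- function(kind = c("epi", "am")) {
  kind <- match.arg(kind)
  if (kind == "epi")
    list(outer_um = 30, inner_um = 14, n_nuclei = 40,
         semi_axes_um = c(4, 1.6, 1.6))
  else
    list(outer_um = 30, inner_um = 28, n_nuclei = 30,
         semi_axes_um = c(3.5, 2.2, 0.8))
}

#' Default channel specification
#' @return list: channel names, per-kind per-channel mean intensity, sd across
#'   nuclei
#' @export
default_channel_spec <- function() {
  list(names = c("DAPI", "SOX2", "TFAP2C"),
       means = list(epi = c(DAPI = 200, SOX2 = 150, TFAP2C = 10),
                    am  = c(DAPI = 200, SOX2 = 10, TFAP2C = 150)),
       sd = 10)
}

#' Simulate a 3D spheroid image stack
#'
#' Voxelizes an epithelial shell (inner/outer radius) and ellipsoidal nuclei
#' placed mid-shell on a near-uniform angular grid. Nuclear major axes are
#' radial for columnar ("epi") spheroids and tangential for squamous ("am")
#' ones. Per-nucleus channel intensities are drawn around the stated means;
#' the returned object carries the full ground truth.
#'
#' @param kind "epi" (columnar, radial nuclei) or "am" (squamous, tangential)
#' @param geometry list(outer_um, inner_um, n_nuclei, semi_axes_um); see
#'   \code{\link{default_stack_geometry}}
#' @param channel_spec list(names, means, sd); see
#'   \code{\link{default_channel_spec}}
#' @param voxel_um isotropic voxel size (micrometres); anisotropic z via
#'   \code{voxel_z_um}
#' @param voxel_z_um z spacing (defaults to \code{voxel_um})
#' @param seed integer seed
#' @return object of class \code{spheroid_stack}: \code{voxels} array
#'   (z, y, x, channel), \code{labels} (z, y, x) nucleus label volume,
#'   \code{shell_mask}, \code{voxel_um} (z, y, x), \code{centroid_um},
#'   \code{channels}, \code{truth} data.frame (nucleus, centroid, ground-truth
#'   orientation angle, per-channel intensity), \code{thickness_um}, \code{kind}
#' @export
make_spheroid_stack <- function(kind = c("epi", "am"),
                                geometry = default_stack_geometry(kind),
                                channel_spec = default_channel_spec(),
                                voxel_um = 0.8, voxel_z_um = voxel_um,
                                seed = 1L) {
  kind <- match.arg(kind)
  g <- geometry
  if (g$inner_um >= g$outer_um) stop("inner radius must be < outer radius")
  r_mid <- (g$inner_um + g$outer_um) / 2
  a <- g$semi_axes_um
  ## feasibility: nuclei occupy at most ~60% of the mid-shell sphere area
  footprint <- pi * max(a[2], a[3]) * a[1]
  if (kind == "epi") footprint <- pi * a[2] * a[3]
  if (g$n_nuclei * footprint > 0.6 * 4 * pi * r_mid^2)
    stop(sprintf("nucleus count %d infeasible for the shell surface", g$n_nuclei))

  half <- g$outer_um + 2 * max(a)
  nx <- ny <- as.integer(ceiling(2 * half / voxel_um))
  nz <- as.integer(ceiling(2 * half / voxel_z_um))
  ## voxel-centre coordinates relative to the spheroid centre
  xs <- (seq_len(nx) - (nx + 1) / 2) * voxel_um
  ys <- (seq_len(ny) - (ny + 1) / 2) * voxel_um
  zs <- (seq_len(nz) - (nz + 1) / 2) * voxel_z_um

  chn <- channel_spec$names
  voxels <- array(0, dim = c(nz, ny, nx, length(chn)))
  labels <- array(0L, dim = c(nz, ny, nx))

  ## shell mask on voxel centres
  r2 <- outer(outer(zs^2, ys^2, "+"), xs^2, "+")   # dim (z, y, x)
  shell <- r2 > g$inner_um^2 & r2 <= g$outer_um^2

  withr::with_seed(as.integer(seed), {
    dirs <- fibonacci_directions(g$n_nuclei)
    ## seeded tangential jitter keeps placements distinct across seeds
    jitter <- matrix(stats::rnorm(3 * g$n_nuclei, sd = 0.02), ncol = 3)
    dirs <- dirs + jitter
    dirs <- dirs / sqrt(rowSums(dirs^2))
    means <- channel_spec$means[[kind]][chn]
    intens <- vapply(seq_along(chn), function(k)
      pmax(stats::rnorm(g$n_nuclei, means[k], channel_spec$sd), 0),
      numeric(g$n_nuclei))
  })
  colnames(intens) <- chn

  truth <- data.frame(nucleus = seq_len(g$n_nuclei),
                      cx = NA_real_, cy = NA_real_, cz = NA_real_,
                      angle_deg = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(chn)) truth[[chn[k]]] <- intens[, k]

  for (i in seq_len(g$n_nuclei)) {
    u <- dirs[i, ]
    ctr <- u * r_mid
    fr <- tangent_frame(u)
    if (kind == "epi") {
      ax1 <- u; ax2 <- fr$t1; ax3 <- fr$t2       # major axis radial
      truth$angle_deg[i] <- 0
    } else {
      ax1 <- fr$t1; ax2 <- fr$t2; ax3 <- u       # major axis tangential
      truth$angle_deg[i] <- 90
    }
    truth$cx[i] <- ctr[1]; truth$cy[i] <- ctr[2]; truth$cz[i] <- ctr[3]
    ix <- which(abs(xs - ctr[1]) <= a[1] + voxel_um)
    iy <- which(abs(ys - ctr[2]) <= a[1] + voxel_um)
    iz <- which(abs(zs - ctr[3]) <= a[1] + voxel_z_um)
    for (zz in iz) for (yy in iy) {
      d <- cbind(xs[ix] - ctr[1], ys[yy] - ctr[2], zs[zz] - ctr[3])
      q <- (d %*% ax1 / a[1])^2 + (d %*% ax2 / a[2])^2 + (d %*% ax3 / a[3])^2
      inside <- which(q <= 1)
      if (length(inside)) {
        labels[zz, yy, ix[inside]] <- i
        for (k in seq_along(chn))
          voxels[zz, yy, ix[inside], k] <- intens[i, k]
      }
    }
  }

  structure(list(voxels = voxels, labels = labels, shell_mask = shell,
                 voxel_um = c(z = voxel_z_um, y = voxel_um, x = voxel_um),
                 centroid_um = c(z = 0, y = 0, x = 0),
                 origin_um = c(z = zs[1], y = ys[1], x = xs[1]),
                 channels = chn, truth = truth,
                 thickness_um = g$outer_um - g$inner_um,
                 geometry = g, kind = kind, seed = as.integer(seed)),
            class = "spheroid_stack")
}

#' @export
print.spheroid_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("spheroid_stack (%s): %d x %d x %d voxels, %d channels, %d nuclei, thickness %.1f um\n",
              x$kind, d[1], d[2], d[3], d[4], nrow(x$truth), x$thickness_um))
  invisible(x)
}

#' Write a spheroid stack as multi-page TIFFs
#'
#' One 32-bit float multi-page TIFF per channel (pages = z slices), a label
#' TIFF, and a CSV of the ground truth plus a small JSON manifest with voxel
#' sizes.
#'
#' @param stack a \code{spheroid_stack}
#' @param dir output directory
#' @export
write_stack_tiff <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nz <- dim(stack$voxels)[1]
  ## TIFF floats live in [0, 1]: store a per-file scale in the manifest
  int_scale <- max(stack$voxels, 1)
  for (k in seq_along(stack$channels)) {
    pages <- lapply(seq_len(nz), function(z) stack$voxels[z, , , k] / int_scale)
    tiff::writeTIFF(pages, file.path(dir, paste0(stack$channels[k], ".tiff")),
                    bits.per.sample = 32L, reduce = FALSE)
  }
  lab_scale <- max(stack$labels, 1)
  pages <- lapply(seq_len(nz), function(z) stack$labels[z, , ] / lab_scale)
  tiff::writeTIFF(pages, file.path(dir, "labels.tiff"),
                  bits.per.sample = 32L, reduce = FALSE)
  utils::write.csv(stack$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(list(channels = stack$channels,
                            voxel_um = as.list(stack$voxel_um),
                            kind = stack$kind,
                            thickness_um = stack$thickness_um,
                            intensity_scale = int_scale,
                            label_scale = lab_scale),
                       file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a spheroid stack written by \code{\link{write_stack_tiff}}
#' @param dir directory
#' @return a \code{spheroid_stack} (shell mask reconstructed from labels'
#'   bounding radii is not attempted; it is NULL for stacks read from disk)
#' @export
read_stack_tiff <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "stack.json"), simplifyVector = TRUE)
  chn <- man$channels
  rd <- function(f) {
    pages <- tiff::readTIFF(f, all = TRUE)
    array(unlist(pages), dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                                 length(pages)))
  }
  vol1 <- rd(file.path(dir, paste0(chn[1], ".tiff")))  # (y, x, z)
  nz <- dim(vol1)[3]
  voxels <- array(0, dim = c(nz, dim(vol1)[1], dim(vol1)[2], length(chn)))
  for (k in seq_along(chn)) {
    v <- if (k == 1) vol1 else rd(file.path(dir, paste0(chn[k], ".tiff")))
    voxels[, , , k] <- aperm(v, c(3, 1, 2)) * man$intensity_scale
  }
  lab <- aperm(rd(file.path(dir, "labels.tiff")), c(3, 1, 2)) * man$label_scale
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  structure(list(voxels = voxels, labels = round(lab), shell_mask = NULL,
                 voxel_um = unlist(man$voxel_um),
                 centroid_um = c(z = 0, y = 0, x = 0),
                 origin_um = NULL, channels = chn, truth = truth,
                 thickness_um = man$thickness_um, geometry = NULL,
                 kind = man$kind, seed = NA_integer_),
            class = "spheroid_stack")
}
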