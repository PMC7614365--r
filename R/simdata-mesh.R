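#' Synthetic embryo surface mesh
#'
#' Builds a closed triangulated surface made of two opposing spherical caps
#' joined at a common rim: a deep cap standing in for the columnar embryonic
#' disc and a shallower (flattened) cap standing in for the squamous amnion.
#' Vertices are partitioned into four regions: the embryonic disc is split
#' anterior/posterior along one tangential axis (x), the amnion is split
#' proximal (near the rim) / distal (near the pole) by polar angle.
#'
#' @param n_vertices target number of vertices (>= 50); the structured
#'   ring/segment construction lands within a few vertices of the target.
#' @param radius_um rim radius of the embryo in micrometres.
#' @param seed integer seed; a small seeded jitter is applied to vertex
#'   positions so distinct seeds give distinct (but reproducible) meshes.
#' @param amnion_flatten factor in (0, 1] flattening the amnion cap along z.
#' @param jitter_frac radial jitter amplitude as a fraction of the radius.
#' @return an object of class \code{embryo_mesh}: list with \code{vertices}
#'   (n x 3 matrix, micrometres), \code{faces} (m x 3 integer matrix, 1-based),
#'   \code{region} (character per vertex), \code{polar} (polar angle from the
#'   amnion pole, radians, pre-flattening), \code{stage} (stage tag).
#' @export
make_embryo_mesh <- function(n_vertices, radius_um = 100, seed = 1L,
                             amnion_flatten = 0.45, jitter_frac = 0.02,
                             stage = "CS6") {
  if (!is.numeric(n_vertices) || n_vertices < 50)
    stop("n_vertices must be >= 50 to populate all four regions")
  stopifnot(radius_um > 0, amnion_flatten > 0, amnion_flatten <= 1)

  ## ring/segment sphere: 2 poles + n_rings rings of n_seg vertices
  n_seg   <- max(8L, as.integer(round(sqrt(2 * n_vertices))))
  n_rings <- max(7L, as.integer(round((n_vertices - 2) / n_seg)))

  theta <- seq_len(n_rings) * pi / (n_rings + 1)   # polar angle from +z pole
  phi   <- (seq_len(n_seg) - 1) * 2 * pi / n_seg

  verts <- matrix(0, nrow = 2 + n_rings * n_seg, ncol = 3)
  polar <- numeric(nrow(verts))
  verts[1, ] <- c(0, 0, radius_um)                  # amnion pole
  polar[1] <- 0
  for (i in seq_len(n_rings)) {
    idx <- 1 + (i - 1) * n_seg + seq_len(n_seg)
    verts[idx, 1] <- radius_um * sin(theta[i]) * cos(phi)
    verts[idx, 2] <- radius_um * sin(theta[i]) * sin(phi)
    verts[idx, 3] <- radius_um * cos(theta[i])
    polar[idx] <- theta[i]
  }
  n <- nrow(verts)
  verts[n, ] <- c(0, 0, -radius_um)                 # disc pole
  polar[n] <- pi

  ## faces: pole fans + ring quads split into triangles
  faces <- vector("list", 2 * n_seg + 2 * n_seg * (n_rings - 1))
  k <- 0L
  ring <- function(i) 1 + (i - 1) * n_seg + seq_len(n_seg)
  r1 <- ring(1)
  for (j in seq_len(n_seg)) {
    k <- k + 1L
    faces[[k]] <- c(1L, r1[j], r1[if (j == n_seg) 1L else j + 1L])
  }
  for (i in seq_len(n_rings - 1)) {
    a <- ring(i); b <- ring(i + 1)
    for (j in seq_len(n_seg)) {
      jn <- if (j == n_seg) 1L else j + 1L
      k <- k + 1L; faces[[k]] <- c(a[j], b[j], b[jn])
      k <- k + 1L; faces[[k]] <- c(a[j], b[jn], a[jn])
    }
  }
  rl <- ring(n_rings)
  for (j in seq_len(n_seg)) {
    k <- k + 1L
    faces[[k]] <- c(n, rl[if (j == n_seg) 1L else j + 1L], rl[j])
  }
  faces <- do.call(rbind, faces)
  storage.mode(faces) <- "integer"

  ## seeded jitter (radial), then flatten the amnion cap (z > 0)
  withr::with_seed(as.integer(seed), {
    jit <- 1 + stats::runif(n, -jitter_frac, jitter_frac)
  })
  verts <- verts * jit
  up <- verts[, 3] > 0
  verts[up, 3] <- verts[up, 3] * amnion_flatten

  region <- character(n)
  am <- polar < pi / 2 - 1e-9
  region[am  & polar <  pi / 4] <- "Am_distal"
  region[am  & polar >= pi / 4] <- "Am_proximal"
  region[!am & verts[, 1] >= 0] <- "EmDisc_anterior"
  region[!am & verts[, 1] <  0] <- "EmDisc_posterior"

  counts <- table(factor(region, levels = embryo_regions()))
  if (any(counts == 0))
    stop("n_vertices too small: empty region(s): ",
         paste(names(counts)[counts == 0], collapse = ", "))

  structure(list(vertices = verts, faces = faces, region = region,
                 polar = polar, stage = stage),
            class = "embryo_mesh")
}

#' The four embryo surface regions
#' @return character vector of region labels in canonical order.
#' @export
embryo_regions <- function() {
  c("EmDisc_anterior", "EmDisc_posterior", "Am_proximal", "Am_distal")
}

#' @export
print.embryo_mesh <- function(x, ...) {
  cat("embryo_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces, stage", x$stage, "\n")
  print(table(x$region))
  invisible(x)
}

#' Mesh edge lengths
#' @param mesh an \code{embryo_mesh}
#' @return numeric vector of unique edge lengths (micrometres).
#' @export
mesh_edge_lengths <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- unique(t(apply(e, 1, sort)))
  sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                mesh$vertices[e[, 2], , drop = FALSE])^2))
}

#' Mesh diameter (maximum pairwise vertex distance)
#' @param mesh an \code{embryo_mesh}
#' @return scalar, micrometres.
#' @export
mesh_diameter <- function(mesh) {
  max(stats::dist(mesh$vertices))
}

## connected components over the face graph (used by validity checks/tests)
mesh_n_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[r, ]
    a <- find(f[1]); b <- find(f[2]); c3 <- find(f[3])
    parent[b] <- a; parent[c3] <- a
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Write a mesh as PLY
#'
#' Writes vertices, faces and a per-vertex integer \code{region} property
#' (index into \code{\link{embryo_regions}}). Optionally a per-vertex scalar
#' \code{value} and RGB colour (used by the field exporters).
#'
#' @param mesh an \code{embryo_mesh}
#' @param path output file path
#' @param binary write binary little-endian PLY instead of ASCII
#' @param value optional numeric per-vertex scalar stored as property `value`
#' @param rgb optional n x 3 integer matrix (0-255) of vertex colours
#' @export
write_mesh_ply <- function(mesh, path, binary = FALSE, value = NULL, rgb = NULL) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$faces)
  reg <- match(mesh$region, embryo_regions()) - 1L
  if (!is.null(value)) stopifnot(length(value) == n)
  if (!is.null(rgb)) stopifnot(nrow(rgb) == n, ncol(rgb) == 3)
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z",
           "property int region",
           if (!is.null(value)) "property float value",
           if (!is.null(rgb)) c("property uchar red", "property uchar green",
                                "property uchar blue"),
           sprintf("element face %d", m),
           "property list uchar int vertex_indices",
           "end_header")
  if (!binary) {
    vl <- sprintf("%.6f %.6f %.6f %d", mesh$vertices[, 1], mesh$vertices[, 2],
                  mesh$vertices[, 3], reg)
    if (!is.null(value)) vl <- paste(vl, sprintf("%.6f", value))
    if (!is.null(rgb)) vl <- paste(vl, rgb[, 1], rgb[, 2], rgb[, 3])
    fl <- sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                  mesh$faces[, 3] - 1L)
    writeLines(c(hdr, vl, fl), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    for (i in seq_len(n)) {
      writeBin(as.numeric(mesh$vertices[i, ]), con, size = 4, endian = "little")
      writeBin(as.integer(reg[i]), con, size = 4, endian = "little")
      if (!is.null(value))
        writeBin(as.numeric(value[i]), con, size = 4, endian = "little")
      if (!is.null(rgb))
        writeBin(as.raw(rgb[i, ]), con)
    }
    for (i in seq_len(m)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' Read a PLY mesh written by \code{\link{write_mesh_ply}}
#'
#' A deliberately small reader covering the subset of PLY this package writes
#' (x/y/z float, int region, optional float value, uchar rgb; uchar-int face
#' lists), in ASCII or binary little-endian form.
#'
#' @param path PLY file path
#' @param stage stage tag to attach (PLY carries none)
#' @return an \code{embryo_mesh}
#' @export
read_mesh_ply <- function(path, stage = "CS6") {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln)) stop("malformed PLY: no end_header")
    hdr <- c(hdr, ln)
    if (ln == "end_header") break
  }
  fmt <- sub("^format ([a-z_]+) .*$", "\\1", grep("^format", hdr, value = TRUE))
  n <- as.integer(sub("^element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  m <- as.integer(sub("^element face ", "", grep("^element face", hdr, value = TRUE)))
  ## vertex property layout in header order
  vstart <- grep("^element vertex", hdr)
  vend <- grep("^element face", hdr)
  props <- grep("^property ", hdr[vstart:vend], value = TRUE)
  pnames <- sub("^property [a-z0-9]+ ", "", props)
  ptypes <- sub("^property ([a-z0-9]+) .*$", "\\1", props)
  if (fmt == "ascii") {
    lines <- readLines(con)
    vl <- do.call(rbind, lapply(strsplit(lines[seq_len(n)], " +"), as.numeric))
    colnames(vl) <- pnames
    fl <- do.call(rbind, lapply(strsplit(lines[n + seq_len(m)], " +"), as.integer))
    faces <- fl[, 2:4, drop = FALSE] + 1L
  } else if (fmt == "binary_little_endian") {
    vl <- matrix(0, n, length(pnames), dimnames = list(NULL, pnames))
    for (i in seq_len(n)) for (j in seq_along(pnames)) {
      vl[i, j] <- switch(ptypes[j],
        float = readBin(con, "numeric", 1, size = 4, endian = "little"),
        int   = readBin(con, "integer", 1, size = 4, endian = "little"),
        uchar = as.integer(readBin(con, "raw", 1)),
        stop("unsupported PLY property type: ", ptypes[j]))
    }
    faces <- matrix(0L, m, 3)
    for (i in seq_len(m)) {
      cnt <- as.integer(readBin(con, "raw", 1))
      if (cnt != 3L) stop("non-triangular face in PLY")
      faces[i, ] <- readBin(con, "integer", 3, size = 4, endian = "little") + 1L
    }
  } else stop("unsupported PLY format: ", fmt)
  verts <- vl[, c("x", "y", "z"), drop = FALSE]
  region <- embryo_regions()[vl[, "region"] + 1L]
  ## recover polar angle from pre-flattening geometry is impossible in
  ## general; recompute from the unflattened proxy (angle in the x/y/|r| frame)
  r_xy <- sqrt(verts[, 1]^2 + verts[, 2]^2)
  polar <- atan2(r_xy, verts[, 3])
  structure(list(vertices = unname(verts), faces = faces, region = region,
                 polar = polar, stage = stage),
            class = "embryo_mesh")
}
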