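## Triangulated surface meshes used by the mapping modules.  Vertices are in
## millimetres; faces are 1-based vertex index triples.

#' Create a triangulated surface mesh
#'
#' @param vertices numeric matrix (n x 3), coordinates in mm.
#' @param faces integer matrix (m x 3), 1-based vertex indices.
#' @return An object of class `ep_mesh`.
#' @export
ep_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  .assert(ncol(vertices) == 3, "vertices must be an n x 3 matrix")
  .assert(ncol(faces) == 3, "faces must be an m x 3 matrix")
  .assert(max(faces) <= nrow(vertices) && min(faces) >= 1,
          "face indices out of range")
  areas <- mesh_face_areas(vertices, faces)
  if (any(areas <= .Machine$double.eps * 100))
    stop("mesh contains zero-area (degenerate) triangles", call. = FALSE)
  structure(list(vertices = vertices, faces = faces),
            class = "ep_mesh")
}

mesh_face_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a
  v <- c - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Flat rectangular patch mesh in the z = 0 plane
#'
#' @param width,height extents in mm.
#' @param spacing target vertex spacing in mm.
#' @return An `ep_mesh`.
#' @export
flat_patch_mesh <- function(width = 40, height = 40, spacing = 2) {
  nx <- max(2L, round(width / spacing) + 1L)
  ny <- max(2L, round(height / spacing) + 1L)
  xs <- seq(0, width, length.out = nx)
  ys <- seq(0, height, length.out = ny)
  vertices <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  faces <- matrix(0L, nrow = 2L * (nx - 1L) * (ny - 1L), ncol = 3L)
  k <- 1L
  for (j in seq_len(ny - 1L)) {
    for (i in seq_len(nx - 1L)) {
      v00 <- (j - 1L) * nx + i
      v10 <- v00 + 1L
      v01 <- v00 + nx
      v11 <- v01 + 1L
      faces[k, ] <- c(v00, v10, v11); k <- k + 1L
      faces[k, ] <- c(v00, v11, v01); k <- k + 1L
    }
  }
  ep_mesh(vertices, faces)
}

#' Spherical-cap patch mesh
#'
#' A curved test surface: the cap of a sphere of radius `radius` subtending
#' half-angle `cap_angle` (degrees), triangulated over a polar grid.
#'
#' @param radius sphere radius in mm.
#' @param cap_angle half-angle of the cap in degrees.
#' @param spacing target vertex spacing in mm.
#' @return An `ep_mesh`.
#' @export
spherical_cap_mesh <- function(radius = 30, cap_angle = 45, spacing = 2) {
  theta_max <- cap_angle * pi / 180
  n_rings <- max(2L, ceiling(radius * theta_max / spacing))
  verts <- matrix(c(0, 0, radius), ncol = 3)   # pole
  ring_start <- integer(n_rings)
  for (r in seq_len(n_rings)) {
    theta <- theta_max * r / n_rings
    circ <- 2 * pi * radius * sin(theta)
    n_phi <- max(3L, ceiling(circ / spacing))
    phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
    ring_start[r] <- nrow(verts) + 1L
    verts <- rbind(verts, cbind(radius * sin(theta) * cos(phi),
                                radius * sin(theta) * sin(phi),
                                radius * cos(theta)))
  }
  ## connect pole to ring 1, then consecutive rings, by nearest-angle fans
  faces <- NULL
  r1 <- ring_start[1]
  n1 <- (if (n_rings > 1) ring_start[2] else nrow(verts) + 1L) - r1
  for (i in seq_len(n1)) {
    faces <- rbind(faces, c(1L, r1 + i - 1L, r1 + (i %% n1)))
  }
  for (r in seq_len(n_rings - 1L)) {
    a0 <- ring_start[r]
    b0 <- ring_start[r + 1L]
    na <- b0 - a0
    nb <- (if (r + 1L < n_rings) ring_start[r + 2L] else nrow(verts) + 1L) - b0
    ## stitch rings with a merge walk over angular position
    ia <- 0L; ib <- 0L
    while (ia < na || ib < nb) {
      pa <- (ia + 0.5) / na
      pb <- (ib + 0.5) / nb
      if (ib >= nb || (ia < na && pa <= pb)) {
        faces <- rbind(faces, c(a0 + ia, b0 + (ib %% nb), a0 + ((ia + 1L) %% na)))
        ia <- ia + 1L
      } else {
        faces <- rbind(faces, c(b0 + ib, b0 + ((ib + 1L) %% nb), a0 + (ia %% na)))
        ib <- ib + 1L
      }
    }
  }
  ep_mesh(verts, faces)
}

#' Sample electrode positions on a mesh surface
#'
#' Poisson-disk (dart-throwing) sampling at a requested areal density,
#' mimicking the irregular coverage of multielectrode mapping catheters.
#'
#' @param mesh an `ep_mesh`.
#' @param density electrodes per cm^2.
#' @param seed integer RNG seed.
#' @return matrix (n x 3) of electrode coordinates in mm, on the surface.
#' @export
sample_electrodes <- function(mesh, density = 2, seed = 1) {
  .assert(density > 0, "density must be positive")
  areas <- mesh_face_areas(mesh$vertices, mesh$faces)
  total_cm2 <- sum(areas) / 100
  n_target <- max(4L, round(density * total_cm2))
  r_min <- 0.65 * sqrt(sum(areas) / n_target)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ## oversample candidate points uniformly by area, then dart-throw
  n_cand <- n_target * 30L
  fidx <- sample.int(nrow(mesh$faces), n_cand, replace = TRUE,
                     prob = areas / sum(areas))
  r1 <- sqrt(runif(n_cand)); r2 <- runif(n_cand)
  a <- mesh$vertices[mesh$faces[fidx, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[fidx, 2], , drop = FALSE]
  c <- mesh$vertices[mesh$faces[fidx, 3], , drop = FALSE]
  pts <- (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * c
  keep <- matrix(NA_real_, nrow = 0, ncol = 3)
  for (i in seq_len(n_cand)) {
    p <- pts[i, ]
    if (nrow(keep) == 0 ||
        min(sqrt(colSums((t(keep) - p)^2))) >= r_min) {
      keep <- rbind(keep, p)
      if (nrow(keep) >= n_target) break
    }
  }
  dimnames(keep) <- NULL
  keep
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write / read a mesh as ASCII PLY
#'
#' @param mesh an `ep_mesh`.
#' @param path output file.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(mesh$vertices, trim = TRUE, digits = 9), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  hdr <- which(lines == "end_header")
  vl <- lines[(hdr + 1):(hdr + nv)]
  fl <- lines[(hdr + nv + 1):(hdr + nv + nf)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), as.numeric))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"),
                                 function(x) as.integer(x[2:4]) + 1L))
  ep_mesh(verts, faces)
}
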