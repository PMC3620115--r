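#' Closed triangular surface mesh
#'
#' Constructs a `surface_mesh`: vertices in millimetres, triangles as
#' vertex-index triples, and per-triangle outward unit normals. Tissue
#' regions are bounded by such meshes; a valid region boundary must be
#' closed (every edge shared by exactly two triangles), free of degenerate
#' triangles, and oriented outward (positive signed volume).
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param triangles integer matrix, m x 3, 1-based vertex indices, ordered
#'   counter-clockwise when viewed from outside.
#' @param validate logical; check closedness, orientation and degeneracy.
#' @return an object of class `surface_mesh` with elements `vertices`,
#'   `triangles`, `normals`, `areas`.
#' @export
surface_mesh <- function(vertices, triangles, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  if (any(triangles < 1L) || any(triangles > nrow(vertices)))
    stop("triangle indices out of range")
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c3 <- vertices[triangles[, 3], , drop = FALSE]
  cr <- row_cross(b - a, c3 - a)
  twoA <- sqrt(rowSums(cr^2))
  if (validate && any(twoA < 1e-12))
    stop("mesh contains degenerate (zero-area) triangles")
  normals <- cr / pmax(twoA, 1e-300)
  m <- structure(
    list(vertices = vertices, triangles = triangles,
         normals = normals, areas = twoA / 2),
    class = "surface_mesh")
  if (validate) {
    if (!mesh_is_closed(m))
      stop("mesh is not closed: every edge must be shared by exactly 2 triangles")
    if (mesh_volume(m) <= 0)
      stop("mesh is inward-oriented (non-positive signed volume); flip triangle winding")
  }
  m
}

row_cross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  cat(sprintf("  enclosed volume %.6g mm^3, area %.6g mm^2\n",
              mesh_volume(x), sum(x$areas)))
  invisible(x)
}

#' Signed enclosed volume of a closed mesh (mm^3)
#'
#' Sum of signed tetrahedra against the origin; positive for outward
#' orientation.
#' @param mesh a `surface_mesh`.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c3 <- v[tr[, 3], , drop = FALSE]
  sum(rowSums(a * row_cross(b, c3))) / 6
}

#' Is every mesh edge shared by exactly two triangles?
#' @param mesh a `surface_mesh`.
#' @export
mesh_is_closed <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Axis-aligned cube phantom mesh
#'
#' Closed, outward-oriented cube centred at `center`, with each face split
#' into `subdivisions^2` quads of two triangles each (12 * subdivisions^2
#' triangles total). The 10 mm homogeneous cube used by the packaged
#' bioluminescence example is `make_cube_phantom(10)`.
#'
#' @param side edge length in mm (> 0).
#' @param subdivisions subdivisions per edge (>= 1).
#' @param center cube centre, length-3 numeric.
#' @return a `surface_mesh`.
#' @examples
#' m <- make_cube_phantom(10)
#' mesh_volume(m)  # 1000
#' @export
make_cube_phantom <- function(side, subdivisions = 1L, center = c(0, 0, 0)) {
  if (!is.numeric(side) || length(side) != 1L || !is.finite(side) || side <= 0)
    stop("side must be a positive number")
  subdivisions <- as.integer(subdivisions)
  if (is.na(subdivisions) || subdivisions < 1L)
    stop("subdivisions must be >= 1")
  h <- side / 2
  s <- seq(-h, h, length.out = subdivisions + 1L)
  verts <- list(); tris <- list(); nv <- 0L
  # each face: fixed axis ax at sign sg; spanning axes u < v;
  # winding chosen so the normal points along sg * ax
  for (ax in 1:3) for (sg in c(-1, 1)) {
    sp <- setdiff(1:3, ax)
    g <- as.matrix(expand.grid(u = s, v = s))
    p <- matrix(0, nrow(g), 3)
    p[, ax] <- sg * h
    p[, sp[1]] <- g[, 1]
    p[, sp[2]] <- g[, 2]
    n1 <- subdivisions + 1L
    idx <- function(i, j) (j - 1L) * n1 + i  # i over u, j over v
    ft <- matrix(0L, 0, 3)
    for (j in 1:subdivisions) for (i in 1:subdivisions) {
      q <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
      ft <- rbind(ft, q[c(1, 2, 3)], q[c(1, 3, 4)])
    }
    # orient: normal of (p1,p2,p3) for this winding is +cross(u_dir,v_dir)
    # which points along sp-axis cross product; flip when needed
    e1 <- p[ft[1, 2], ] - p[ft[1, 1], ]
    e2 <- p[ft[1, 3], ] - p[ft[1, 1], ]
    nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
             e1[3] * e2[1] - e1[1] * e2[3],
             e1[1] * e2[2] - e1[2] * e2[1])
    if (nrm[ax] * sg < 0) ft <- ft[, c(1, 3, 2)]
    verts[[length(verts) + 1L]] <- p
    tris[[length(tris) + 1L]] <- ft + nv
    nv <- nv + nrow(p)
  }
  V <- do.call(rbind, verts)
  F1 <- do.call(rbind, tris)
  # merge duplicated vertices along cube edges so the mesh closes
  key <- apply(round(V, 9), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  V <- V[uk, , drop = FALSE]
  F1 <- matrix(map[F1], ncol = 3)
  V <- sweep(V, 2, as.numeric(center), "+")
  surface_mesh(V, F1)
}

#' Ellipsoid (icosphere) mesh
#'
#' Subdivided icosahedron projected to the unit sphere, then scaled to the
#' requested semi-axes and translated. Enclosed volume converges to
#' (4/3) * pi * a * b * c as refinement grows.
#'
#' @param semi_axes length-3 positive numeric (mm).
#' @param center length-3 numeric (mm).
#' @param refinement number of 4-to-1 subdivision passes (>= 0).
#' @return a `surface_mesh` with `20 * 4^refinement` triangles.
#' @export
make_ellipsoid_mesh <- function(semi_axes, center = c(0, 0, 0), refinement = 3L) {
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3L || any(!is.finite(semi_axes)) || any(semi_axes <= 0))
    stop("semi_axes must be three positive numbers")
  refinement <- as.integer(refinement)
  if (is.na(refinement) || refinement < 0L) stop("refinement must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(1 + phi^2)
  F1 <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (r in seq_len(refinement)) {
    mids <- new.env(hash = TRUE)
    Vl <- lapply(seq_len(nrow(V)), function(i) V[i, ])
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      got <- mids[[key]]
      if (!is.null(got)) return(got)
      p <- (Vl[[i]] + Vl[[j]]) / 2
      p <- p / sqrt(sum(p^2))
      Vl[[length(Vl) + 1L]] <<- p
      id <- length(Vl)
      assign(key, id, envir = mids)
      id
    }
    F2 <- matrix(0L, 0, 3)
    Fn <- vector("list", nrow(F1))
    for (k in seq_len(nrow(F1))) {
      i <- F1[k, 1]; j <- F1[k, 2]; l <- F1[k, 3]
      a <- midpoint(i, j); b <- midpoint(j, l); c3 <- midpoint(l, i)
      Fn[[k]] <- rbind(c(i, a, c3), c(j, b, a), c(l, c3, b), c(a, b, c3))
    }
    F1 <- do.call(rbind, Fn)
    V <- do.call(rbind, Vl)
  }
  V <- sweep(V %*% diag(semi_axes), 2, as.numeric(center), "+")
  surface_mesh(V, F1)
}

#' Sphere mesh (equal semi-axes ellipsoid)
#' @inheritParams make_ellipsoid_mesh
#' @param radius sphere radius (mm).
#' @export
make_sphere_mesh <- function(radius, center = c(0, 0, 0), refinement = 3L) {
  make_ellipsoid_mesh(rep(radius, 3), center, refinement)
}

#' Map a cube-face exit point to transmittance-grid bin indices
#'
#' Each cube face is recorded as a rows x cols matrix (the packaged
#' bioluminescence example uses 300 x 300). The face chart spans the two
#' axes orthogonal to the face, rows along the lower axis index, origin at
#' the minimal corner; `bin = floor(local / delta)` clamped to the last bin
#' on the maximal edge. Indices are 0-based, matching the recorder arrays.
#'
#' @param hit_point length-3 point on the face (mm).
#' @param face one of `"x-","x+","y-","y+","z-","z+"`.
#' @param grid integer c(rows, cols).
#' @param side cube edge length (mm).
#' @param center cube centre.
#' @param eps tolerance for the on-face test (mm).
#' @return integer c(row, col), 0-based.
#' @export
face_grid_index <- function(hit_point, face, grid, side, center = c(0, 0, 0),
                            eps = 1e-6) {
  faces <- c("x-" = 1, "x+" = 1, "y-" = 2, "y+" = 2, "z-" = 3, "z+" = 3)
  if (!face %in% names(faces)) stop("unknown face id: ", face)
  ax <- faces[[face]]
  sg <- if (grepl("\\+", face)) 1 else -1
  l <- as.numeric(hit_point) - as.numeric(center)
  h <- side / 2
  if (abs(l[ax] - sg * h) > eps)
    stop("point does not lie on face ", face, " within eps")
  sp <- setdiff(1:3, ax)
  u <- l[sp[1]] + h
  v <- l[sp[2]] + h
  if (u < -eps || v < -eps || u > side + eps || v > side + eps)
    stop("point is outside the face extent")
  du <- side / grid[1]; dv <- side / grid[2]
  row <- min(max(floor(u / du), 0), grid[1] - 1)
  col <- min(max(floor(v / dv), 0), grid[2] - 1)
  as.integer(c(row, col))
}
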