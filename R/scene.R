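#' Optical properties of a turbid medium
#'
#' Absorption coefficient `mu_a` and scattering coefficient `mu_s`
#' (mm^-1), Henyey-Greenstein anisotropy factor `g` (mean cosine of the
#' single-scattering deflection angle), and refractive index `n`.
#'
#' @param mu_a absorption coefficient, mm^-1, >= 0.
#' @param mu_s scattering coefficient, mm^-1, >= 0.
#' @param g anisotropy factor, strictly inside (-1, 1).
#' @param n refractive index, >= 1.
#' @return an `optical_props` object.
#' @examples
#' optical_props(mu_a = 0.0002, mu_s = 11.7, g = 0.95, n = 1.37)
#' @export
optical_props <- function(mu_a, mu_s, g, n) {
  stopifnot(length(mu_a) == 1, length(mu_s) == 1, length(g) == 1, length(n) == 1)
  if (!is.finite(mu_a) || mu_a < 0) stop("mu_a must be >= 0")
  if (!is.finite(mu_s) || mu_s < 0) stop("mu_s must be >= 0")
  if (!is.finite(g) || abs(g) >= 1) stop("g must lie strictly in (-1, 1)")
  if (!is.finite(n) || n < 1) stop("n must be >= 1")
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n),
            class = "optical_props")
}

#' @export
print.optical_props <- function(x, ...) {
  cat(sprintf("optical_props: mu_a=%g mm^-1, mu_s=%g mm^-1, g=%g, n=%g\n",
              x$mu_a, x$mu_s, x$g, x$n))
  invisible(x)
}

#' Tissue region
#'
#' A region is a closed mesh boundary with the optical properties of the
#' medium inside it, nested under a parent region (or the ambient medium).
#'
#' @param id character label, unique within a scene.
#' @param mesh a [surface_mesh()].
#' @param props an [optical_props()] for the primary (or excitation) band.
#' @param parent id of the enclosing region, or `"ambient"`.
#' @param emission_props optional [optical_props()] at the emission
#'   wavelength (fluorescence runs).
#' @export
region <- function(id, mesh, props, parent = "ambient", emission_props = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(props, "optical_props"))
  if (!is.null(emission_props)) stopifnot(inherits(emission_props, "optical_props"))
  structure(list(id = as.character(id), mesh = mesh, props = props,
                 parent = as.character(parent),
                 emission_props = emission_props),
            class = "mc_region")
}

#' Scene of nested tissue regions
#'
#' Validates that region containment forms a tree rooted at the ambient
#' medium with a unique outermost boundary, checks that every photon-
#' reachable region has `mu_a + mu_s > 0`, and compiles the triangle soup
#' (with per-triangle inside/outside region labels) for the C++ ray-tracing
#' core. Meshes with more than 1000 triangles are traced through an AABB
#' bounding-volume hierarchy.
#'
#' @param regions list of [region()] objects.
#' @param ambient_n refractive index of the surrounding free space.
#' @return an object of class `mc_scene`.
#' @export
scene <- function(regions, ambient_n = 1.0) {
  if (inherits(regions, "mc_region")) regions <- list(regions)
  stopifnot(length(regions) >= 1, all(vapply(regions, inherits, TRUE, "mc_region")))
  ids <- vapply(regions, function(r) r$id, "")
  if (anyDuplicated(ids)) stop("duplicate region ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  parents <- vapply(regions, function(r) r$parent, "")
  bad <- parents != "ambient" & !parents %in% ids
  if (any(bad)) stop("unresolved parent ids: ", paste(parents[bad], collapse = ", "))
  # depth in the containment tree (ambient = 0), and cycle detection
  depth <- integer(length(ids)); names(depth) <- ids
  for (i in seq_along(ids)) {
    d <- 0L; p <- parents[i]; seen <- character()
    while (p != "ambient") {
      if (p %in% seen) stop("region containment contains a cycle at ", p)
      seen <- c(seen, p)
      d <- d + 1L
      p <- parents[match(p, ids)]
    }
    depth[i] <- d + 1L
  }
  if (sum(depth == 1L) != 1L)
    stop("scene must have exactly one outermost region (a unique tissue surface)")
  for (r in regions) {
    if (r$props$mu_a + r$props$mu_s <= 0)
      stop("region '", r$id, "' has mu_a + mu_s == 0; step sampling is undefined")
  }
  # compile triangle soup
  V <- list(); F1 <- list(); N <- list(); tin <- list(); tout <- list(); nv <- 0L
  for (i in seq_along(regions)) {
    m <- regions[[i]]$mesh
    V[[i]] <- m$vertices
    F1[[i]] <- m$triangles + nv
    N[[i]] <- m$normals
    pr <- parents[i]
    tin[[i]] <- rep.int(i, nrow(m$triangles))
    tout[[i]] <- rep.int(if (pr == "ambient") 0L else match(pr, ids),
                         nrow(m$triangles))
    nv <- nv + nrow(m$vertices)
  }
  sc <- structure(
    list(regions = regions, ids = ids, parents = parents, depth = depth,
         ambient_n = ambient_n,
         V = do.call(rbind, V), F = do.call(rbind, F1) - 1L,
         N = do.call(rbind, N),
         tri_in = unlist(tin), tri_out = unlist(tout),
         tri_offsets = cumsum(c(0L, vapply(regions, function(r)
           nrow(r$mesh$triangles), 0L))),
         ptr_env = new.env(parent = emptyenv())),
    class = "mc_scene")
  # nesting check: child mesh vertices must lie inside the parent region
  for (i in seq_along(regions)) {
    if (parents[i] == "ambient") next
    vv <- regions[[i]]$mesh$vertices
    probe <- vv[unique(round(seq(1, nrow(vv), length.out = min(25, nrow(vv))))), ,
                drop = FALSE]
    pid <- match(parents[i], ids)
    cr <- cpp_region_crossings(scene_ptr(sc), probe, c(1, 2, 3))
    if (any(cr[, pid] %% 2 == 0))
      stop("region '", ids[i], "' is not strictly inside its parent '",
           parents[i], "'")
  }
  sc
}

# compiled scene pointer, built lazily and cached per session
scene_ptr <- function(sc) {
  p <- sc$ptr_env$ptr
  if (is.null(p)) {
    p <- cpp_scene_build(sc$V, sc$F, sc$N, as.integer(sc$tri_in),
                         as.integer(sc$tri_out), length(sc$ids))
    sc$ptr_env$ptr <- p
  }
  p
}

#' @export
print.mc_scene <- function(x, ...) {
  cat("mc_scene:", length(x$ids), "region(s),", nrow(x$F), "triangles,",
      sprintf("ambient n = %g\n", x$ambient_n))
  for (i in seq_along(x$ids)) {
    r <- x$regions[[i]]
    cat(sprintf("  %s%s (parent: %s): mu_a=%g, mu_s=%g, g=%g, n=%g\n",
                strrep("  ", x$depth[i] - 1L), x$ids[i], r$parent,
                r$props$mu_a, r$props$mu_s, r$props$g, r$props$n))
  }
  invisible(x)
}

#' Innermost region containing a point
#'
#' Classifies a point by the parity of boundary crossings along a probe
#' ray: the point lies inside every region whose boundary it crosses an
#' odd number of times; the deepest such region wins. Returns `"ambient"`
#' for points outside the outermost surface.
#'
#' @param point length-3 numeric (mm), not on a boundary.
#' @param scene an `mc_scene`.
#' @return a region id, or `"ambient"`.
#' @export
locate_region <- function(point, scene) {
  stopifnot(inherits(scene, "mc_scene"))
  cr <- cpp_region_crossings(scene_ptr(scene), matrix(as.numeric(point), 1, 3),
                             c(1, 2, 3))
  inside <- which(cr[1, ] %% 2 == 1)
  if (!length(inside)) return("ambient")
  scene$ids[inside[which.max(scene$depth[inside])]]
}

#' Nearest ray-mesh intersection across all region boundaries
#'
#' Moeller-Trumbore intersection with inclusive edges; coincident hits are
#' resolved to the smallest triangle id so replays are deterministic.
#' Intersections closer than `1e-7` mm are discarded (self-hit guard).
#' The region transition is deduced from the sign of `direction . normal`
#' of the hit triangle: moving against the outward normal enters the
#' triangle's region.
#'
#' @param origin length-3 numeric (mm).
#' @param direction length-3 unit vector.
#' @param scene an `mc_scene`.
#' @param max_dist maximum hit distance (mm), may be `Inf`.
#' @return `NULL` if no hit, else a list with `distance`, `triangle_id`,
#'   `hit_point`, `surface_normal`, `region_from`, `region_to`.
#' @export
first_intersection <- function(origin, direction, scene, max_dist = Inf) {
  stopifnot(inherits(scene, "mc_scene"))
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be a non-zero vector")
  direction <- direction / nrm
  h <- cpp_first_hits(scene_ptr(scene), matrix(as.numeric(origin), 1, 3),
                      matrix(direction, 1, 3), max_dist, 1e-7)
  if (is.na(h$triangle[1])) return(NULL)
  ti <- h$triangle[1]
  n <- scene$N[ti, ]
  entering <- sum(direction * n) < 0
  rin <- scene$tri_in[ti]; rout <- scene$tri_out[ti]
  from <- if (entering) rout else rin
  to <- if (entering) rin else rout
  lab <- function(k) if (k == 0L) "ambient" else scene$ids[k]
  list(distance = h$distance[1], triangle_id = ti,
       hit_point = as.numeric(origin) + h$distance[1] * direction,
       surface_normal = n,
       region_from = lab(from), region_to = lab(to))
}
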