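#' Triangle meshes
#'
#' A `trimesh` is a closed triangle surface: an `n x 3` vertex matrix (mm) and
#' an `m x 3` integer face matrix with counter-clockwise outward winding.
#' Meshes bound the solids whose mass properties the volumetric pipeline
#' integrates, so watertightness and consistent orientation are enforced
#' before any integration.
#'
#' @param vertices Numeric `n x 3` matrix, mm.
#' @param faces Integer `m x 3` matrix of 1-based vertex indices.
#' @param component_id Optional identifier.
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, component_id = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (anyNA(vertices) || any(!is.finite(vertices))) {
    abort("mesh vertices must be finite", class = "commass_validation")
  }
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    abort("face indices out of range", class = "commass_validation")
  }
  structure(list(vertices = vertices, faces = faces, component_id = component_id),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("Triangle mesh%s: %d vertices, %d faces\n",
              if (is.null(x$component_id)) "" else paste0(" '", x$component_id, "'"),
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Directed edge table: each row one half-edge (from, to).
directed_edges <- function(mesh) {
  f <- mesh$faces
  rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
}

#' Check that a mesh is watertight and consistently oriented
#'
#' Watertight: every undirected edge is shared by exactly two faces.
#' Consistently oriented: each directed half-edge appears exactly once (so the
#' two faces sharing an edge traverse it in opposite directions).
#'
#' @param mesh A [trimesh()].
#' @return `TRUE`/`FALSE`; attribute `"boundary_edges"` lists offending edges
#'   when `FALSE`.
#' @export
mesh_is_watertight <- function(mesh) {
  de <- directed_edges(mesh)
  dir_key <- paste(de[, 1], de[, 2])
  und_key <- paste(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  und_counts <- table(und_key)
  dir_counts <- table(dir_key)
  ok <- all(und_counts == 2L) && all(dir_counts == 1L)
  bad <- names(und_counts)[und_counts != 2L]
  structure(ok, boundary_edges = bad)
}

validate_mesh_closed <- function(mesh) {
  wt <- mesh_is_watertight(mesh)
  if (!wt) {
    bad <- attr(wt, "boundary_edges")
    abort(paste0("mesh is not watertight/consistently oriented; offending edges: ",
                 paste(head(bad, 5), collapse = "; "),
                 if (length(bad) > 5) " ..." else ""),
          class = "commass_validation")
  }
  invisible(mesh)
}

# Flip every face's winding.
flip_faces <- function(mesh) {
  mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

#' Axis-aligned box mesh
#'
#' @param dims Side lengths (mm).
#' @param origin Minimum corner (mm).
#' @param component_id Optional identifier.
#' @return A [trimesh()] of 12 triangles with outward winding.
#' @export
mesh_box <- function(dims, origin = c(0, 0, 0), component_id = NULL) {
  dims <- vec3(dims)
  if (any(dims <= 0)) abort("box dimensions must be positive", class = "commass_validation")
  o <- vec3(origin)
  v <- as.matrix(expand.grid(c(0, dims[1]), c(0, dims[2]), c(0, dims[3])))
  v <- sweep(v, 2, o, "+")
  dimnames(v) <- NULL
  # vertex order from expand.grid: index = 1 + ix + 2*iy + 4*iz (ix,iy,iz in 0/1)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0 face, outward -z
    c(5, 6, 7), c(6, 8, 7),   # z = max, outward +z
    c(1, 2, 5), c(2, 6, 5),   # y = 0, outward -y
    c(3, 7, 4), c(4, 7, 8),   # y = max, outward +y
    c(1, 5, 3), c(3, 5, 7),   # x = 0, outward -x
    c(2, 4, 6), c(4, 8, 6))   # x = max, outward +x
  trimesh(v, f, component_id)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto the sphere; the standard nearly
#' uniform sphere triangulation.
#'
#' @param radius Sphere radius, mm.
#' @param center Centre, mm.
#' @param subdivisions Number of 4-to-1 subdivisions (default 3, 1280 faces).
#' @param component_id Optional identifier.
#' @return A [trimesh()].
#' @export
mesh_icosphere <- function(radius = 1, center = c(0, 0, 0), subdivisions = 3,
                           component_id = NULL) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midpoint_cache <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midpoint_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (verts[i, ] + verts[j, ]) / 2
      m <- m / norm3(m)
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      midpoint_cache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(k - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- newf
  }
  v <- sweep(v * radius, 2, vec3(center), "+")
  trimesh(v, f, component_id)
}

#' Ellipsoid mesh
#'
#' An icosphere mapped linearly onto the ellipsoid. Because the map is linear,
#' the mesh volume equals `det` of the scaling times the icosphere mesh
#' volume, so ellipsoids built at the same subdivision share an identical
#' relative discretisation deficit.
#'
#' @param semiaxes Length-3 semi-axis lengths (mm).
#' @param center Centre, mm.
#' @param subdivisions Icosphere subdivisions.
#' @param component_id Optional identifier.
#' @return A [trimesh()].
#' @export
mesh_ellipsoid <- function(semiaxes, center = c(0, 0, 0), subdivisions = 3,
                           component_id = NULL) {
  semiaxes <- vec3(semiaxes)
  if (any(semiaxes <= 0)) abort("semi-axes must be positive", class = "commass_validation")
  sph <- mesh_icosphere(1, c(0, 0, 0), subdivisions)
  v <- sweep(sph$vertices, 2, semiaxes, "*")
  v <- sweep(v, 2, vec3(center), "+")
  trimesh(v, sph$faces, component_id)
}

#' Nested boolean-difference mesh
#'
#' For an `inner` shell strictly inside an `outer` shell, the boolean
#' difference solid (outer minus inner) is represented exactly by the two
#' shells with the inner winding flipped so its normals point into the cavity.
#'
#' @param outer,inner Watertight [trimesh()] objects, inner strictly inside.
#' @param component_id Optional identifier.
#' @return A [trimesh()] with two shells.
#' @export
mesh_difference_nested <- function(outer, inner, component_id = NULL) {
  inner <- flip_faces(inner)
  trimesh(rbind(outer$vertices, inner$vertices),
          rbind(outer$faces, inner$faces + nrow(outer$vertices)),
          component_id)
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh A [trimesh()].
#' @param t A [rigid_transform()].
#' @return The transformed mesh.
#' @export
transform_mesh <- function(mesh, t) {
  stopifnot(inherits(t, "rigid_transform"))
  v <- mesh$vertices %*% t(t$rotation)
  mesh$vertices <- sweep(v, 2, t$translation, "+")
  mesh
}

#' Read a triangle mesh from OBJ or ASCII STL
#'
#' Minimal readers for the two plain-text formats the package writes; format
#' is chosen from the file extension (`.obj` or `.stl`).
#'
#' @param path File path.
#' @param component_id Optional identifier (defaults to the file name).
#' @return A [trimesh()].
#' @export
read_mesh <- function(path, component_id = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path), class = "commass_validation")
  component_id <- component_id %||% basename(path)
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  if (ext == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p) as.numeric(p[2:4])))
    f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p) {
      idx <- as.integer(sub("/.*", "", p[2:4]))
      idx
    }))
    return(trimesh(v, f, component_id))
  }
  if (ext == "stl") {
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                               function(p) as.numeric(p[2:4])))
    if (nrow(v) %% 3 != 0) abort("malformed STL: vertex count not a multiple of 3",
                                 class = "commass_parse")
    # weld duplicated vertices so the mesh is a closed, indexed surface
    key <- apply(v, 1, paste, collapse = " ")
    uniq <- !duplicated(key)
    idx <- match(key, key[uniq])
    f <- matrix(idx, ncol = 3, byrow = TRUE)
    return(trimesh(v[uniq, , drop = FALSE], f, component_id))
  }
  abort(paste0("unsupported mesh format: .", ext), class = "commass_validation")
}

#' Write a triangle mesh to OBJ or ASCII STL
#'
#' @param mesh A [trimesh()].
#' @param path Output path ending in `.obj` or `.stl`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") {
    v <- sprintf("v %.9g %.9g %.9g",
                 mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
    f <- sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
    writeLines(c(v, f), path)
  } else if (ext == "stl") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid commass", con)
    for (k in seq_len(nrow(mesh$faces))) {
      tri <- mesh$vertices[mesh$faces[k, ], , drop = FALSE]
      n <- cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
      nn <- norm3(n)
      if (nn > 0) n <- n / nn
      writeLines(c(sprintf("facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                   "  outer loop",
                   sprintf("    vertex %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3]),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid commass", con)
  } else {
    abort(paste0("unsupported mesh format: .", ext), class = "commass_validation")
  }
  invisible(path)
}

#' Point-in-mesh test by ray casting
#'
#' Casts a ray along +z from each query point and counts crossings with the
#' mesh surface (odd crossings = inside). This is a surface-walking algorithm
#' entirely independent of the signed-tetrahedron integration in
#' [mesh_mass_properties()], which is what makes it useful as a cross-check.
#'
#' @param mesh A watertight [trimesh()].
#' @param points `k x 3` matrix of query points (mm).
#' @return Logical vector of length `k`.
#' @export
point_in_mesh <- function(mesh, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  v <- mesh$vertices
  f <- mesh$faces
  crossings <- integer(nrow(points))
  px <- points[, 1]; py <- points[, 2]; pz <- points[, 3]
  for (k in seq_len(nrow(f))) {
    a <- v[f[k, 1], ]; b <- v[f[k, 2], ]; cc <- v[f[k, 3], ]
    xr <- range(a[1], b[1], cc[1]); yr <- range(a[2], b[2], cc[2])
    cand <- which(px >= xr[1] & px <= xr[2] & py >= yr[1] & py <= yr[2])
    if (length(cand) == 0L) next
    # 2D barycentric test in the xy-plane (half-open rule on the sign of the
    # sub-areas keeps shared edges from double counting almost surely for
    # random query points)
    d <- (b[2] - cc[2]) * (a[1] - cc[1]) + (cc[1] - b[1]) * (a[2] - cc[2])
    if (abs(d) < 1e-300) next  # triangle vertical in z; ray pierces its edge only
    l1 <- ((b[2] - cc[2]) * (px[cand] - cc[1]) + (cc[1] - b[1]) * (py[cand] - cc[2])) / d
    l2 <- ((cc[2] - a[2]) * (px[cand] - cc[1]) + (a[1] - cc[1]) * (py[cand] - cc[2])) / d
    l3 <- 1 - l1 - l2
    inside2d <- l1 >= 0 & l1 < 1 & l2 >= 0 & l2 < 1 & l3 >= 0 & l3 < 1
    if (!any(inside2d)) next
    hit <- cand[inside2d]
    zint <- l1[inside2d] * a[3] + l2[inside2d] * b[3] + l3[inside2d] * cc[3]
    above <- zint > pz[hit]
    crossings[hit[above]] <- crossings[hit[above]] + 1L
  }
  crossings %% 2L == 1L
}
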