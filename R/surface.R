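# Discrete Solvent Excluded Surface pipeline.
#
# Stage 1: signed solvent-accessible field f(p) = min_i(|p - c_i| - r_i) - r_probe
#          on a regular grid (negative strictly inside the probe-inflated
#          atom union), computed by per-atom local stamping.
# Stage 2: h(p) = r_probe - EDT(p), with EDT the exact Euclidean distance to
#          the nearest grid node with f >= 0; h = 0 on the SES, h < 0 inside
#          the solvent-excluded volume.
# Stage 3: marching cubes at iso 0 with gradient normals.
#
# The 256-entry marching-cubes case table is derived programmatically from
# face-boundary crossings: on each cube face, isosurface segments are paired
# and directed so the positive (outside) region lies to the left when the
# face is viewed from outside the cube; segments then chain into closed,
# consistently oriented polygons, which are fan-triangulated. Ambiguous
# faces (diagonal sign pattern) always connect the positive corners -- the
# fixed pairing keeps adjacent cubes agreeing, so meshes are watertight.

#' Construct a scalar grid
#' @param origin 3-vector (Angstrom), position of node (1,1,1)
#' @param spacing isotropic node spacing (Angstrom)
#' @param values 3-d numeric array of node values
#' @export
scalar_grid <- function(origin, spacing, values) {
  stopifnot(length(origin) == 3, spacing > 0, length(dim(values)) == 3,
            all(dim(values) >= 2))
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = dim(values), values = values),
            class = "scalar_grid")
}

#' Construct a triangle mesh
#' @param vertices n x 3 matrix
#' @param normals n x 3 matrix of unit normals (or NULL)
#' @param triangles m x 3 integer matrix of 1-based vertex indices
#' @param colors optional n x 4 RGBA matrix (0-255)
#' @export
trimesh <- function(vertices, normals = NULL, triangles, colors = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (NROW(triangles) && NROW(vertices) &&
      (max(triangles) > nrow(vertices) || min(triangles) < 1L))
    stop("triangle indices out of range", call. = FALSE)
  structure(list(vertices = vertices, normals = normals,
                 triangles = triangles, colors = colors), class = "trimesh")
}

#' Total surface area of a mesh
#' @param mesh a `trimesh`
#' @return area in square Angstrom
#' @export
mesh_area <- function(mesh) {
  f <- mesh$triangles
  if (!NROW(f)) return(0)
  v <- mesh$vertices
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sum(sqrt(cx^2 + cy^2 + cz^2))
}

# ---- SAS signed field -------------------------------------------------------

#' Signed solvent-accessible field on a regular grid
#'
#' Node value `f(p) = min_i(|p - c_i| - r_i) - probe_radius`; negative
#' strictly inside the solvent-accessible volume. Values are exact within
#' `r_i + probe_radius + stamp_margin` of each atom (per-atom local
#' stamping); farther nodes receive a positive sentinel, which preserves the
#' sign everywhere.
#'
#' @param system a `molsys` with radii assigned
#' @param probe_radius solvent probe radius (Angstrom, default water 1.4)
#' @param spacing grid spacing (Angstrom)
#' @param stamp_margin stamping halo beyond the accessible surface
#'   (Angstrom); `Inf` computes the exact field on the whole grid
#' @return a [scalar_grid()]
#' @export
build_sas_field <- function(system, probe_radius = 1.4, spacing = 0.4,
                            stamp_margin = 2 * spacing) {
  if (n_atoms(system) == 0L) stop("empty system", call. = FALSE)
  if (any(is.na(system$atoms$vdw_radius)))
    stop("radii not assigned; call assign_radii() first", call. = FALSE)
  xyz <- coords(system)
  r <- system$atoms$vdw_radius
  pad <- max(r) + probe_radius + 2 * spacing
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  sentinel <- probe_radius + max(spacing, min(stamp_margin, 1e6))
  vals <- array(sentinel, dim = dims)
  ax <- lapply(1:3, function(a) lo[a] + (seq_len(dims[a]) - 1) * spacing)
  for (i in seq_len(nrow(xyz))) {
    reach <- r[i] + probe_radius + stamp_margin
    rng <- lapply(1:3, function(a) {
      if (is.infinite(reach)) seq_len(dims[a])
      else which(abs(ax[[a]] - xyz[i, a]) <= reach)
    })
    if (any(lengths(rng) == 0L)) next
    dx2 <- (ax[[1]][rng[[1]]] - xyz[i, 1])^2
    dy2 <- (ax[[2]][rng[[2]]] - xyz[i, 2])^2
    dz2 <- (ax[[3]][rng[[3]]] - xyz[i, 3])^2
    d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
    f_local <- d - r[i] - probe_radius
    vals[rng[[1]], rng[[2]], rng[[3]]] <-
      pmin(vals[rng[[1]], rng[[2]], rng[[3]]], f_local)
  }
  scalar_grid(lo, spacing, vals)
}

#' SES level field from the SAS field
#'
#' `h(p) = probe_radius - EDT(p)`, where EDT is the exact Euclidean distance
#' from node p to the nearest node with SAS field value >= 0. `h < 0`
#' strictly inside the solvent-excluded volume, `h = 0` on the SES, and
#' `h = +probe_radius` on all exterior nodes.
#'
#' @param sas a [scalar_grid()] from [build_sas_field()]
#' @param probe_radius the probe radius used to build `sas`
#' @return a [scalar_grid()] carrying h
#' @export
ses_level_field <- function(sas, probe_radius = 1.4) {
  seeds <- ifelse(sas$values >= 0, 0, Inf)
  ft <- edt3d_feature(as.numeric(seeds), as.integer(sas$dims))
  edt <- sas$spacing * sqrt(ft$sq)
  # sub-voxel correction: the nearest exterior node sits f(site) beyond the
  # continuous accessible surface (f is the exact Euclidean distance to the
  # sphere-union boundary outside it), so subtracting it removes the O(spacing)
  # node-offset bias. Exterior nodes keep EDT = 0, i.e. h = +probe exactly.
  fsite <- pmin(pmax(sas$values[ft$site + 1L], 0), sqrt(3) * sas$spacing)
  inside <- as.numeric(sas$values < 0)
  d_corr <- pmax(edt - fsite * inside, 0)
  h <- probe_radius - d_corr
  # exterior nodes continue smoothly as probe + f (f = distance beyond the
  # accessible surface there): irrelevant for probe >> spacing, but it makes
  # the probe -> 0 limit recover the van der Waals surface instead of
  # snapping the isosurface to the first exterior node.
  ext <- sas$values >= 0
  h[ext] <- probe_radius + sas$values[ext]
  scalar_grid(sas$origin, sas$spacing, array(h, dim = sas$dims))
}

#' Euclidean distance transform on a grid (node units: Angstrom)
#'
#' Distance from every node to the nearest marked node, exact (separable
#' squared-distance transform).
#'
#' @param mask logical 3-d array marking the target set
#' @param spacing node spacing (Angstrom)
#' @export
distance_transform <- function(mask, spacing = 1) {
  stopifnot(length(dim(mask)) == 3)
  seeds <- ifelse(mask, 0, Inf)
  sq <- edt3d_sq(as.numeric(seeds), as.integer(dim(mask)))
  array(spacing * sqrt(sq), dim = dim(mask))
}

# ---- Marching cubes ---------------------------------------------------------

.mc_env <- new.env(parent = emptyenv())

# Cube conventions: corner c in 0..7 at ((c>>0)&1, (c>>1)&1, (c>>2)&1);
# edges 1..12 listed x-aligned, then y-aligned, then z-aligned.
.MC_EDGE_CORNERS <- matrix(c(
  0L, 1L,  2L, 3L,  4L, 5L,  6L, 7L,   # x edges
  0L, 2L,  1L, 3L,  4L, 6L,  5L, 7L,   # y edges
  0L, 4L,  1L, 5L,  2L, 6L,  3L, 7L    # z edges
), ncol = 2, byrow = TRUE)
.MC_EDGE_AXIS <- rep(1:3, each = 4)

.mc_case_table <- function() {
  if (!is.null(.mc_env$table)) return(.mc_env$table)
  corners <- t(vapply(0:7, function(c)
    c(bitwAnd(c, 1L), bitwAnd(bitwShiftR(c, 1L), 1L),
      bitwAnd(bitwShiftR(c, 2L), 1L)), integer(3)))
  edge_of <- matrix(NA_integer_, 8, 8)
  for (e in seq_len(12)) {
    a <- .MC_EDGE_CORNERS[e, 1] + 1L
    b <- .MC_EDGE_CORNERS[e, 2] + 1L
    edge_of[a, b] <- e
    edge_of[b, a] <- e
  }
  # faces: for each axis/side, the 4 corners ordered CCW as seen from outside
  faces <- list()
  for (axis in 1:3) for (side in 0:1) {
    ids <- which(corners[, axis] == side)
    nrm <- c(0, 0, 0)
    nrm[axis] <- if (side == 1) 1 else -1
    others <- setdiff(1:3, axis)
    u <- c(0, 0, 0); u[others[1]] <- 1
    v <- c(crossprod3(nrm, u))
    ctr <- colMeans(corners[ids, ])
    rel <- sweep(corners[ids, ], 2, ctr)
    ang <- atan2(rel %*% v, rel %*% u)
    faces[[length(faces) + 1L]] <- ids[order(ang)] - 1L
  }
  tri <- vector("list", 256)
  for (cfg in 0:255) {
    inside <- bitwAnd(cfg, bitwShiftL(1L, 0:7)) > 0L  # corner value < iso
    segs_from <- integer(0); segs_to <- integer(0)
    for (fc in faces) {
      loop <- c(fc, fc[1])
      cross_t <- integer(0); cross_edge <- integer(0); cross_leave <- logical(0)
      for (t in 1:4) {
        a <- loop[t]; b <- loop[t + 1]
        if (inside[a + 1] != inside[b + 1]) {
          cross_t <- c(cross_t, t)
          cross_edge <- c(cross_edge, edge_of[a + 1, b + 1])
          cross_leave <- c(cross_leave, !inside[a + 1])  # + -> -
        }
      }
      if (!length(cross_t)) next
      nc <- length(cross_t)
      for (q in seq_len(nc)) {
        if (!cross_leave[q]) next
        nxt <- c(seq_len(nc)[-seq_len(q)], seq_len(q))  # cyclic successors
        enter <- nxt[which(!cross_leave[nxt])[1]]
        segs_from <- c(segs_from, cross_edge[q])
        segs_to <- c(segs_to, cross_edge[enter])
      }
    }
    if (!length(segs_from)) { tri[[cfg + 1]] <- matrix(integer(0), 0, 3); next }
    nxt_of <- integer(12)
    nxt_of[segs_from] <- segs_to
    used <- rep(FALSE, 12)
    tris <- list()
    for (s in segs_from) {
      if (used[s]) next
      cyc <- s
      used[s] <- TRUE
      p <- nxt_of[s]
      while (p != s) { cyc <- c(cyc, p); used[p] <- TRUE; p <- nxt_of[p] }
      if (length(cyc) >= 3)
        for (t in 2:(length(cyc) - 1))
          tris[[length(tris) + 1L]] <- c(cyc[1], cyc[t], cyc[t + 1])
    }
    tri[[cfg + 1]] <- if (length(tris)) do.call(rbind, tris)
                      else matrix(integer(0), 0, 3)
  }
  # pack into a 256 x 15 padded matrix for vectorized lookup
  flat <- matrix(0L, 256, 15)
  cnt <- integer(256)
  for (cfg in 0:255) {
    tt <- tri[[cfg + 1]]
    cnt[cfg + 1] <- nrow(tt)
    if (nrow(tt)) flat[cfg + 1, seq_len(3 * nrow(tt))] <- as.integer(t(tt))
  }
  .mc_env$table <- list(flat = flat, n_tri = cnt)
  .mc_env$table
}

crossprod3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Marching-cubes isosurface extraction
#'
#' Standard 256-case table (derived once at first use), edge vertices by
#' linear interpolation, vertex normals from the central-difference gradient
#' of the field (pointing toward increasing field values). Shared edge
#' vertices are merged, so the mesh is watertight for fields that do not
#' cross the grid boundary.
#'
#' @param grid a [scalar_grid()]
#' @param iso iso level (default 0)
#' @return a `trimesh` (empty if the field does not cross `iso`)
#' @export
marching_cubes <- function(grid, iso = 0) {
  v <- grid$values
  d <- grid$dims
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  inside <- v < iso
  cfg <- array(0L, dim = d - 1L)
  corners <- t(vapply(0:7, function(c)
    c(bitwAnd(c, 1L), bitwAnd(bitwShiftR(c, 1L), 1L),
      bitwAnd(bitwShiftR(c, 2L), 1L)), integer(3)))
  for (c in 0:7) {
    off <- corners[c + 1, ]
    blk <- inside[(1 + off[1]):(nx - 1 + off[1]),
                  (1 + off[2]):(ny - 1 + off[2]),
                  (1 + off[3]):(nz - 1 + off[3]), drop = FALSE]
    cfg <- cfg + bitwShiftL(1L, c) * (blk * 1L)
  }
  active <- which(cfg != 0L & cfg != 255L)
  if (!length(active))
    return(trimesh(matrix(numeric(0), 0, 3), matrix(numeric(0), 0, 3),
                   matrix(integer(0), 0, 3)))
  tab <- .mc_case_table()
  acfg <- cfg[active]
  ntri <- tab$n_tri[acfg + 1L]
  edges_rows <- tab$flat[acfg + 1L, , drop = FALSE]
  sel <- t(edges_rows)            # 15 x n_active, column-major per cell
  keep <- sel != 0L
  local_edge <- sel[keep]
  cell_of <- rep(active, each = 15L)[as.vector(keep)]

  # (i,j,k) 0-based cell coords
  c0 <- cell_of - 1L
  ci <- c0 %% (nx - 1L)
  cj <- (c0 %/% (nx - 1L)) %% (ny - 1L)
  ck <- c0 %/% ((nx - 1L) * (ny - 1L))
  lower <- .MC_EDGE_CORNERS[local_edge, 1]
  lx <- bitwAnd(lower, 1L); ly <- bitwAnd(bitwShiftR(lower, 1L), 1L)
  lz <- bitwAnd(bitwShiftR(lower, 2L), 1L)
  axis <- .MC_EDGE_AXIS[local_edge]
  node <- (ci + lx) + nx * (cj + ly) + nx * ny * (ck + lz)  # 0-based node
  key <- 3 * node + (axis - 1L)

  uk <- unique(key)
  vid <- match(key, uk)
  triangles <- matrix(vid, ncol = 3, byrow = TRUE)

  unode <- uk %/% 3
  uaxis <- uk %% 3 + 1L
  ui <- unode %% nx
  uj <- (unode %/% nx) %% ny
  uzk <- unode %/% (nx * ny)
  step <- c(1L, nx, nx * ny)[uaxis]
  n1 <- unode + 1L                     # 1-based linear index of lower node
  n2 <- unode + step + 1L
  v1 <- v[n1]; v2 <- v[n2]
  tt <- (iso - v1) / (v2 - v1)
  tt[!is.finite(tt)] <- 0.5
  pos0 <- cbind(ui, uj, uzk)
  offs <- matrix(0, length(uk), 3)
  offs[cbind(seq_along(uk), uaxis)] <- tt
  verts <- sweep((pos0 + offs) * grid$spacing, 2, grid$origin, "+")

  grad_at <- function(lin) {
    i <- (lin - 1L) %% nx
    j <- ((lin - 1L) %/% nx) %% ny
    k <- (lin - 1L) %/% (nx * ny)
    g <- matrix(0, length(lin), 3)
    for (a in 1:3) {
      stp <- c(1L, nx, nx * ny)[a]
      idx <- switch(a, i, j, k)
      nmax <- c(nx, ny, nz)[a]
      hi_ok <- idx < nmax - 1L
      lo_ok <- idx > 0L
      vp <- v[lin + ifelse(hi_ok, stp, 0L)]
      vm <- v[lin - ifelse(lo_ok, stp, 0L)]
      g[, a] <- (vp - vm) / (grid$spacing * (hi_ok + lo_ok))
    }
    g
  }
  g <- grad_at(n1) * (1 - tt) + grad_at(n2) * tt
  gl <- sqrt(rowSums(g^2))
  gl[gl == 0] <- 1
  normals <- g / gl

  mesh <- trimesh(verts, normals, triangles)
  .orient_mesh(mesh)
}

# Flip triangle winding where the geometric normal disagrees with the
# gradient normal, so cross-product normals and shading are consistent.
.orient_mesh <- function(mesh) {
  f <- mesh$triangles
  if (!NROW(f)) return(mesh)
  v <- mesh$vertices
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  gn <- (mesh$normals[f[, 1], , drop = FALSE] +
           mesh$normals[f[, 2], , drop = FALSE] +
           mesh$normals[f[, 3], , drop = FALSE])
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  flip <- (cx * gn[, 1] + cy * gn[, 2] + cz * gn[, 3]) < 0
  if (any(flip)) {
    tmp <- f[flip, 2]
    f[flip, 2] <- f[flip, 3]
    f[flip, 3] <- tmp
    mesh$triangles <- f
  }
  mesh
}

#' Compute the Solvent Excluded Surface mesh of a system
#'
#' Composition of [build_sas_field()], [ses_level_field()] and
#' [marching_cubes()]. Vertex colors come from the nearest atom (surface
#' distance `|v - c_i| - r_i`), using the element color scheme by default.
#'
#' @param system a `molsys` with radii assigned
#' @param probe_radius solvent probe radius (Angstrom)
#' @param spacing grid spacing (Angstrom)
#' @param atom_colors optional n_atoms x 4 RGBA matrix (see [assign_colors()])
#' @return a `trimesh` in model coordinates
#' @export
compute_ses <- function(system, probe_radius = 1.4, spacing = 0.4,
                        atom_colors = NULL) {
  sas <- build_sas_field(system, probe_radius, spacing)
  h <- ses_level_field(sas, probe_radius)
  mesh <- marching_cubes(h, iso = 0)
  if (NROW(mesh$vertices)) {
    if (is.null(atom_colors)) atom_colors <- assign_colors(system, "element")
    xyz <- coords(system)
    r <- system$atoms$vdw_radius
    nearest <- integer(nrow(mesh$vertices))
    block <- 20000L
    for (s in seq(1L, nrow(mesh$vertices), by = block)) {
      e <- min(s + block - 1L, nrow(mesh$vertices))
      vv <- mesh$vertices[s:e, , drop = FALSE]
      best_d <- rep(Inf, e - s + 1L)
      best_i <- rep(1L, e - s + 1L)
      for (i in seq_len(nrow(xyz))) {
        di <- sqrt((vv[, 1] - xyz[i, 1])^2 + (vv[, 2] - xyz[i, 2])^2 +
                     (vv[, 3] - xyz[i, 3])^2) - r[i]
        upd <- di < best_d
        best_d[upd] <- di[upd]
        best_i[upd] <- i
      }
      nearest[s:e] <- best_i
    }
    mesh$colors <- atom_colors[nearest, , drop = FALSE]
  }
  mesh
}
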