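# Ray-primitive intersection. The public single-ray functions implement the
# implicit-equation contracts; the .batch_* variants evaluate one primitive
# against many rays at once (vectorized) and drive the G-buffer fill.

.RAY_EPS <- 1e-6

#' Ray-sphere intersection
#'
#' Smallest root t > 1e-6 of |o + t d - c|^2 = r^2.
#'
#' @param origin,dir ray origin and unit direction
#' @param center,radius sphere
#' @return list(t, normal) or NULL on miss
#' @export
intersect_sphere <- function(origin, dir, center, radius) {
  hit <- .batch_sphere(matrix(dir, 1), origin, center, radius)
  if (!is.finite(hit$t)) return(NULL)
  p <- origin + hit$t * dir
  list(t = hit$t, normal = (p - center) / radius)
}

.batch_sphere <- function(dirs, origin, center, radius) {
  oc <- origin - center
  b <- dirs %*% oc
  cc <- sum(oc^2) - radius^2
  disc <- b^2 - cc
  t <- rep(Inf, nrow(dirs))
  ok <- disc >= 0
  if (any(ok)) {
    s <- sqrt(disc[ok])
    t1 <- -b[ok] - s
    t2 <- -b[ok] + s
    tt <- ifelse(t1 > .RAY_EPS, t1, ifelse(t2 > .RAY_EPS, t2, Inf))
    t[ok] <- tt
  }
  list(t = t)
}

#' Ray-cylinder intersection (finite open cylinder, no caps)
#'
#' Smallest positive root of the distance-to-axis quadratic, accepted only
#' when the hit projects strictly inside the segment a-b. A ray inside and
#' parallel to the axis misses (open cylinder).
#'
#' @param origin,dir ray origin and unit direction
#' @param a,b axis endpoints
#' @param radius cylinder radius
#' @return list(t, normal, s) (s = axial fraction) or NULL on miss
#' @export
intersect_cylinder <- function(origin, dir, a, b, radius) {
  hit <- .batch_cylinder(matrix(dir, 1), origin, a, b, radius)
  if (!is.finite(hit$t)) return(NULL)
  list(t = hit$t, normal = c(hit$nx, hit$ny, hit$nz), s = hit$s)
}

.batch_cylinder <- function(dirs, origin, a, b, radius) {
  ax <- b - a
  L <- sqrt(sum(ax^2))
  v <- ax / L
  w <- origin - a
  dv <- dirs %*% v            # n x 1
  wv <- sum(w * v)
  dd <- dirs - outer(c(dv), v)
  ww <- w - wv * v
  A <- rowSums(dd^2)
  B <- 2 * (dd %*% ww)
  C <- sum(ww^2) - radius^2
  disc <- B^2 - 4 * A * C
  n <- nrow(dirs)
  t <- rep(Inf, n)
  ok <- disc >= 0 & A > 1e-18
  if (any(ok)) {
    s <- sqrt(disc[ok])
    t1 <- (-B[ok] - s) / (2 * A[ok])
    t2 <- (-B[ok] + s) / (2 * A[ok])
    s1 <- wv + t1 * dv[ok]     # axial coordinate of each root
    s2 <- wv + t2 * dv[ok]
    ok1 <- t1 > .RAY_EPS & s1 > 0 & s1 < L
    ok2 <- t2 > .RAY_EPS & s2 > 0 & s2 < L
    t[ok] <- ifelse(ok1, t1, ifelse(ok2, t2, Inf))
  }
  tf <- is.finite(t)
  nx <- ny <- nz <- ss <- rep(NA_real_, n)
  if (any(tf)) {
    p <- origin + dirs[tf, , drop = FALSE] * t[tf]
    sax <- c((p - matrix(a, sum(tf), 3, byrow = TRUE)) %*% v)
    foot <- matrix(a, sum(tf), 3, byrow = TRUE) + outer(sax, v)
    nn <- (p - foot) / radius
    nx[tf] <- nn[, 1]; ny[tf] <- nn[, 2]; nz[tf] <- nn[, 3]
    ss[tf] <- sax / L
  }
  list(t = t, nx = nx, ny = ny, nz = nz, s = ss)
}

# ---- Triangle meshes: Moller-Trumbore + axis-aligned BVH -------------------

.MT_EPS <- 1e-9

# one ray against a block of triangles (v0/e1/e2 rows)
.mt_block <- function(origin, dir, v0, e1, e2) {
  pv <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
              dir[3] * e2[, 1] - dir[1] * e2[, 3],
              dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det <- rowSums(e1 * pv)
  tvec <- -sweep(v0, 2, origin)
  u <- rowSums(tvec * pv) / det
  qv <- cbind(tvec[, 2] * e1[, 3] - tvec[, 3] * e1[, 2],
              tvec[, 3] * e1[, 1] - tvec[, 1] * e1[, 3],
              tvec[, 1] * e1[, 2] - tvec[, 2] * e1[, 1])
  vv <- (qv %*% dir) / det
  t <- rowSums(e2 * qv) / det
  bad <- abs(det) < .MT_EPS | u < -.MT_EPS | vv < -.MT_EPS |
    (u + vv) > 1 + .MT_EPS | t <= .RAY_EPS | !is.finite(t)
  t[bad] <- Inf
  list(t = t, u = u, v = c(vv))
}

#' Build a bounding-volume hierarchy over a triangle mesh
#'
#' Axis-aligned boxes, median split on the widest centroid axis, leaves of
#' at most `leaf_size` triangles.
#'
#' @param mesh a `trimesh`
#' @param leaf_size maximum triangles per leaf
#' @return a `bvh` object usable with [intersect_mesh()]
#' @export
bvh_build <- function(mesh, leaf_size = 8L) {
  f <- mesh$triangles
  v <- mesh$vertices
  nt <- nrow(f)
  if (!nt) return(structure(list(n_tri = 0L), class = "bvh"))
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  tmin <- pmin(p1, p2, p3)
  tmax <- pmax(p1, p2, p3)
  cent <- (p1 + p2 + p3) / 3
  nodes <- list()
  order_idx <- integer(0)
  build <- function(ids) {
    node <- list(lo = apply(tmin[ids, , drop = FALSE], 2, min),
                 hi = apply(tmax[ids, , drop = FALSE], 2, max))
    me <- length(nodes) + 1L
    nodes[[me]] <<- node  # reserve slot
    if (length(ids) <= leaf_size) {
      node$start <- length(order_idx) + 1L
      node$count <- length(ids)
      node$left <- node$right <- 0L
      order_idx <<- c(order_idx, ids)
    } else {
      ext <- node$hi - node$lo
      axis <- which.max(ext)
      ord <- ids[order(cent[ids, axis], ids)]
      half <- length(ord) %/% 2
      node$count <- 0L
      node$left <- build(ord[seq_len(half)])
      node$right <- build(ord[(half + 1L):length(ord)])
    }
    nodes[[me]] <<- node
    me
  }
  build(seq_len(nt))
  structure(list(
    nodes = nodes, order = order_idx, n_tri = nt,
    v0 = p1, e1 = p2 - p1, e2 = p3 - p1,
    mesh = mesh), class = "bvh")
}

.slab_hit <- function(origin, inv_dir, lo, hi, tbest) {
  t1 <- (lo - origin) * inv_dir
  t2 <- (hi - origin) * inv_dir
  tn <- max(pmin(t1, t2))
  tf <- min(pmax(t1, t2))
  tf >= tn && tf > 0 && tn < tbest
}

#' Nearest ray-mesh intersection through a BVH
#'
#' @param bvh from [bvh_build()]
#' @param origin,dir ray
#' @return list(t, normal, triangle) with the interpolated vertex normal,
#'   or NULL on miss
#' @export
intersect_mesh <- function(bvh, origin, dir) {
  if (bvh$n_tri == 0L) return(NULL)
  inv <- 1 / (dir + (dir == 0) * 1e-30)  # avoid 0*Inf = NaN in slab tests
  stack <- c(1L)
  best_t <- Inf
  best_tri <- 0L
  best_uv <- c(0, 0)
  while (length(stack)) {
    ni <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nd <- bvh$nodes[[ni]]
    if (!.slab_hit(origin, inv, nd$lo, nd$hi, best_t)) next
    if (nd$count > 0L) {
      ids <- bvh$order[nd$start:(nd$start + nd$count - 1L)]
      h <- .mt_block(origin, dir, bvh$v0[ids, , drop = FALSE],
                     bvh$e1[ids, , drop = FALSE], bvh$e2[ids, , drop = FALSE])
      k <- which.min(h$t)
      if (length(k) && h$t[k] < best_t) {
        best_t <- h$t[k]
        best_tri <- ids[k]
        best_uv <- c(h$u[k], h$v[k])
      }
    } else {
      stack <- c(stack, nd$left, nd$right)
    }
  }
  if (!is.finite(best_t)) return(NULL)
  f <- bvh$mesh$triangles[best_tri, ]
  w <- c(1 - sum(best_uv), best_uv)
  nrm <- if (!is.null(bvh$mesh$normals)) {
    nn <- w[1] * bvh$mesh$normals[f[1], ] + w[2] * bvh$mesh$normals[f[2], ] +
      w[3] * bvh$mesh$normals[f[3], ]
    nn / sqrt(sum(nn^2))
  } else {
    e1 <- bvh$e1[best_tri, ]; e2 <- bvh$e2[best_tri, ]
    nn <- crossprod3(e1, e2)
    nn / sqrt(sum(nn^2))
  }
  list(t = best_t, normal = nrm, triangle = best_tri, weights = w)
}
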