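# Shared test helpers. All fixtures are built in code; nothing is read from
# disk except files the tests themselves write to tempdir().

sphere_df <- function(x, y, z, r, col = c(255, 255, 255, 255), group = NA_integer_) {
  data.frame(x = x, y = y, z = z, r = r,
             cr = col[1], cg = col[2], cb = col[3], ca = col[4],
             atom_ref = seq_along(x), union_group = group)
}

quad_mesh <- function(v1, v2, v3, v4, normals = NULL) {
  trimesh(rbind(v1, v2, v3, v4), normals,
          matrix(c(1, 2, 3, 1, 3, 4), 2, 3, byrow = TRUE))
}

axis_camera <- function(dist = 5, fov = 45, target = c(0, 0, 0)) {
  camera(position = target + c(0, 0, dist), target = target, fov = fov)
}

# independent Moller-Trumbore for the BVH oracle (deliberately separate from
# the package implementation)
oracle_ray_mesh <- function(origin, dir, vertices, triangles) {
  best <- Inf
  for (q in seq_len(nrow(triangles))) {
    v0 <- vertices[triangles[q, 1], ]
    e1 <- vertices[triangles[q, 2], ] - v0
    e2 <- vertices[triangles[q, 3], ] - v0
    pv <- c(dir[2] * e2[3] - dir[3] * e2[2],
            dir[3] * e2[1] - dir[1] * e2[3],
            dir[1] * e2[2] - dir[2] * e2[1])
    det <- sum(e1 * pv)
    if (abs(det) < 1e-12) next
    tv <- origin - v0
    u <- sum(tv * pv) / det
    qv <- c(tv[2] * e1[3] - tv[3] * e1[2],
            tv[3] * e1[1] - tv[1] * e1[3],
            tv[1] * e1[2] - tv[2] * e1[1])
    v <- sum(dir * qv) / det
    t <- sum(e2 * qv) / det
    if (u >= -1e-9 && v >= -1e-9 && u + v <= 1 + 1e-9 && t > 1e-6 && t < best)
      best <- t
  }
  best
}

# smooth non-periodic CA trace (random-walk curve with bounded turning), so
# CE alignments have a unique optimum
make_wiggle_chain <- function(n, seed = 7) {
  rng <- molray:::.local_rng(seed)
  dirv <- c(1, 0, 0)
  pts <- matrix(0, n, 3)
  for (i in 2:n) {
    pert <- (rng$unif(3) - 0.5) * 0.8
    dirv <- dirv + pert
    dirv <- dirv / sqrt(sum(dirv^2))
    pts[i, ] <- pts[i - 1, ] + 3.8 * dirv
  }
  pts
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

expect_image_equal <- function(a, b) {
  expect_equal(dim(a), dim(b))
  expect_true(all(unclass(a) == unclass(b)))
}
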