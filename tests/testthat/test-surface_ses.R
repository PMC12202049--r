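# discrete SES pipeline: signed SAS field, exact EDT, marching cubes

single_atom <- function() molray:::.ca_system(matrix(0, 1, 3))

test_that("SAS field follows f(p) = min_i(|p-c_i| - r_i) - probe", {
  sas <- build_sas_field(single_atom(), probe_radius = 1.4, spacing = 0.4,
                         stamp_margin = Inf)
  ax <- lapply(1:3, function(a)
    sas$origin[a] + (seq_len(sas$dims[a]) - 1) * sas$spacing)
  dist <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))
  expect_equal(sas$values, dist - 1.7 - 1.4, tolerance = 1e-12,
               ignore_attr = TRUE)
  # value at the node nearest the atom center ~ -3.1
  expect_lt(min(sas$values), -3.1 + 0.4 * sqrt(3))
  empty_sys <- molecule_system(
    data.frame(name = character(0), element = character(0),
               chain_id = character(0), residue_name = character(0),
               residue_seq = integer(0)), matrix(numeric(0), 0, 3))
  expect_error(build_sas_field(empty_sys), "empty")
})

test_that("exact EDT equals brute force on random grids", {
  rng <- molray:::.local_rng(99)
  for (rep in 1:3) {
    d <- 4L + floor(rng$unif(3) * 8)
    mask <- array(rng$unif(prod(d)) < 0.15, dim = d)
    mask[1 + floor(rng$unif(1) * d[1]), 1, 1] <- TRUE
    dt <- distance_transform(mask, spacing = 1)
    idx <- which(mask, arr.ind = TRUE)
    bf <- array(Inf, dim = d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
      bf[i, j, k] <- sqrt(min(colSums((t(idx) - c(i, j, k))^2)))
    expect_equal(max(abs(dt - bf)), 0)
  }
})

test_that("SES level field matches the single-sphere closed form", {
  sas <- build_sas_field(single_atom(), probe_radius = 1.4, spacing = 0.3)
  h <- ses_level_field(sas, probe_radius = 1.4)
  ax <- lapply(1:3, function(a)
    h$origin[a] + (seq_len(h$dims[a]) - 1) * h$spacing)
  dist <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))
  # closed-form: inside the SAS volume, EDT(p) = (r + r_probe) - |p - c|,
  # so h = 1.4 - (3.1 - d) = d - 1.7
  inside <- dist < 3.1 - 0.4          # away from the discretization boundary
  expect_lt(max(abs(h$values[inside] - (dist[inside] - 1.7))), 0.2)
  # exterior nodes carry h = probe + f >= +probe
  expect_true(all(h$values[sas$values >= 0] >= 1.4))
  expect_equal(h$values[sas$values >= 0],
               1.4 + sas$values[sas$values >= 0], ignore_attr = TRUE)
  # center is deeply interior: h ~ -1.7
  expect_lt(abs(min(h$values) - (-1.7)), 0.25)
})

test_that("marching cubes recovers analytic surfaces", {
  sp <- 0.2
  x <- seq(-2.8, 2.8, by = sp)
  g <- scalar_grid(rep(-2.8, 3), sp,
                   array(sqrt(outer(outer(x^2, x^2, "+"), x^2, "+")) - 2,
                         dim = rep(length(x), 3)))
  mesh <- marching_cubes(g, 0)
  expect_lt(abs(mesh_area(mesh) - 4 * pi * 4) / (4 * pi * 4), 0.02)
  # watertight: every edge is shared by exactly two triangles
  f <- mesh$triangles
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  ek <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  expect_true(all(table(ek) == 2))
  # normals unit length and outward
  expect_equal(sqrt(rowSums(mesh$normals^2)), rep(1, nrow(mesh$normals)),
               tolerance = 1e-6)
  radial <- mesh$vertices / sqrt(rowSums(mesh$vertices^2))
  expect_gt(min(rowSums(mesh$normals * radial)), 0.9)

  # constant positive field -> empty mesh
  cg <- scalar_grid(c(0, 0, 0), 1, array(1, dim = c(4, 4, 4)))
  expect_equal(nrow(marching_cubes(cg)$triangles), 0L)

  # half-space: planar mesh with normals (0,0,1)
  z <- array(rep(seq(-1.5, 1.5, by = 0.5), each = 16), dim = c(4, 4, 7))
  hg <- scalar_grid(c(0, 0, 0), 0.5, z)
  hm <- marching_cubes(hg, 0)
  expect_gt(nrow(hm$triangles), 0)
  expect_equal(hm$normals[, 3], rep(1, nrow(hm$normals)), tolerance = 1e-9)
  expect_lt(diff(range(hm$vertices[, 3])), 1e-12)
})

test_that("SES area approaches the analytic sphere and is additive", {
  m1 <- compute_ses(single_atom(), probe_radius = 1.4, spacing = 0.3)
  a_ref <- 4 * pi * 1.7^2
  expect_lt(abs(mesh_area(m1) - a_ref) / a_ref, 0.03)
  two <- molray:::.ca_system(rbind(c(0, 0, 0), c(20, 0, 0)))
  m2 <- compute_ses(two, probe_radius = 1.4, spacing = 0.3)
  expect_lt(abs(mesh_area(m2) - 2 * a_ref) / (2 * a_ref), 0.03)
  # probe 0 degenerates to the van der Waals surface
  m0 <- compute_ses(single_atom(), probe_radius = 0, spacing = 0.3)
  expect_lt(abs(mesh_area(m0) - a_ref) / a_ref, 0.05)
})

test_that("mesh area converges with decreasing spacing", {
  a_ref <- 4 * pi * 1.7^2
  errs <- vapply(c(0.6, 0.3), function(s)
    abs(mesh_area(compute_ses(single_atom(), 1.4, s)) - a_ref) / a_ref,
    numeric(1))
  expect_lt(errs[2], errs[1] + 0.01)
  expect_lt(errs[2], 0.03)
})

test_that("SES encloses the vdW union and ignores atom order", {
  sys <- molray:::.ca_system(rbind(c(0, 0, 0), c(2.5, 0.5, 0), c(1, 2, 1)))
  sas <- build_sas_field(sys, 1.4, 0.4)
  h <- ses_level_field(sas, 1.4)
  # atom centers have negative h
  for (i in 1:3) {
    node <- round((coords(sys)[i, ] - h$origin) / h$spacing) + 1
    expect_lt(h$values[node[1], node[2], node[3]], 0)
  }
  # atom order must not matter
  sys_r <- molray:::.ca_system(coords(sys)[3:1, , drop = FALSE])
  m_a <- compute_ses(sys, 1.4, 0.4)
  m_b <- compute_ses(sys_r, 1.4, 0.4)
  expect_equal(mesh_area(m_a), mesh_area(m_b), tolerance = 1e-12)
  expect_equal(sort(m_a$vertices[, 1]), sort(m_b$vertices[, 1]),
               tolerance = 1e-9)
})

test_that("SES vertices carry nearest-atom colors", {
  two <- molray:::.ca_system(rbind(c(0, 0, 0), c(20, 0, 0)))
  cols <- matrix(0, 2, 4)
  cols[1, ] <- c(255, 0, 0, 255)
  cols[2, ] <- c(0, 0, 255, 255)
  mesh <- compute_ses(two, 1.4, 0.4, atom_colors = cols)
  left <- mesh$vertices[, 1] < 10
  expect_true(all(mesh$colors[left, 1] == 255))
  expect_true(all(mesh$colors[!left, 3] == 255))
})
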