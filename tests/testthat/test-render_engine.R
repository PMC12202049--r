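# cameras, ray-primitive intersection, G-buffer, post-processing

test_that("camera rays go through pixel centers; center ray is forward", {
  cam <- axis_camera(5)
  r <- camera_rays(cam, 1, 1)
  expect_equal(unname(r$dirs[1, ]), c(0, 0, -1), tolerance = 1e-12)
  r65 <- camera_rays(cam, 65, 65)
  expect_equal(unname(r65$dirs[33 + 32 * 65, ]), c(0, 0, -1), tolerance = 1e-12)
  # corner symmetry
  d <- r65$dirs
  expect_equal(abs(d[1, 1]), abs(d[65 * 65, 1]), tolerance = 1e-12)
  expect_equal(abs(d[1, 2]), abs(d[65 * 65, 2]), tolerance = 1e-12)
  # small-fov limit: rays converge to forward
  tight <- camera(position = c(0, 0, 5), target = c(0, 0, 0), fov = 1e-4)
  rt <- camera_rays(tight, 9, 9)
  expect_lt(max(abs(sweep(rt$dirs, 2, c(0, 0, -1)))), 1e-5)
})

test_that("trackball orbits preserve target distance and compose to identity", {
  cam <- camera(position = c(0, 0, 10), target = c(0, 0, 0))
  half <- trackball_update(cam, d_yaw = 180)
  expect_equal(half$position, c(0, 0, -10), tolerance = 1e-9)
  full <- trackball_update(cam, d_yaw = 360)
  expect_equal(full$position, cam$position, tolerance = 1e-6)
  rot <- trackball_update(cam, d_yaw = 33, d_pitch = 21, d_zoom = 0)
  expect_equal(sqrt(sum(rot$position^2)), 10, tolerance = 1e-9)
  zoom <- trackball_update(cam, d_zoom = log(2))
  expect_equal(sqrt(sum(zoom$position^2)), 20, tolerance = 1e-9)
  # pitch clamps near the pole instead of flipping
  steep <- trackball_update(cam, d_pitch = 300)
  elev <- asin(steep$position[2] / sqrt(sum(steep$position^2))) * 180 / pi
  expect_lte(abs(elev), 89 + 1e-6)
})

test_that("freefly moves in the rotated camera basis and inverts cleanly", {
  cam <- camera(position = c(0, 0, 10), target = c(0, 0, 0), mode = "freefly")
  fwd <- freefly_update(cam, move = c(0, 0, 3))
  expect_equal(fwd$position, c(0, 0, 7), tolerance = 1e-12)
  none <- freefly_update(cam)
  expect_equal(none$position, cam$position)
  expect_equal(none$orientation, cam$orientation)
  yawed <- freefly_update(freefly_update(cam, d_yaw = 25), d_yaw = -25)
  expect_equal(yawed$orientation, cam$orientation, tolerance = 1e-9)
})

test_that("ray-sphere intersection matches the closed form", {
  hit <- intersect_sphere(c(0, 0, 0), c(0, 0, -1), c(0, 0, -5), 1)
  expect_equal(hit$t, 4)
  expect_equal(hit$normal, c(0, 0, 1))
  expect_null(intersect_sphere(c(2, 0, 0), c(0, 0, -1), c(0, 0, -5), 1))
  tang <- intersect_sphere(c(1, 0, 0), c(0, 0, -1), c(0, 0, -5), 1)
  expect_equal(tang$t, 5, tolerance = 1e-6)
})

test_that("ray-cylinder intersection respects the open-segment contract", {
  # z-axis cylinder r = 0.5 between z in [-2, 2]
  a <- c(0, 0, -2); b <- c(0, 0, 2)
  hit <- intersect_cylinder(c(5, 0, 0), c(-1, 0, 0), a, b, 0.5)
  expect_equal(hit$t, 4.5)
  expect_equal(hit$normal, c(1, 0, 0))
  # beyond the endpoint: miss
  expect_null(intersect_cylinder(c(5, 0, 3), c(-1, 0, 0), a, b, 0.5))
  # along the axis inside the radius: miss (open cylinder)
  expect_null(intersect_cylinder(c(0, 0, -5), c(0, 0, 1), a, b, 0.5))
})

test_that("BVH mesh intersection equals a brute-force scan", {
  rng <- molray:::.local_rng(2024)
  nt <- 300L
  v <- matrix((rng$unif(3 * nt * 3) - 0.5) * 10, ncol = 3)
  f <- matrix(seq_len(3 * nt), ncol = 3, byrow = TRUE)
  mesh <- trimesh(v, NULL, f)
  bvh <- bvh_build(mesh)
  for (q in 1:120) {
    o <- (rng$unif(3) - 0.5) * 24
    d <- rng$unif(3) - 0.5
    d <- d / sqrt(sum(d^2))
    got <- intersect_mesh(bvh, o, d)
    want <- oracle_ray_mesh(o, d, v, f)
    if (is.null(got)) expect_equal(want, Inf)
    else expect_equal(got$t, want, tolerance = 1e-9)
  }
  # simple case: unit right triangle in the z = -3 plane
  tri <- trimesh(rbind(c(0, 0, -3), c(1, 0, -3), c(0, 1, -3)), NULL,
                 matrix(c(1, 2, 3), 1))
  h <- intersect_mesh(bvh_build(tri), c(1 / 3, 1 / 3, 0), c(0, 0, -1))
  expect_equal(h$t, 3)
  # ray in the triangle's plane misses
  expect_null(intersect_mesh(bvh_build(tri), c(-1, 0.2, -3), c(1, 0, 0)))
})

test_that("G-buffer depth is the exact eye distance for a sphere", {
  scn <- scene(spheres = sphere_df(0, 0, 0, 1))
  cam <- axis_camera(5)
  gb <- render_gbuffer(scn, cam, 65, 65)
  expect_equal(gb$depth[33, 33], 4)
  rays <- camera_rays(cam, 65, 65)
  b <- rays$dirs %*% c(0, 0, -5)       # toward center from origin offset
  disc <- b^2 - (25 - 1)
  texp <- rep(Inf, 65 * 65)
  ok <- disc >= 0
  texp[ok] <- b[ok] - sqrt(disc[ok])
  expect_lt(max(abs(gb$depth[is.finite(gb$depth)] - texp[is.finite(texp)])), 1e-6)
  # miss pixels: sentinel values
  expect_true(all(gb$objid[!is.finite(gb$depth)] == 0L))
  expect_true(all(gb$alb_a[!is.finite(gb$depth)] == 0))
  # empty scene -> all miss
  gb0 <- render_gbuffer(scene(), cam, 5, 5)
  expect_true(all(!is.finite(gb0$depth)))
  expect_error(render_gbuffer(scn, cam, 0, 5), ">= 1")
})

test_that("union-group spheres expose only the union boundary", {
  two <- sphere_df(c(0, 1), c(0, 0), c(0, 0), c(1, 1), group = 1L)
  cam <- camera(position = c(0.5, 0, 6), target = c(0.5, 0, 0), fov = 45)
  gb <- render_gbuffer(scene(spheres = two), cam, 65, 65)
  # center ray passes through the lens-shaped overlap: union entry at
  # z = sqrt(1 - 0.5^2) on either sphere
  expect_equal(gb$depth[33, 33], 6 - sqrt(0.75), tolerance = 1e-9)
  # no depth may lie strictly inside the union
  hit <- which(is.finite(gb$depth))
  rays <- camera_rays(cam, 65, 65)
  p <- sweep(rays$dirs[hit, , drop = FALSE] * gb$depth[hit], 2,
             cam$position, "+")
  d1 <- sqrt(rowSums(sweep(p, 2, c(0, 0, 0))^2))
  d2 <- sqrt(rowSums(sweep(p, 2, c(1, 0, 0))^2))
  expect_true(all(pmin(d1, d2) >= 1 - 1e-6))
})

test_that("shading models follow their stated formulas", {
  scn <- scene(spheres = sphere_df(0, 0, 0, 1, col = c(200, 100, 50, 255)))
  cam <- axis_camera(5)
  gb <- render_gbuffer(scn, cam, 33, 33)
  flat <- shade_deferred(gb, render_settings(shading = "flat"))
  expect_equal(flat$r[17, 17], 200)
  matte <- shade_deferred(gb, render_settings(shading = "matte"))
  # center pixel: N = (0,0,1), L = (0,0,1) -> N.L = 1
  expect_equal(matte$r[17, 17], 200 * (0.15 + 0.85), tolerance = 1e-9)
  # grazing pixel: N.L ~ 0 -> 0.15 * albedo
  edge <- which(is.finite(gb$depth) & abs(gb$nz) < 0.2, arr.ind = TRUE)
  if (nrow(edge)) {
    px <- edge[1, ]
    nl <- max(gb$nz[px[1], px[2]], 0)
    expect_equal(matte$r[px[1], px[2]], 200 * (0.15 + 0.85 * nl),
                 tolerance = 1e-9)
  }
  toon <- shade_deferred(gb, render_settings(shading = "toon"))
  expect_equal(toon$r[17, 17], 200)          # top band at N.L = 1
  bands <- unique(round(toon$r[is.finite(gb$depth)] / 200, 10))
  expect_true(all(bands %in% c(0.25, 0.5, 0.75, 1)))
  glossy <- shade_deferred(gb, render_settings(shading = "glossy"))
  expect_equal(glossy$r[17, 17], min(200 * 1 + 255 * 0.4, 255))
})

test_that("SSAO is 1 on open planes, lower in a concave corner, in [0,1]", {
  floor_m <- quad_mesh(c(-50, -50, 0), c(50, -50, 0), c(50, 50, 0), c(-50, 50, 0))
  wall_m <- quad_mesh(c(-50, 0, 0), c(50, 0, 0), c(50, 0, 60), c(-50, 0, 60))
  cam <- camera(position = c(0, -4, 4), target = c(0, -1, 0), fov = 60)
  gb_f <- render_gbuffer(scene(meshes = list(floor_m)), cam, 33, 33)
  gb_c <- render_gbuffer(scene(meshes = list(floor_m, wall_m)), cam, 33, 33)
  # identify a floor pixel near the corner line (y in [-0.5, -0.1], z = 0)
  rays <- camera_rays(cam, 33, 33)
  hp <- sweep(rays$dirs * as.vector(gb_c$depth), 2, cam$position, "+")
  corner_px <- which(abs(hp[, 3]) < 1e-6 & hp[, 2] > -0.5 & hp[, 2] < -0.1)[1]
  expect_false(is.na(corner_px))
  flat_vals <- corner_vals <- numeric(3)
  for (sd in 1:3) {
    of <- ssao(gb_f, 32, 1.5, seed = sd)
    oc <- ssao(gb_c, 32, 1.5, seed = sd)
    expect_true(all(of >= 0 & of <= 1))
    expect_true(all(oc >= 0 & oc <= 1))
    flat_vals[sd] <- mean(of)
    corner_vals[sd] <- oc[corner_px]
  }
  expect_gte(mean(flat_vals), 0.95)
  expect_lt(mean(corner_vals), mean(flat_vals))
})

test_that("SSAO is monotone under an added occluder", {
  plane <- quad_mesh(c(-50, -50, 0), c(50, -50, 0), c(50, 50, 0), c(-50, 50, 0))
  cam <- camera(position = c(0, 0, 6), target = c(0, 0, 0), fov = 50)
  occluder <- sphere_df(0, 0, 0.9, 0.8)
  gb_open <- render_gbuffer(scene(meshes = list(plane)), cam, 33, 33)
  gb_occ <- render_gbuffer(scene(spheres = occluder, meshes = list(plane)),
                           cam, 33, 33)
  plane_px <- which(gb_occ$objid == 2L & is.finite(gb_open$depth))
  for (sd in 1:3) {
    o1 <- ssao(gb_open, 32, 1.5, seed = sd)
    o2 <- ssao(gb_occ, 32, 1.5, seed = sd)
    expect_lte(mean(o2[plane_px]), mean(o1[plane_px]) + 1e-12)
  }
})

test_that("linear fog follows its formula and skips miss pixels", {
  sh <- list(r = matrix(100, 2, 2), g = matrix(100, 2, 2),
             b = matrix(100, 2, 2), alpha = matrix(255, 2, 2))
  dep <- matrix(c(0, 5, 10, Inf), 2, 2)
  fogged <- apply_fog(sh, dep, list(near = 0, far = 10,
                                    color = c(255, 255, 255), density = 1))
  expect_equal(fogged$r[1, 1], 100)            # depth = near
  expect_equal(fogged$r[2, 1], 177.5)          # midpoint, exact average
  expect_equal(fogged$r[1, 2], 255)            # depth >= far
  expect_equal(fogged$r[2, 2], 100)            # miss untouched
  expect_error(apply_fog(sh, dep, list(near = 5, far = 5, color = 0,
                                       density = 1)), "far")
})

test_that("outline mask rings the silhouette and honors the threshold", {
  scn <- scene(spheres = sphere_df(0, 0, 0, 1))
  cam <- axis_camera(5)
  gb <- render_gbuffer(scn, cam, 65, 65)
  mask <- detect_outline(gb, threshold = 0.05)
  hit <- is.finite(gb$depth)
  shift <- function(m, dr, dc) molray:::.shift_mat(m, dr, dc)
  boundary <- hit & (!shift(hit, -1, 0) | !shift(hit, 1, 0) |
                       !shift(hit, 0, -1) | !shift(hit, 0, 1))
  expect_true(all(mask[boundary]))             # closed ring
  # uniform buffer -> empty mask; infinite threshold -> empty mask
  gb0 <- render_gbuffer(scene(), cam, 17, 17)
  expect_false(any(detect_outline(gb0, 0.05)))
  expect_false(any(detect_outline(gb, Inf)))
  # thickness dilates
  expect_gte(sum(detect_outline(gb, 0.05, thickness = 3L)), sum(mask))
})

test_that("supersampling AA preserves flat regions and blends silhouettes", {
  scn <- scene(spheres = sphere_df(0, 0, 0, 1))
  cam <- axis_camera(5)
  opaque <- c(0, 0, 0, 255)
  plainset <- render_settings(shading = "flat", background = opaque)
  aaset <- render_settings(shading = "flat", background = opaque,
                           aa = list(enabled = TRUE, factor = 4L))
  i1 <- render_snapshot(scn, cam, plainset, 33, 33)
  i4 <- render_snapshot(scn, cam, aaset, 33, 33)
  expect_equal(dim(i4), dim(i1))
  # factor-1 AA is the identity pipeline
  aa1 <- render_settings(shading = "flat", background = opaque,
                         aa = list(enabled = TRUE, factor = 1L))
  expect_image_equal(render_snapshot(scn, cam, aa1, 33, 33), i1)
  # interior and far background unchanged; silhouette blends
  expect_equal(i4[17, 17, 1], i1[17, 17, 1])
  expect_true(any(i4[, , 1] > 0 & i4[, , 1] < 255))
  # constant scene invariant under AA
  e1 <- render_snapshot(scene(), cam, plainset, 8, 8)
  e2 <- render_snapshot(scene(), cam,
                        render_settings(shading = "flat", background = opaque,
                                        aa = list(enabled = TRUE, factor = 2L)),
                        8, 8)
  expect_image_equal(e1, e2)
})

test_that("background compositing is source-over with alpha preserved", {
  scn <- scene(spheres = sphere_df(0, 0, 0, 1, col = c(10, 200, 30, 255)))
  cam <- axis_camera(5)
  transparent <- render_settings(shading = "flat", background = c(0, 0, 0, 0))
  white <- render_settings(shading = "flat", background = c(255, 255, 255, 255))
  it <- render_snapshot(scn, cam, transparent, 33, 33)
  iw <- render_snapshot(scn, cam, white, 33, 33)
  expect_equal(it[1, 1, 4], 0L)                     # corner: miss, alpha 0
  expect_equal(iw[1, 1, ], c(255L, 255L, 255L, 255L))
  # geometry pixels unchanged by background choice
  expect_equal(it[17, 17, ], iw[17, 17, ])
  # mismatched background image errors
  bad_bg <- new_image(5, 5, c(0, 0, 0, 255))
  expect_error(render_snapshot(scn, cam,
                               render_settings(background = bad_bg), 33, 33),
               "dimensions")
})

test_that("pipeline is deterministic and each stage gates cleanly", {
  scn <- scene(spheres = sphere_df(c(0, 1.2), c(0, 0.4), c(0, -0.5),
                                   c(1, 0.8), col = c(180, 40, 90, 255)))
  cam <- axis_camera(6)
  full <- render_settings(shading = "glossy",
                          ssao = list(enabled = TRUE, seed = 7L),
                          fog = list(enabled = TRUE, near = 2, far = 12,
                                     density = 0.6),
                          outline = list(enabled = TRUE, threshold = 0.05),
                          aa = list(enabled = TRUE, factor = 2L),
                          background = c(30, 30, 60, 255))
  i1 <- render_snapshot(scn, cam, full, 48, 48)
  i2 <- render_snapshot(scn, cam, full, 48, 48)
  expect_image_equal(i1, i2)
  # PNG bytes bit-identical
  f1 <- file.path(tempdir(), "d1.png"); f2 <- file.path(tempdir(), "d2.png")
  write_png(i1, f1); write_png(i2, f2)
  expect_identical(readBin(f1, "raw", 1e6), readBin(f2, "raw", 1e6))
  # disabling one stage reproduces the simpler pipeline bit-exactly
  for (stage in c("ssao", "fog", "outline", "aa")) {
    args <- list(shading = "glossy",
                 ssao = list(enabled = TRUE, seed = 7L),
                 fog = list(enabled = TRUE, near = 2, far = 12, density = 0.6),
                 outline = list(enabled = TRUE, threshold = 0.05),
                 aa = list(enabled = TRUE, factor = 2L),
                 background = c(30, 30, 60, 255))
    args[[stage]]["enabled"] <- FALSE
    off1 <- render_snapshot(scn, cam, do.call(render_settings, args), 48, 48)
    off2 <- render_snapshot(scn, cam, do.call(render_settings, args), 48, 48)
    expect_image_equal(off1, off2)
    expect_false(isTRUE(all.equal(unclass(off1), unclass(i1))))
  }
  # 8K cap is enforced
  expect_error(render_snapshot(scn, cam, full, 7681, 100), "8K")
})
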