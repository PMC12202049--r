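# representation builders, color schemes, secondary structure, cartoon

test_that("build_vdw emits one sphere per selected atom with scaled radii", {
  sys <- read_pdb(make_toy_pdb_text("minimal"))
  s <- build_vdw(sys)
  expect_equal(nrow(s), 3L)
  expect_equal(s$r, sys$atoms$vdw_radius)
  expect_equal(build_vdw(sys, scale = 0.5)$r, sys$atoms$vdw_radius / 2)
  expect_equal(nrow(build_vdw(sys, integer(0))), 0L)
})

test_that("build_sas_spheres inflates by the probe and shares a union group", {
  one <- molray:::.ca_system(matrix(0, 1, 3))
  s <- build_sas_spheres(one, probe = 1.4)
  expect_equal(s$r, 1.7 + 1.4)
  expect_equal(build_sas_spheres(one, probe = 0)$r, 1.7)
  two <- molray:::.ca_system(rbind(c(0, 0, 0), c(1, 0, 0)))
  s2 <- build_sas_spheres(two)
  expect_equal(nrow(s2), 2L)
  expect_length(unique(s2$union_group), 1L)
})

test_that("sticks: one cylinder per selected bond, caps for all selected atoms", {
  chain3 <- molray:::.ca_system(rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0)))
  chain3$bonds <- rbind(c(1L, 2L), c(2L, 3L))
  st <- build_sticks(chain3)
  expect_equal(nrow(st$cylinders), 2L)
  expect_equal(nrow(st$spheres), 3L)
  expect_equal(unique(st$spheres$r), 0.15)
  # partial selection drops cylinders missing an endpoint
  st2 <- build_sticks(chain3, c(1L, 2L))
  expect_equal(nrow(st2$cylinders), 1L)
  expect_equal(nrow(st2$spheres), 2L)
  # no bonds: caps only
  lone <- molray:::.ca_system(matrix(0, 1, 3))
  st3 <- build_sticks(lone)
  expect_equal(nrow(st3$cylinders), 0L)
  expect_equal(nrow(st3$spheres), 1L)
})

test_that("ball-and-stick scales balls from vdW radii", {
  two <- molray:::.ca_system(rbind(c(0, 0, 0), c(1.54, 0, 0)))
  two$bonds <- rbind(c(1L, 2L))
  bs <- build_ball_and_stick(two)
  expect_equal(bs$spheres$r, c(0.51, 0.51))   # 0.3 * 1.70
  expect_equal(nrow(bs$cylinders), 1L)
  lone <- molray:::.ca_system(matrix(0, 1, 3))
  bs2 <- build_ball_and_stick(lone)
  expect_equal(nrow(bs2$spheres), 1L)
  expect_equal(nrow(bs2$cylinders), 0L)
})

test_that("color schemes: element table, chain palette cycling, uniform", {
  atoms <- data.frame(name = c("O1", "C1", "X1"), element = c("O", "C", "Xq"),
                      chain_id = c("A", "B", "B"), residue_name = "L",
                      residue_seq = 1L)
  sys <- molecule_system(atoms, matrix(0, 3, 3))
  ce <- assign_colors(sys, "element")
  expect_equal(ce[1, 1:3], c(255, 13, 13))          # CPK red oxygen
  expect_equal(ce[3, 1:3], c(255, 105, 180))        # pink fallback
  cc <- assign_colors(sys, "chain")
  expect_equal(cc[1, 1:3], molray:::.CHAIN_PALETTE[1, ])
  expect_equal(cc[2, 1:3], molray:::.CHAIN_PALETTE[2, ])
  expect_equal(cc[2, ], cc[3, ])
  cu <- assign_colors(sys, "uniform", c(0, 255, 0))
  expect_true(all(cu[, 2] == 255) && all(cu[, 1] == 0))
})

test_that("CA-geometry secondary structure separates helix from extended", {
  ss_h <- assign_secondary_structure(make_ideal_helix(12))
  expect_gte(sum(ss_h$ss == "helix"), 8)
  ss_e <- assign_secondary_structure(make_extended_chain(12))
  expect_equal(sum(ss_e$ss == "helix"), 0)
  # chains under 5 CA are all coil
  ss_s <- assign_secondary_structure(make_ideal_helix(4))
  expect_true(all(ss_s$ss == "coil"))
  # file records take precedence
  hx <- read_pdb(make_toy_pdb_text("helix_record"))
  ss_f <- assign_secondary_structure(hx)
  expect_equal(ss_f$residue_seq[ss_f$ss == "helix"], 2:10)
})

test_that("cartoon sweeps a closed mesh along the CA spline", {
  tube <- build_cartoon(make_extended_chain(4))
  ext <- diff(range(tube$vertices[, 1]))
  expect_lt(abs(ext - 11.4), 0.5)

  helix <- build_cartoon(make_ideal_helix(20))
  expect_true(all(is.finite(helix$vertices)))
  expect_equal(sqrt(rowSums(helix$normals^2)), rep(1, nrow(helix$normals)),
               tolerance = 1e-6)
  # vertices within the inflated convex hull of the CA trace
  ca <- coords(make_ideal_helix(20))
  lo <- apply(ca, 2, min) - 2; hi <- apply(ca, 2, max) + 2
  expect_true(all(sweep(helix$vertices, 2, lo, ">=") &
                    sweep(helix$vertices, 2, hi, "<=")))

  # refinement changes vertex count, not extent
  c2 <- build_cartoon(make_extended_chain(4), subdivisions_per_residue = 2L)
  c16 <- build_cartoon(make_extended_chain(4), subdivisions_per_residue = 16L)
  expect_lt(nrow(c2$vertices), nrow(c16$vertices))
  expect_equal(diff(range(c2$vertices[, 1])), diff(range(c16$vertices[, 1])),
               tolerance = 0.3)
  expect_warning(build_cartoon(make_ideal_helix(1)), "fewer than 2")
})

test_that("builders are permutation-stable", {
  sys <- make_sphere_cluster(10, box = 15, min_sep = 2.5, seed = 5)
  perm <- c(4, 1, 9, 2, 10, 3, 8, 5, 7, 6)
  sys_p <- assign_radii(molecule_system(sys$atoms[perm, ],
                                        coords(sys)[perm, , drop = FALSE]))
  a <- build_vdw(sys)
  b <- build_vdw(sys_p)
  expect_equal(sort(a$x), sort(b$x))
  expect_equal(a$r[order(a$x)], b$r[order(b$x)])
})
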