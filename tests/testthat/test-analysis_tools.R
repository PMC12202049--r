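# measurements, Kabsch superposition, CE alignment

test_that("distance/angle/dihedral measures obey their conventions", {
  expect_equal(measure_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(measure_distance(c(1, 1, 1), c(1, 1, 1)), 0)
  expect_equal(measure_distance(c(1, 2, 3), c(-2, 0, 5)),
               measure_distance(c(-2, 0, 5), c(1, 2, 3)))

  expect_equal(measure_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(measure_angle(c(1, 0, 0), c(0, 0, 0), c(2, 0, 0)), 0)
  expect_equal(measure_angle(c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0)), 180)
  expect_error(measure_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "degenerate")

  # planar cis -> 0, trans -> 180, mirror flips the sign
  cis <- measure_dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(abs(cis), 0, tolerance = 1e-9)
  trans <- measure_dihedral(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(abs(trans), 180)
  twist <- measure_dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0.5))
  mirror <- measure_dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, -0.5))
  expect_equal(twist, -mirror, tolerance = 1e-9)
  expect_error(measure_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
               "degenerate")
})

test_that("kabsch recovers exact rigid transforms", {
  rng <- molray:::.local_rng(31)
  P <- matrix((rng$unif(30) - 0.5) * 10, 10, 3)
  expect_equal(kabsch_superpose(P, P)$rmsd, 0, tolerance = 1e-12)
  expect_equal(kabsch_superpose(P, P)$rotation, diag(3), tolerance = 1e-9)
  R <- rotation_z(0.9) %*% rotation_z(0)  # proper rotation
  Q <- P %*% t(R) + matrix(c(1, -2, 3), 10, 3, byrow = TRUE)
  k <- kabsch_superpose(P, Q)
  expect_lt(max(abs(k$rotation - R)), 1e-9)
  expect_lt(k$rmsd, 1e-9)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch_superpose(P[1:2, ], Q[1:2, ]), ">= 3")
})

test_that("kabsch rmsd under isotropic noise sits in the expected envelope", {
  # sigma = 0.1 A per axis on n = 100 points: E[rmsd] ~ sigma * sqrt(3)
  # after removal of 6 rigid dof; Monte-Carlo envelope [0.05, 0.25]
  rng <- molray:::.local_rng(17)
  inside <- 0L
  n_rep <- 100L
  for (rep in seq_len(n_rep)) {
    P <- matrix((rng$unif(300) - 0.5) * 20, 100, 3)
    noise <- matrix(stats::qnorm(rng$unif(300)) * 0.1, 100, 3)
    r <- kabsch_superpose(P, P + noise)$rmsd
    if (r >= 0.05 && r <= 0.25) inside <- inside + 1L
  }
  expect_equal(inside, n_rep)
})

test_that("CE aligns identical and rigidly moved chains end to end", {
  A <- make_wiggle_chain(30)
  self <- ce_align(A, A)
  expect_equal(self$aligned_length, 30L)
  expect_lt(self$rmsd, 1e-6)
  R <- rotation_z(1.1)
  B <- A %*% t(R) + matrix(c(5, -3, 2), 30, 3, byrow = TRUE)
  rigid <- ce_align(A, B)
  expect_equal(rigid$aligned_length, 30L)
  expect_lt(rigid$rmsd, 1e-6)
  # pairs strictly increasing in both sequences
  expect_true(all(diff(rigid$pairs[, 1]) > 0))
  expect_true(all(diff(rigid$pairs[, 2]) > 0))
  expect_equal(det(rigid$rotation), 1, tolerance = 1e-9)
})

test_that("CE fragment containment matches the brute-force path oracle", {
  A <- make_wiggle_chain(30)
  B <- A[8:23, , drop = FALSE]
  got <- ce_align(A, B, max_gap = 5)

  # oracle: full enumeration of admissible AFP paths (no pruning)
  m <- 8L; d0 <- 3.0; d1 <- 4.0; max_gap <- 5L
  DA <- as.matrix(dist(A)); DB <- as.matrix(dist(B))
  S <- molray:::.afp_similarity(DA, DB, m)
  adm <- which(S <= d0, arr.ind = TRUE)
  adm <- adm[order(adm[, 1], adm[, 2]), , drop = FALSE]
  pairs_of <- function(path) {
    u <- unique(cbind(unlist(lapply(path, function(p) p[1] + 0:(m - 1))),
                      unlist(lapply(path, function(p) p[2] + 0:(m - 1)))))
    u[order(u[, 1]), , drop = FALSE]
  }
  best <- list(len = -1L, rmsd = Inf)
  enum <- function(path) {
    pr <- pairs_of(path)
    r <- kabsch_superpose(A[pr[, 1], , drop = FALSE],
                          B[pr[, 2], , drop = FALSE])$rmsd
    if (nrow(pr) > best$len ||
        (nrow(pr) == best$len && r < best$rmsd - 1e-12))
      best <<- list(len = nrow(pr), rmsd = r)
    last <- path[[length(path)]]
    for (q in seq_len(nrow(adm))) {
      cand <- adm[q, ]
      di <- cand[1] - last[1]; dj <- cand[2] - last[2]
      if (di < 1 || dj < 1) next
      step_ok <- if (di == dj) di < m || (di - m) <= max_gap
      else di >= m && dj >= m && (di - m) <= max_gap && (dj - m) <= max_gap
      if (!step_ok) next
      ok <- all(vapply(path, function(p)
        molray:::.afp_cross(DA, DB, p[1], p[2], cand[1], cand[2], m) <= d1,
        logical(1)))
      if (ok) enum(c(path, list(cand)))
    }
  }
  for (q in seq_len(nrow(adm))) enum(list(adm[q, ]))

  expect_equal(got$aligned_length, best$len)
  expect_equal(got$rmsd, best$rmsd, tolerance = 1e-9)
  expect_equal(got$aligned_length, 16L)
  expect_equal(got$pairs[, 1], 8:23)       # covers the fragment
  expect_equal(got$pairs[, 2], 1:16)
})

test_that("CE is symmetric and internally consistent; disjoint chains empty", {
  A <- make_wiggle_chain(26, seed = 12)
  B <- make_wiggle_chain(20, seed = 77)
  ab <- ce_align(A, B)
  ba <- ce_align(B, A)
  expect_equal(ab$aligned_length, ba$aligned_length)
  if (ab$aligned_length > 0) {
    expect_equal(ab$rmsd, ba$rmsd, tolerance = 1e-9)
    k <- kabsch_superpose(A[ab$pairs[, 1], , drop = FALSE],
                          B[ab$pairs[, 2], , drop = FALSE])
    expect_equal(ab$rmsd, k$rmsd, tolerance = 1e-12)
  }
  # grossly incompatible geometry: no admissible AFP
  line <- cbind(seq(0, by = 38, length.out = 10), 0, 0)   # 38 A spacing
  res <- ce_align(make_wiggle_chain(10), line)
  expect_equal(res$aligned_length, 0L)
})
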