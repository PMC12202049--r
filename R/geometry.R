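# Renderable geometry builders: implicit sphere/cylinder lists for the
# meshless representations (Van der Waals, solvent-accessible surface,
# sticks, ball-and-sticks) and triangle meshes for cartoon ribbons.
# All builders are deterministic and permutation-stable in file order.

.empty_spheres <- function() data.frame(
  x = numeric(0), y = numeric(0), z = numeric(0), r = numeric(0),
  cr = numeric(0), cg = numeric(0), cb = numeric(0), ca = numeric(0),
  atom_ref = integer(0), union_group = integer(0))

.empty_cylinders <- function() data.frame(
  ax = numeric(0), ay = numeric(0), az = numeric(0),
  bx = numeric(0), by = numeric(0), bz = numeric(0), r = numeric(0),
  cr_a = numeric(0), cg_a = numeric(0), cb_a = numeric(0),
  cr_b = numeric(0), cg_b = numeric(0), cb_b = numeric(0),
  atom_i = integer(0), atom_j = integer(0))

#' Assemble a renderable scene
#' @param spheres sphere data.frame (from the builders) or NULL
#' @param cylinders cylinder data.frame or NULL
#' @param meshes list of `trimesh`
#' @param labels list of measurement labels (anchor + text)
#' @export
scene <- function(spheres = NULL, cylinders = NULL, meshes = list(),
                  labels = list()) {
  structure(list(
    spheres = if (is.null(spheres)) .empty_spheres() else spheres,
    cylinders = if (is.null(cylinders)) .empty_cylinders() else cylinders,
    meshes = meshes, labels = labels), class = "molscene")
}

#' Per-atom colors
#'
#' `element` uses the shipped CPK-style table (unknown elements: pink);
#' `chain` cycles a fixed 10-color palette by order of first appearance;
#' `uniform` paints everything `color`.
#'
#' @param system a `molsys`
#' @param scheme `"element"`, `"chain"` or `"uniform"`
#' @param color RGB(A) 0-255 vector for the uniform scheme
#' @return n_atoms x 4 RGBA matrix (0-255)
#' @export
assign_colors <- function(system, scheme = c("element", "chain", "uniform"),
                          color = c(200, 200, 200)) {
  scheme <- match.arg(scheme)
  n <- n_atoms(system)
  rgb <- switch(scheme,
    element = t(vapply(system$atoms$element, function(el) {
      cc <- .ELEMENT_COLORS[[el]]
      if (is.null(cc)) .ELEMENT_COLOR_FALLBACK else cc
    }, numeric(3))),
    chain = {
      ord <- unique(system$atoms$chain_id)
      idx <- ((match(system$atoms$chain_id, ord) - 1L) %% nrow(.CHAIN_PALETTE)) + 1L
      .CHAIN_PALETTE[idx, , drop = FALSE]
    },
    uniform = matrix(rep(color[1:3], each = n), n, 3))
  a <- if (length(color) >= 4 && scheme == "uniform") color[4] else 255
  unname(cbind(rgb, rep(a, n)))
}

#' Van der Waals sphere representation
#' @param system a `molsys` with radii assigned
#' @param selection `molsel` atom indices (default: all)
#' @param scale radius multiplier
#' @param colors n_atoms x 4 RGBA matrix (default element scheme)
#' @export
build_vdw <- function(system, selection = NULL, scale = 1.0, colors = NULL) {
  sel <- .resolve_sel(system, selection)
  if (!length(sel)) return(.empty_spheres())
  if (is.null(colors)) colors <- assign_colors(system, "element")
  xyz <- coords(system)
  data.frame(x = xyz[sel, 1], y = xyz[sel, 2], z = xyz[sel, 3],
             r = scale * system$atoms$vdw_radius[sel],
             cr = colors[sel, 1], cg = colors[sel, 2], cb = colors[sel, 3],
             ca = colors[sel, 4], atom_ref = sel, union_group = NA_integer_)
}

#' Solvent Accessible Surface as a sphere union
#'
#' Spheres of radius `r_i + probe` sharing one union group, so the renderer
#' shows only the boundary of their union.
#' @inheritParams build_vdw
#' @param probe probe radius (Angstrom)
#' @export
build_sas_spheres <- function(system, selection = NULL, probe = 1.4,
                              colors = NULL) {
  s <- build_vdw(system, selection, scale = 1.0, colors = colors)
  if (nrow(s)) {
    s$r <- s$r + probe
    s$union_group <- 1L
  }
  s
}

#' Stick representation (bond cylinders + atom cap spheres)
#'
#' One cylinder per bond whose two endpoints are both selected, colored by
#' endpoint atom and split at the bond midpoint; every selected atom gets a
#' cap sphere of the stick radius (isolated atoms keep their cap).
#' @inheritParams build_vdw
#' @param radius stick radius (Angstrom)
#' @return list(cylinders, spheres)
#' @export
build_sticks <- function(system, selection = NULL, radius = 0.15,
                         colors = NULL) {
  sel <- .resolve_sel(system, selection)
  if (is.null(colors)) colors <- assign_colors(system, "element")
  xyz <- coords(system)
  caps <- if (length(sel)) data.frame(
    x = xyz[sel, 1], y = xyz[sel, 2], z = xyz[sel, 3], r = radius,
    cr = colors[sel, 1], cg = colors[sel, 2], cb = colors[sel, 3],
    ca = colors[sel, 4], atom_ref = sel, union_group = NA_integer_)
  else .empty_spheres()
  b <- system$bonds
  keep <- b[, 1] %in% sel & b[, 2] %in% sel
  b <- b[keep, , drop = FALSE]
  cyl <- if (nrow(b)) data.frame(
    ax = xyz[b[, 1], 1], ay = xyz[b[, 1], 2], az = xyz[b[, 1], 3],
    bx = xyz[b[, 2], 1], by = xyz[b[, 2], 2], bz = xyz[b[, 2], 3],
    r = radius,
    cr_a = colors[b[, 1], 1], cg_a = colors[b[, 1], 2], cb_a = colors[b[, 1], 3],
    cr_b = colors[b[, 2], 1], cg_b = colors[b[, 2], 2], cb_b = colors[b[, 2], 3],
    atom_i = b[, 1], atom_j = b[, 2])
  else .empty_cylinders()
  list(cylinders = cyl, spheres = caps)
}

#' Ball-and-stick representation
#' @inheritParams build_sticks
#' @param ball_scale atom sphere radius as a fraction of the vdW radius
#' @param stick_radius bond cylinder radius (Angstrom)
#' @return list(spheres, cylinders)
#' @export
build_ball_and_stick <- function(system, selection = NULL, ball_scale = 0.3,
                                 stick_radius = 0.15, colors = NULL) {
  balls <- build_vdw(system, selection, scale = ball_scale, colors = colors)
  st <- build_sticks(system, selection, radius = stick_radius, colors = colors)
  list(spheres = balls, cylinders = st$cylinders)
}

.resolve_sel <- function(system, selection) {
  if (is.null(selection)) return(seq_len(n_atoms(system)))
  idx <- as.integer(selection)
  if (length(idx) && (min(idx) < 1L || max(idx) > n_atoms(system)))
    stop("selection index out of range", call. = FALSE)
  sort(unique(idx))
}

# ---- Secondary structure ----------------------------------------------------

#' Assign per-residue secondary structure
#'
#' File HELIX/SHEET records take precedence when present. Otherwise a
#' CA-geometry rule (P-SEA-like) is applied per chain from the distances
#' d13 = |CA_i - CA_(i+2)|, d14 = |CA_i - CA_(i+3)|, d15 = |CA_i - CA_(i+4)|:
#' helix when 4.8 <= d13 <= 5.8, 4.9 <= d14 <= 6.1 and 5.7 <= d15 <= 6.6;
#' sheet when d13 >= 6.4 and d14 >= 9.0; else coil. Runs shorter than 3
#' residues revert to coil; chains with fewer than 5 CA atoms are all coil.
#'
#' @param system a `molsys`
#' @return data.frame with `chain_id`, `residue_seq`, `ss`
#'   (helix/sheet/coil), one row per residue that has a CA atom
#' @export
assign_secondary_structure <- function(system) {
  atoms <- system$atoms
  xyz <- coords(system)
  ca <- which(toupper(atoms$name) == "CA" & atoms$element == "C")
  if (!length(ca)) ca <- which(toupper(atoms$name) == "CA")
  out <- list()
  for (ch in unique(atoms$chain_id[ca])) {
    idx <- ca[atoms$chain_id[ca] == ch]
    idx <- idx[order(atoms$residue_seq[idx])]
    n <- length(idx)
    res <- atoms$residue_seq[idx]
    ss <- rep("coil", n)
    if (!is.null(system$ss_records) &&
        any(system$ss_records$chain_id == ch)) {
      rc <- system$ss_records[system$ss_records$chain_id == ch, , drop = FALSE]
      for (q in seq_len(nrow(rc)))
        ss[res >= rc$res_start[q] & res <= rc$res_end[q]] <- rc$kind[q]
    } else if (n >= 5) {
      p <- xyz[idx, , drop = FALSE]
      dd <- function(k) c(sqrt(rowSums((p[seq_len(n - k), , drop = FALSE] -
                                          p[(1 + k):n, , drop = FALSE])^2)),
                          rep(NA, k))
      d13 <- dd(2); d14 <- dd(3); d15 <- dd(4)
      helix <- !is.na(d15) & d13 >= 4.8 & d13 <= 5.8 &
        d14 >= 4.9 & d14 <= 6.1 & d15 >= 5.7 & d15 <= 6.6
      sheet <- !is.na(d14) & d13 >= 6.4 & d14 >= 9.0
      ss[sheet] <- "sheet"
      ss[helix] <- "helix"
      ss <- .drop_short_runs(ss, 3L)
    }
    out[[length(out) + 1L]] <- data.frame(
      chain_id = ch, residue_seq = res, ss = ss, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chain_id = character(0), residue_seq = integer(0),
                      ss = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

.drop_short_runs <- function(ss, min_len) {
  r <- rle(ss)
  r$values[r$lengths < min_len & r$values != "coil"] <- "coil"
  inverse.rle(r)
}

# ---- Cartoon ribbons --------------------------------------------------------

# Centripetal Catmull-Rom interpolation between p1 and p2 (with outer control
# points p0, p3), sampled at the given parameter fractions in [0,1).
.catmull_rom <- function(p0, p1, p2, p3, fracs) {
  tj <- function(ti, pa, pb) ti + sqrt(sqrt(sum((pb - pa)^2)) + 1e-12)
  t0 <- 0; t1 <- tj(t0, p0, p1); t2 <- tj(t1, p1, p2); t3 <- tj(t2, p2, p3)
  t <- t1 + fracs * (t2 - t1)
  lerp <- function(pa, pb, ta, tb)
    outer((tb - t) / (tb - ta), pa) + outer((t - ta) / (tb - ta), pb)
  a1 <- lerp(p0, p1, t0, t1); a2 <- lerp(p1, p2, t1, t2); a3 <- lerp(p2, p3, t2, t3)
  b1 <- (a1 * ((t2 - t) / (t2 - t0)) + a2 * ((t - t0) / (t2 - t0)))
  b2 <- (a2 * ((t3 - t) / (t3 - t1)) + a3 * ((t - t1) / (t3 - t1)))
  b1 * ((t2 - t) / (t2 - t1)) + b2 * ((t - t1) / (t2 - t1))
}

# Rotation-minimizing frames along a polyline (double-reflection method).
.rmf_frames <- function(pts) {
  n <- nrow(pts)
  tangents <- matrix(0, n, 3)
  tangents[-n, ] <- pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE]
  tangents[n, ] <- tangents[n - 1, ]
  len <- sqrt(rowSums(tangents^2))
  zero <- len < 1e-12
  if (any(zero)) { # duplicate samples: reuse previous direction
    for (i in which(zero)) tangents[i, ] <- if (i > 1) tangents[i - 1, ] else c(1, 0, 0)
    len <- sqrt(rowSums(tangents^2))
  }
  tangents <- tangents / len
  up <- c(0, 0, 1)
  if (abs(sum(up * tangents[1, ])) > 0.9) up <- c(1, 0, 0)
  r <- crossprod3(tangents[1, ], up)
  r <- r / sqrt(sum(r^2))
  normals <- matrix(0, n, 3)
  normals[1, ] <- crossprod3(r, tangents[1, ])
  for (i in seq_len(n - 1)) {
    v1 <- pts[i + 1, ] - pts[i, ]
    c1 <- sum(v1 * v1)
    if (c1 < 1e-18) { normals[i + 1, ] <- normals[i, ]; next }
    rL <- normals[i, ] - (2 / c1) * sum(v1 * normals[i, ]) * v1
    tL <- tangents[i, ] - (2 / c1) * sum(v1 * tangents[i, ]) * v1
    v2 <- tangents[i + 1, ] - tL
    c2 <- sum(v2 * v2)
    normals[i + 1, ] <- if (c2 < 1e-18) rL else rL - (2 / c2) * sum(v2 * rL) * v2
  }
  list(t = tangents, n = normals)
}

# Cross-section outline (m x 2, local u/v coords) per secondary-structure
# class. Half-widths: coil tube r=0.3; helix ellipse 1.1 x 0.25; sheet
# rectangle 1.1 x 0.25 widening to 1.6 over the arrowhead.
.cross_section <- function(ss, m = 12L, width = NULL) {
  th <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
  switch(ss,
    coil = cbind(0.3 * cos(th), 0.3 * sin(th)),
    helix = cbind(1.1 * cos(th), 0.25 * sin(th)),
    sheet = {
      w <- if (is.null(width)) 1.1 else width
      u <- c(w, w, -w, -w)
      v <- c(0.25, -0.25, -0.25, 0.25)
      # resample the rectangle to m points so ring sizes match everywhere
      t(vapply(seq_len(m), function(i) {
        s <- (i - 1) / m * 4
        k <- floor(s) + 1
        f <- s - floor(s)
        k2 <- if (k == 4) 1 else k + 1
        c(u[k] + f * (u[k2] - u[k]), v[k] + f * (v[k2] - v[k]))
      }, numeric(2)))
    })
}

#' Cartoon ribbon mesh
#'
#' Centripetal Catmull-Rom spline through the CA trace of each chain,
#' rotation-minimizing frames, and swept cross-sections stitched into a
#' closed triangle mesh: circular tube for coil, elliptic ribbon for helix,
#' rectangular ribbon for sheet ending in an arrowhead (1.6 A half-width)
#' over the last residue of each sheet run. Vertex colors follow the
#' residue's first atom.
#'
#' @param system a `molsys`
#' @param subdivisions_per_residue spline samples per residue (>= 1)
#' @param colors optional n_atoms x 4 RGBA matrix
#' @return a `trimesh` (chains with < 2 CA atoms are skipped with a warning)
#' @export
build_cartoon <- function(system, subdivisions_per_residue = 8L, colors = NULL) {
  stopifnot(subdivisions_per_residue >= 1L)
  if (is.null(colors)) colors <- assign_colors(system, "element")
  ss_tab <- assign_secondary_structure(system)
  atoms <- system$atoms
  xyz <- coords(system)
  ca <- which(toupper(atoms$name) == "CA")
  all_v <- list(); all_f <- list(); all_c <- list()
  base <- 0L
  m <- 12L
  for (ch in unique(atoms$chain_id[ca])) {
    idx <- ca[atoms$chain_id[ca] == ch]
    idx <- idx[order(atoms$residue_seq[idx])]
    n <- length(idx)
    if (n < 2L) {
      warning("chain ", ch, " has fewer than 2 CA atoms; skipped", call. = FALSE)
      next
    }
    p <- xyz[idx, , drop = FALSE]
    res_ss <- ss_tab$ss[match(paste(ch, atoms$residue_seq[idx]),
                              paste(ss_tab$chain_id, ss_tab$residue_seq))]
    res_ss[is.na(res_ss)] <- "coil"
    ctrl <- rbind(p[1, ], p, p[n, ])
    samples <- list(); samp_res <- integer(0)
    fr <- seq(0, 1, length.out = subdivisions_per_residue + 1L)[-(subdivisions_per_residue + 1L)]
    for (s in seq_len(n - 1L)) {
      pts <- .catmull_rom(ctrl[s, ], ctrl[s + 1, ], ctrl[s + 2, ], ctrl[s + 3, ], fr)
      samples[[s]] <- pts
      samp_res <- c(samp_res, rep.int(s, length(fr)))
    }
    pts <- rbind(do.call(rbind, samples), p[n, ])
    samp_res <- c(samp_res, n)
    frames <- .rmf_frames(pts)
    ns <- nrow(pts)

    # sheet arrowheads: widen over the last residue of each sheet run
    runs <- rle(res_ss)
    run_end <- cumsum(runs$lengths)
    arrow_res <- run_end[runs$values == "sheet"]
    rings <- vector("list", ns)
    ring_col <- matrix(0, ns, 4)
    for (s in seq_len(ns)) {
      ri <- samp_res[s]
      cls <- res_ss[ri]
      wid <- NULL
      if (cls == "sheet" && ri %in% arrow_res) {
        # fraction through this residue's segment
        f <- if (ri < n) (s - 1 - (ri - 1) * subdivisions_per_residue) /
               subdivisions_per_residue else 1
        wid <- 1.6 * (1 - f) + 0.2 * f   # taper from arrow base to tip
      }
      sec <- .cross_section(cls, m, wid)
      bin <- crossprod3(frames$t[s, ], frames$n[s, ])
      rings[[s]] <- matrix(pts[s, ], m, 3, byrow = TRUE) +
        outer(sec[, 1], frames$n[s, ]) + outer(sec[, 2], bin)
      ring_col[s, ] <- colors[idx[ri], ]
    }
    v <- do.call(rbind, rings)
    # stitch consecutive rings with quads (two triangles each)
    i0 <- rep((seq_len(ns - 1L) - 1L) * m, each = m) + seq_len(m)
    a <- i0
    b <- ifelse(a %% m == 0L, a - m + 1L, a + 1L)
    c2 <- a + m
    d2 <- b + m
    f1 <- cbind(a, c2, b)
    f2 <- cbind(b, c2, d2)
    # end caps: fan to ring centroid
    cap <- function(ring_start, flipcap) {
      ctr_id <- nrow(v) + 1L
      ids <- ring_start + seq_len(m) - 1L
      v <<- rbind(v, colMeans(v[ids, , drop = FALSE]))
      nxt <- c(ids[-1], ids[1])
      if (flipcap) cbind(ctr_id, nxt, ids) else cbind(ctr_id, ids, nxt)
    }
    capcol1 <- ring_col[1, ]; capcol2 <- ring_col[ns, ]
    fc1 <- cap(1L, TRUE)
    fc2 <- cap((ns - 1L) * m + 1L, FALSE)
    f <- rbind(f1, f2, fc1, fc2)
    cols <- rbind(ring_col[rep(seq_len(ns), each = m), , drop = FALSE],
                  capcol1, capcol2)
    all_v[[length(all_v) + 1L]] <- v
    all_f[[length(all_f) + 1L]] <- f + base
    all_c[[length(all_c) + 1L]] <- cols
    base <- base + nrow(v)
  }
  if (!length(all_v))
    return(trimesh(matrix(numeric(0), 0, 3), matrix(numeric(0), 0, 3),
                   matrix(integer(0), 0, 3)))
  v <- do.call(rbind, all_v)
  f <- do.call(rbind, all_f)
  mesh <- trimesh(v, NULL, f, colors = do.call(rbind, all_c))
  mesh$normals <- .vertex_normals(v, f)
  mesh
}

# Area-weighted averaged vertex normals; always unit length.
.vertex_normals <- function(v, f) {
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  nrm <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    acc <- rowsum(fn, group = f[, k])
    rows <- as.integer(rownames(acc))
    nrm[rows, ] <- nrm[rows, ] + acc
  }
  len <- sqrt(rowSums(nrm^2))
  len[len < 1e-12] <- 1
  nrm / len
}
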