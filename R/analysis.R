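# Measurement and structural-analysis tools: distance / angle / dihedral,
# Kabsch least-squares superposition, and combinatorial-extension (CE)
# structural alignment over aligned fragment pairs (AFPs).

#' Euclidean distance between two points (Angstrom)
#' @param p1,p2 3-vectors
#' @export
measure_distance <- function(p1, p2) {
  stopifnot(all(is.finite(p1)), all(is.finite(p2)))
  sqrt(sum((p1 - p2)^2))
}

#' Angle at p2 formed by p1-p2-p3, in degrees [0, 180]
#' @param p1,p2,p3 3-vectors
#' @export
measure_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12)
    stop("degenerate angle: coincident points", call. = FALSE)
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Signed dihedral angle p1-p2-p3-p4 in degrees (-180, 180]
#'
#' Angle between the planes (p1,p2,p3) and (p2,p3,p4); sign by the
#' right-hand rule about the p2 -> p3 axis.
#' @param p1,p2,p3,p4 3-vectors
#' @export
measure_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sum(b2^2) < 1e-18) stop("degenerate dihedral: b2 is zero", call. = FALSE)
  n1 <- crossprod3(b1, b2)
  n2 <- crossprod3(b2, b3)
  if (sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18)
    stop("degenerate dihedral: collinear points", call. = FALSE)
  m1 <- crossprod3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Kabsch superposition
#'
#' Least-squares rigid transform (rotation + translation, reflection
#' corrected so det(R) = +1) mapping the paired points P onto Q, with the
#' residual RMSD.
#'
#' @param P,Q n x 3 matrices of paired points (n >= 3)
#' @return list(rotation 3x3, translation 3-vector, rmsd)
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) < 3 || nrow(Q) != nrow(P))
    stop("kabsch requires >= 3 paired points", call. = FALSE)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  if (min(sv$d) < 1e-12 && sum(sv$d > 1e-12) < 2)
    stop("degenerate point set (rank-deficient)", call. = FALSE)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cq - c(R %*% cp)
  res <- sweep(P %*% t(R), 2, t_vec, "+") - Q
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(rowSums(res^2))))
}

# admissibility matrix: S[i, j] = mean |DA(i+k, i+l) - DB(j+k, j+l)| over
# the m(m-1)/2 intra-fragment pairs, computed from diagonal slices.
.afp_similarity <- function(DA, DB, m) {
  nA <- nrow(DA) - m + 1L
  nB <- nrow(DB) - m + 1L
  if (nA < 1L || nB < 1L) return(NULL)
  S <- matrix(0, nA, nB)
  np <- 0L
  for (k in 0:(m - 2L)) for (l in (k + 1L):(m - 1L)) {
    dA <- DA[cbind(seq_len(nA) + k, seq_len(nA) + l)]
    dB <- DB[cbind(seq_len(nB) + k, seq_len(nB) + l)]
    S <- S + abs(outer(dA, dB, "-"))
    np <- np + 1L
  }
  S / np
}

# cross-consistency of AFP (i2, j2) against path AFP (i1, j1)
.afp_cross <- function(DA, DB, i1, j1, i2, j2, m) {
  ka <- i1:(i1 + m - 1L); la <- i2:(i2 + m - 1L)
  kb <- j1:(j1 + m - 1L); lb <- j2:(j2 + m - 1L)
  mean(abs(DA[ka, la] - DB[kb, lb]))
}

#' CE structural alignment of two CA traces
#'
#' Combinatorial extension over aligned fragment pairs of length `m`: AFP
#' (i, j) is admissible when the average absolute difference of the
#' intra-fragment CA-CA distance matrices is at most `d0`; a path is
#' extended by an AFP whose cross-consistency against every fragment
#' already on the path is at most `d1`, with sequence gaps capped at
#' `max_gap` (same-diagonal overlapping extensions are allowed, which lets
#' identical structures align end to end). The path with the most aligned
#' residues wins; ties prefer smaller superposition RMSD, then the
#' lexicographically first start. Exhaustive depth-first search with
#' optimistic-bound pruning (a node budget caps pathological cases).
#'
#' @param A,B n x 3 CA coordinate matrices (or `molsys`, from which CA
#'   atoms are taken in chain/residue order)
#' @param m AFP fragment length
#' @param d0 AFP admissibility threshold (Angstrom)
#' @param d1 path cross-consistency threshold (Angstrom)
#' @param max_gap maximum sequence gap between consecutive AFPs
#' @param max_nodes DFS node budget
#' @return list(pairs, rotation, translation, rmsd, aligned_length)
#' @export
ce_align <- function(A, B, m = 8L, d0 = 3.0, d1 = 4.0, max_gap = 30L,
                     max_nodes = 2e5) {
  A <- .ca_coords(A); B <- .ca_coords(B)
  nA <- nrow(A); nB <- nrow(B)
  empty <- list(pairs = matrix(integer(0), 0, 2), rotation = diag(3),
                translation = c(0, 0, 0), rmsd = NA_real_, aligned_length = 0L)
  if (nA < m || nB < m) stop("both chains need at least m = ", m, " CA atoms",
                             call. = FALSE)
  DA <- as.matrix(stats::dist(A)); DB <- as.matrix(stats::dist(B))
  S <- .afp_similarity(DA, DB, m)
  adm <- which(S <= d0, arr.ind = TRUE)
  if (!nrow(adm)) return(structure(empty, class = "ce_alignment"))
  adm <- adm[order(adm[, 1], adm[, 2]), , drop = FALSE]

  pairs_of_path <- function(path) {
    ii <- unlist(lapply(path, function(p) p[1] + 0:(m - 1L)))
    jj <- unlist(lapply(path, function(p) p[2] + 0:(m - 1L)))
    u <- unique(cbind(ii, jj))
    u[order(u[, 1]), , drop = FALSE]
  }
  path_rmsd <- function(path) {
    pr <- pairs_of_path(path)
    kabsch_superpose(A[pr[, 1], , drop = FALSE], B[pr[, 2], , drop = FALSE])$rmsd
  }
  aligned_len <- function(path) nrow(pairs_of_path(path))

  best <- list(len = 0L, rmsd = Inf, path = NULL)
  nodes_seen <- 0L

  admissible_step <- function(last, cand) {
    di <- cand[1] - last[1]; dj <- cand[2] - last[2]
    if (di < 1L || dj < 1L) return(FALSE)
    if (di == dj) return(di < m || (di - m) <= max_gap)  # same diagonal: overlap OK
    di >= m && dj >= m && (di - m) <= max_gap && (dj - m) <= max_gap
  }

  consider <- function(path) {
    len <- aligned_len(path)
    if (len > best$len) {
      best <<- list(len = len, rmsd = path_rmsd(path), path = path)
    } else if (len == best$len) {
      r <- path_rmsd(path)
      if (r < best$rmsd - 1e-12) best <<- list(len = len, rmsd = r, path = path)
    }
  }

  dfs <- function(path, iend, jend) {
    nodes_seen <<- nodes_seen + 1L
    if (nodes_seen > max_nodes) return()
    last <- path[[length(path)]]
    extended <- FALSE
    cur_len <- aligned_len(path)
    for (q in seq_len(nrow(adm))) {
      cand <- adm[q, ]
      if (cand[1] <= last[1]) next
      if (!admissible_step(last, cand)) next
      # optimistic bound: everything after cand could align
      new_iend <- max(iend, cand[1] + m - 1L)
      new_jend <- max(jend, cand[2] + m - 1L)
      gain <- nrow(unique(rbind(pairs_of_path(path),
                                cbind(cand[1] + 0:(m - 1L), cand[2] + 0:(m - 1L)))))
      bound <- gain + min(nA - new_iend, nB - new_jend)
      if (bound < best$len) next
      if (bound == best$len && best$rmsd <= 1e-9) next
      ok <- TRUE
      for (p in path)
        if (.afp_cross(DA, DB, p[1], p[2], cand[1], cand[2], m) > d1) {
          ok <- FALSE; break
        }
      if (!ok) next
      extended <- TRUE
      dfs(c(path, list(cand)), new_iend, new_jend)
      if (nodes_seen > max_nodes) return()
    }
    if (!extended) consider(path)
  }

  for (q in seq_len(nrow(adm))) {
    root <- adm[q, ]
    bound <- m + min(nA - (root[1] + m - 1L), nB - (root[2] + m - 1L))
    if (bound < best$len) next
    if (bound == best$len && best$rmsd <= 1e-9) next
    dfs(list(root), root[1] + m - 1L, root[2] + m - 1L)
    if (nodes_seen > max_nodes) break
  }

  if (is.null(best$path)) return(structure(empty, class = "ce_alignment"))
  pr <- pairs_of_path(best$path)
  kb <- kabsch_superpose(A[pr[, 1], , drop = FALSE], B[pr[, 2], , drop = FALSE])
  structure(list(pairs = unname(pr), rotation = kb$rotation,
                 translation = kb$translation, rmsd = kb$rmsd,
                 aligned_length = nrow(pr)), class = "ce_alignment")
}

#' @export
print.ce_alignment <- function(x, ...) {
  cat(sprintf("<ce_alignment> aligned_length %d, rmsd %.3f A\n",
              x$aligned_length, x$rmsd))
  invisible(x)
}

.ca_coords <- function(x) {
  if (is.matrix(x)) return(unname(as.matrix(x)))
  if (inherits(x, "molsys")) {
    atoms <- x$atoms
    ca <- which(toupper(atoms$name) == "CA")
    ord <- ca[order(match(atoms$chain_id[ca], unique(atoms$chain_id)),
                    atoms$residue_seq[ca])]
    return(unname(coords(x)[ord, , drop = FALSE]))
  }
  stop("expected an n x 3 matrix or a molsys", call. = FALSE)
}
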