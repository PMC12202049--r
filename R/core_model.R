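# In-memory molecular model: atom table + bond list + coordinate frames.
#
# Atoms are stored as a data.frame (one row per atom, 1-based indices);
# coordinates live in a list of n_atoms x 3 matrices (Angstrom), one per
# trajectory frame, with a single active frame that all downstream geometry
# reads. Secondary-structure records from files (HELIX/SHEET) are kept as
# metadata and take precedence over the geometric assignment.

#' Construct a molecular system
#'
#' @param atoms data.frame with columns `name`, `element`, `chain_id`,
#'   `residue_name`, `residue_seq`, and optionally `occupancy`, `bfactor`,
#'   `altloc`, `vdw_radius`, `covalent_radius`.
#' @param coords numeric n x 3 matrix of positions (Angstrom) for frame 1,
#'   or a list of such matrices (one per frame).
#' @param bonds integer 2-column matrix of 1-based atom indices (i < j), or
#'   NULL for no connectivity.
#' @param ss_records optional data.frame of file secondary-structure records
#'   with columns `kind` ("helix"/"sheet"), `chain_id`, `res_start`, `res_end`.
#' @return An object of class `molsys`.
#' @export
molecule_system <- function(atoms, coords, bonds = NULL, ss_records = NULL) {
  stopifnot(is.data.frame(atoms))
  n <- nrow(atoms)
  if (is.matrix(coords)) coords <- list(coords)
  stopifnot(is.list(coords), length(coords) >= 1L)
  for (k in seq_along(coords)) {
    fr <- coords[[k]]
    if (!is.matrix(fr) || ncol(fr) != 3L || nrow(fr) != n)
      stop("frame ", k, " is not an n_atoms x 3 matrix")
    if (!all(is.finite(fr))) stop("frame ", k, " contains non-finite coordinates")
    storage.mode(coords[[k]]) <- "double"
  }
  defaults <- list(occupancy = 1, bfactor = 0, altloc = "",
                   vdw_radius = NA_real_, covalent_radius = NA_real_)
  for (col in names(defaults))
    if (is.null(atoms[[col]])) atoms[[col]] <- rep(defaults[[col]], length.out = n)
  atoms$element <- .normalize_element(as.character(atoms$element))
  bonds <- .canonical_bonds(bonds, n)
  structure(list(atoms = atoms, frames = coords, active_frame = 1L,
                 bonds = bonds, ss_records = ss_records),
            class = "molsys")
}

.canonical_bonds <- function(bonds, n_atoms) {
  if (is.null(bonds) || NROW(bonds) == 0L)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (any(bonds < 1L | bonds > n_atoms)) stop("bond index out of range")
  if (any(bonds[, 1] == bonds[, 2])) stop("self-bond not allowed")
  ij <- cbind(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  ij <- unique(ij)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  dimnames(ij) <- list(NULL, c("i", "j"))
  ij
}

#' @export
print.molsys <- function(x, ...) {
  cat(sprintf("<molsys> %d atoms, %d bonds, %d frame(s) [active %d], %d chain(s)\n",
              n_atoms(x), nrow(x$bonds), length(x$frames), x$active_frame,
              length(unique(x$atoms$chain_id))))
  invisible(x)
}

#' Number of atoms in a system
#' @param system a `molsys`
#' @export
n_atoms <- function(system) nrow(system$atoms)

#' Coordinates of the active frame
#' @param system a `molsys`
#' @return n x 3 matrix (Angstrom)
#' @export
coords <- function(system) system$frames[[system$active_frame]]

#' Select the active trajectory frame
#'
#' All downstream geometry (representations, surfaces, rendering) reads the
#' active frame.
#'
#' @param system a `molsys`
#' @param k 1-based frame index
#' @export
set_active_frame <- function(system, k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > length(system$frames))
    stop("frame index ", k, " out of range [1, ", length(system$frames), "]")
  system$active_frame <- k
  system
}

#' Assign van der Waals and covalent radii
#'
#' Looks each atom's element up in the shipped Bondi-style vdW table and
#' Cordero-style covalent table. Unknown elements receive the documented
#' fallbacks (1.50 A vdW, 0.76 A covalent) and trigger one warning per
#' distinct unknown element. Idempotent.
#'
#' @param system a `molsys`
#' @param vdw_table,covalent_table named numeric vectors overriding the
#'   shipped tables (element symbol -> Angstrom).
#' @export
assign_radii <- function(system, vdw_table = .VDW_RADII,
                         covalent_table = .COVALENT_RADII) {
  el <- system$atoms$element
  unknown <- setdiff(unique(el), names(vdw_table))
  for (u in unknown)
    warning("unknown element '", u, "': using fallback radii", call. = FALSE)
  vr <- unname(vdw_table[el])
  vr[is.na(vr)] <- .VDW_FALLBACK
  cr <- unname(covalent_table[el])
  cr[is.na(cr)] <- .COV_FALLBACK
  system$atoms$vdw_radius <- vr
  system$atoms$covalent_radius <- cr
  system
}

#' Perceive covalent bonds from interatomic distances
#'
#' Bond (i, j) is created iff `min_dist < |p_i - p_j| < cov_i + cov_j + tol`
#' using active-frame coordinates. A uniform spatial grid keeps the cost
#' near-linear in the number of atoms. Output is deterministic: i < j,
#' ordered lexicographically.
#'
#' @param system a `molsys` with radii assigned
#' @param tol distance tolerance added to the covalent radii sum (Angstrom)
#' @param min_dist clash cutoff below which no bond is created (Angstrom)
#' @return integer 2-column matrix of bonds
#' @export
perceive_bonds <- function(system, tol = 0.4, min_dist = 0.4) {
  if (any(is.na(system$atoms$covalent_radius)))
    stop("radii not assigned; call assign_radii() first")
  xyz <- coords(system)
  n <- nrow(xyz)
  if (n < 2L)
    return(.canonical_bonds(NULL, n))
  cov <- system$atoms$covalent_radius
  cell <- max(2 * max(cov) + tol, 1e-6)
  key <- function(p) {
    ix <- floor(p[, 1] / cell); iy <- floor(p[, 2] / cell); iz <- floor(p[, 3] / cell)
    paste(ix, iy, iz)
  }
  cells <- key(xyz)
  lookup <- split(seq_len(n), cells)
  ci <- floor(xyz / cell)
  pairs_i <- integer(0); pairs_j <- integer(0)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (a in seq_len(n)) {
    neigh <- integer(0)
    for (r in seq_len(nrow(offsets))) {
      k <- paste(ci[a, 1] + offsets[r, 1], ci[a, 2] + offsets[r, 2],
                 ci[a, 3] + offsets[r, 3])
      hit <- lookup[[k]]
      if (!is.null(hit)) neigh <- c(neigh, hit)
    }
    neigh <- neigh[neigh > a]
    if (!length(neigh)) next
    d <- sqrt(rowSums((xyz[neigh, , drop = FALSE] -
                         matrix(xyz[a, ], length(neigh), 3, byrow = TRUE))^2))
    cut <- cov[a] + cov[neigh] + tol
    keep <- d > min_dist & d < cut
    if (any(keep)) {
      pairs_i <- c(pairs_i, rep.int(a, sum(keep)))
      pairs_j <- c(pairs_j, neigh[keep])
    }
  }
  .canonical_bonds(cbind(pairs_i, pairs_j), n)
}

# ---- Selection expressions --------------------------------------------------
#
# Grammar (case-insensitive keywords):
#   expr    := or
#   or      := and ( "or" and )*
#   and     := unary ( "and" unary )*
#   unary   := "not" unary | "(" expr ")" | primary
#   primary := "all" | "none"
#            | "chain"   id ("," id)*
#            | "element" sym ("," sym)*
#            | "residue" range ("," range)*      range := int | int ":" int
#            | "name"    id ("," id)*
# Malformed input raises a parse error reporting the character position.

.sel_tokenize <- function(expr) {
  pat <- "\\s*([A-Za-z_][A-Za-z0-9_']*|-?[0-9]+|[(),:])"
  toks <- list(); pos <- 1L; nch <- nchar(expr)
  while (pos <= nch) {
    rest <- substr(expr, pos, nch)
    if (grepl("^\\s*$", rest)) break
    m <- regexpr(pat, rest)
    if (m != 1L)
      stop(sprintf("selection parse error at position %d: unexpected '%s'",
                   pos, substr(rest, 1, 8)), call. = FALSE)
    tok <- gsub("^\\s+", "", regmatches(rest, m))
    skip <- attr(m, "match.length")
    toks[[length(toks) + 1L]] <- list(text = tok, pos = pos + (skip - nchar(tok)))
    pos <- pos + skip
  }
  toks
}

.sel_parse <- function(tokens, system) {
  i <- 1L
  n_tok <- length(tokens)
  peek <- function() if (i <= n_tok) tolower(tokens[[i]]$text) else ""
  take <- function() {
    if (i > n_tok) fail("unexpected end of input", NA_integer_)
    t <- tokens[[i]]
    i <<- i + 1L
    t
  }
  fail <- function(msg, at = if (i <= n_tok) tokens[[i]]$pos else NA_integer_) {
    where <- if (is.na(at)) "end of input" else paste0("position ", at)
    stop("selection parse error at ", where, ": ", msg, call. = FALSE)
  }
  atoms <- system$atoms
  n <- nrow(atoms)

  parse_list <- function() {
    items <- character(0)
    repeat {
      if (i > n_tok) fail("expected a value")
      items <- c(items, take()$text)
      if (peek() == ",") take() else break
    }
    items
  }
  parse_primary <- function() {
    if (i > n_tok) fail("expected an expression")
    kw <- peek()
    if (kw == "(") {
      take()
      v <- parse_or()
      if (peek() != ")") fail("expected ')'")
      take()
      return(v)
    }
    take()
    switch(kw,
      all  = rep(TRUE, n),
      none = rep(FALSE, n),
      chain = atoms$chain_id %in% parse_list(),
      element = {
        toupper(atoms$element) %in% toupper(parse_list())
      },
      name = toupper(atoms$name) %in% toupper(parse_list()),
      residue = {
        mask <- rep(FALSE, n)
        repeat {
          if (i > n_tok) fail("expected a residue number")
          tk <- take()
          a <- suppressWarnings(as.integer(tk$text))
          if (is.na(a)) fail("expected a residue number", tk$pos)
          b <- a
          if (peek() == ":") {
            take()
            tk2 <- take()
            b <- suppressWarnings(as.integer(tk2$text))
            if (is.na(b)) fail("expected a residue number", tk2$pos)
          }
          mask <- mask | (atoms$residue_seq >= min(a, b) &
                            atoms$residue_seq <= max(a, b))
          if (peek() == ",") take() else break
        }
        mask
      },
      fail(paste0("unknown keyword '", kw, "'"),
           tokens[[i - 1L]]$pos)
    )
  }
  parse_unary <- function() {
    if (peek() == "not") { take(); return(!parse_unary()) }
    parse_primary()
  }
  parse_and <- function() {
    v <- parse_unary()
    while (peek() == "and") { take(); v <- v & parse_unary() }
    v
  }
  parse_or <- function() {
    v <- parse_and()
    while (peek() == "or") { take(); v <- v | parse_and() }
    v
  }
  v <- parse_or()
  if (i <= n_tok) fail(paste0("unexpected trailing '", tokens[[i]]$text, "'"))
  v
}

#' Select atoms with a textual expression
#'
#' Supports `chain`, `element`, `residue` (single numbers and `a:b` ranges),
#' `name`, `all`, `none`, combined with `and` / `or` / `not` and parentheses.
#'
#' @param system a `molsys`
#' @param expr selection expression, e.g. `"chain A and not element H"`
#' @return sorted integer vector of 1-based atom indices (class `molsel`)
#' @export
select_atoms <- function(system, expr) {
  stopifnot(is.character(expr), length(expr) == 1L)
  tokens <- .sel_tokenize(expr)
  if (!length(tokens)) stop("selection parse error: empty expression", call. = FALSE)
  mask <- .sel_parse(tokens, system)
  structure(which(mask), class = "molsel")
}
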