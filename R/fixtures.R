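# Deterministic synthetic-structure generators.
#
# These emulate the geometric regimes the pipeline must handle -- ideal
# alpha-helical CA traces, extended chains, random sphere clusters, and toy
# PDB texts -- so every stage is testable without downloading real entries.
# All generators are pure functions of their arguments (and seed).

.ca_system <- function(xyz, chain_id = "A", element = "C", name = "CA",
                       residue_name = "ALA") {
  n <- nrow(xyz)
  atoms <- data.frame(
    name = rep(name, n), element = rep(element, n),
    chain_id = rep(chain_id, n), residue_name = rep(residue_name, n),
    residue_seq = seq_len(n), stringsAsFactors = FALSE)
  assign_radii(molecule_system(atoms, xyz))
}

#' Ideal helical CA-only chain
#'
#' CA_k = (radius cos(k t), radius sin(k t), k rise) for k = 0..n-1, with
#' twist t in degrees. Defaults approximate an ideal alpha helix
#' (rise 1.5 A, twist 100 degrees, radius 2.3 A).
#'
#' @param n number of residues (>= 1)
#' @param rise axial rise per residue (Angstrom)
#' @param twist rotation per residue (degrees)
#' @param radius helix radius (Angstrom)
#' @export
make_ideal_helix <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  stopifnot(n >= 1)
  k <- seq_len(n) - 1
  t <- k * twist * pi / 180
  .ca_system(cbind(radius * cos(t), radius * sin(t), k * rise))
}

#' Extended (collinear) CA-only chain along x
#' @param n number of residues
#' @param spacing CA-CA spacing (Angstrom); 3.8 is the trans peptide value
#' @export
make_extended_chain <- function(n, spacing = 3.8) {
  stopifnot(n >= 1)
  .ca_system(cbind((seq_len(n) - 1) * spacing, 0, 0))
}

#' Random cluster of carbon atoms with a minimum separation
#'
#' Rejection sampling in a cubic box with a fixed seed; errors out if `n`
#' points cannot be placed within `max_tries` draws.
#'
#' @param n atom count
#' @param box cube edge length (Angstrom)
#' @param min_sep minimum pairwise separation (Angstrom)
#' @param seed RNG seed (integer)
#' @param max_tries rejection-sampling budget
#' @export
make_sphere_cluster <- function(n, box = 30, min_sep = 3, seed = 1,
                                max_tries = 200 * n) {
  stopifnot(n >= 1, box > 0, min_sep >= 0)
  rng <- .local_rng(seed)
  pts <- matrix(NA_real_, n, 3)
  placed <- 0L
  for (try in seq_len(max_tries)) {
    cand <- rng$unif(3) * box
    ok <- placed == 0L ||
      all(rowSums((pts[seq_len(placed), , drop = FALSE] -
                     matrix(cand, placed, 3, byrow = TRUE))^2) >= min_sep^2)
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- cand
      if (placed == n) break
    }
  }
  if (placed < n)
    stop("could not place ", n, " atoms with min_sep ", min_sep,
         " in a box of ", box, " A after ", max_tries, " tries")
  .ca_system(pts, name = "C", residue_name = "UNK")
}

#' Toy PDB texts for parser tests
#'
#' @param kind one of `"minimal"` (3 atoms), `"multimodel"` (2 models x 3
#'   atoms), `"conect"` (2 atoms + CONECT), `"helix_record"` (12 CA with a
#'   HELIX record covering residues 2-10), `"malformed"` (bad coordinate
#'   field on line 2).
#' @return PDB-format text (single string)
#' @export
make_toy_pdb_text <- function(kind = c("minimal", "multimodel", "conect",
                                       "helix_record", "malformed")) {
  kind <- match.arg(kind)
  atom_line <- function(serial, name, res, chain, seq, x, y, z, el) {
    sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, paste0(" ", name), res, chain, seq, x, y, z, 1, 0, el)
  }
  three <- c(atom_line(1, "N", "MET", "A", 1, 11.104, 6.134, -6.504, "N"),
             atom_line(2, "CA", "MET", "A", 1, 12.0, 6.9, -5.9, "C"),
             atom_line(3, "C", "MET", "A", 1, 13.1, 6.0, -5.3, "C"))
  txt <- switch(kind,
    minimal = c(three, "END"),
    multimodel = c("MODEL     1", three, "ENDMDL",
                   "MODEL     2",
                   c(atom_line(1, "N", "MET", "A", 1, 12.104, 6.134, -6.504, "N"),
                     atom_line(2, "CA", "MET", "A", 1, 13.0, 6.9, -5.9, "C"),
                     atom_line(3, "C", "MET", "A", 1, 14.1, 6.0, -5.3, "C")),
                   "ENDMDL", "END"),
    conect = c(atom_line(1, "C1", "LIG", "A", 1, 0, 0, 0, "C"),
               atom_line(2, "C2", "LIG", "A", 1, 1.54, 0, 0, "C"),
               "CONECT    1    2", "END"),
    helix_record = {
      helix <- make_ideal_helix(12)
      xyz <- coords(helix)
      c("HELIX    1   1 ALA A    2  ALA A   10  1                                   9",
        vapply(seq_len(12), function(i)
          atom_line(i, "CA", "ALA", "A", i, xyz[i, 1], xyz[i, 2], xyz[i, 3], "C"),
          character(1)),
        "END")
    },
    malformed = c(three[1],
                  sub("12\\.000", "twelve", sprintf(
                    "ATOM      2  CA  MET A   1      %8s   6.900  -5.900  1.00  0.00           C",
                    "12.000")),
                  "END"))
  paste0(paste(txt, collapse = "\n"), "\n")
}

# Small deterministic RNG (xorshift-ish LCG), independent of R's global
# .Random.seed so fixtures never perturb user RNG state.
.local_rng <- function(seed) {
  state <- as.double((as.integer(seed) %% 2147483646L) + 1L)
  nxt <- function() {
    # Park-Miller minimal standard
    state <<- (16807 * state) %% 2147483647
    state / 2147483647
  }
  list(unif = function(k) vapply(seq_len(k), function(i) nxt(), numeric(1)))
}
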