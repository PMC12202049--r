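# Minimal streaming mmCIF reader: a single pass over the lines of the file
# extracting the atom_site loop. Quoted values ('...', "...") follow CIF
# rules (closing quote must be followed by whitespace); '.' and '?' map to
# missing. Memory use beyond the coordinate/atom table is bounded by one
# line of text.

.cif_tokenize_line <- function(line) {
  if (!grepl("['\"]", line))
    return(strsplit(trimws(line), "[ \t]+")[[1]])
  out <- character(0)
  i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch == "'" || ch == "\"") {
      j <- i + 1L
      repeat {
        j2 <- regexpr(ch, substr(line, j, n), fixed = TRUE)
        if (j2 < 0) stop("unterminated quoted CIF value", call. = FALSE)
        j <- j + j2 - 1L
        nxt <- substr(line, j + 1L, j + 1L)
        if (nxt == "" || nxt %in% c(" ", "\t")) break
        j <- j + 1L
      }
      out <- c(out, substr(line, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      m <- regexpr("[ \t]", substr(line, i, n))
      j <- if (m < 0) n + 1L else i + m - 1L
      out <- c(out, substr(line, i, j - 1L))
      i <- j
    }
  }
  out
}

#' Read an mmCIF structure (atom_site loop)
#'
#' Parses the `_atom_site` loop in one streaming pass. Rows are split into
#' trajectory frames by `pdbx_PDB_model_num` when present.
#'
#' @param text mmCIF text (string or lines) or a file path
#' @return a [molecule_system()] with radii assigned
#' @export
read_mmcif <- function(text) {
  lines <- .as_lines(text)
  n_lines <- length(lines)
  i <- 1L
  tags <- character(0)
  data_start <- NA_integer_
  while (i <= n_lines) {
    l <- trimws(lines[i])
    if (l == "loop_") {
      j <- i + 1L
      t2 <- character(0)
      while (j <= n_lines && startsWith(trimws(lines[j]), "_")) {
        t2 <- c(t2, trimws(lines[j])); j <- j + 1L
      }
      if (length(t2) && all(startsWith(t2, "_atom_site."))) {
        tags <- sub("^_atom_site\\.", "", t2)
        data_start <- j
        break
      }
      i <- j
    } else i <- i + 1L
  }
  if (!length(tags)) stop("no _atom_site loop found in mmCIF input", call. = FALSE)

  need <- c("Cartn_x", "Cartn_y", "Cartn_z", "type_symbol")
  missing_col <- setdiff(need, tags)
  if (length(missing_col))
    stop("mmCIF atom_site loop lacks mandatory column: ",
         missing_col[1], call. = FALSE)

  ntag <- length(tags)
  rows <- vector("list", 2048L)
  nrow_used <- 0L
  buf <- character(0)
  i <- data_start
  while (i <= n_lines) {
    l <- lines[i]
    lt <- trimws(l)
    if (lt == "" || startsWith(lt, "#")) { i <- i + 1L; next }
    if (startsWith(lt, "_") || startsWith(lt, "loop_") ||
        startsWith(lt, "data_") || lt == "stop_") break
    buf <- c(buf, .cif_tokenize_line(l))
    while (length(buf) >= ntag) {
      nrow_used <- nrow_used + 1L
      if (nrow_used > length(rows)) rows <- c(rows, vector("list", length(rows)))
      rows[[nrow_used]] <- buf[seq_len(ntag)]
      buf <- buf[-seq_len(ntag)]
    }
    i <- i + 1L
  }
  if (length(buf)) stop("mmCIF atom_site loop has a trailing partial row", call. = FALSE)
  if (!nrow_used) stop("mmCIF atom_site loop contains no rows", call. = FALSE)

  tab <- do.call(rbind, rows[seq_len(nrow_used)])
  colnames(tab) <- tags
  get <- function(col, default = NA_character_) {
    if (col %in% tags) {
      v <- tab[, col]
      v[v %in% c(".", "?")] <- NA_character_
      v
    } else rep(default, nrow(tab))
  }
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(get(col)))
    if (anyNA(v) && col %in% need)
      stop("non-numeric value in mmCIF column ", what, call. = FALSE)
    v
  }

  x <- num("Cartn_x", "Cartn_x"); y <- num("Cartn_y", "Cartn_y")
  z <- num("Cartn_z", "Cartn_z")
  model <- get("pdbx_PDB_model_num")
  model[is.na(model)] <- "1"
  altloc <- get("label_alt_id")
  altloc[is.na(altloc)] <- ""
  keep <- altloc %in% c("", "A")

  chain <- get("label_asym_id")
  if (all(is.na(chain))) chain <- get("auth_asym_id")
  chain[is.na(chain)] <- "A"
  seqid <- suppressWarnings(as.integer(get("label_seq_id")))
  if (all(is.na(seqid))) seqid <- suppressWarnings(as.integer(get("auth_seq_id")))
  seqid[is.na(seqid)] <- 0L
  name <- get("label_atom_id"); name[is.na(name)] <- ""
  resn <- get("label_comp_id"); resn[is.na(resn)] <- ""
  occ <- suppressWarnings(as.numeric(get("occupancy"))); occ[is.na(occ)] <- 1
  bf <- suppressWarnings(as.numeric(get("B_iso_or_equiv"))); bf[is.na(bf)] <- 0

  models <- unique(model[keep])
  first <- keep & model == models[1]
  atoms <- data.frame(
    name = name[first], element = .normalize_element(get("type_symbol")[first]),
    chain_id = chain[first], residue_name = resn[first],
    residue_seq = seqid[first], occupancy = occ[first], bfactor = bf[first],
    altloc = altloc[first], stringsAsFactors = FALSE)
  frames <- list(cbind(x[first], y[first], z[first]))
  for (mm in models[-1]) {
    sel <- keep & model == mm
    if (sum(sel) != nrow(atoms))
      stop("model ", mm, " has ", sum(sel), " atoms, expected ", nrow(atoms),
           call. = FALSE)
    frames[[length(frames) + 1L]] <- cbind(x[sel], y[sel], z[sel])
  }
  assign_radii(molecule_system(atoms, frames))
}
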