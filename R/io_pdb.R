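# Fixed-column PDB reader. MODEL/ENDMDL blocks become trajectory frames,
# CONECT records become bonds, HELIX/SHEET records are kept as metadata.
# Alternate locations other than ' '/'A' are dropped (single-conformer view).

.pdb_field <- function(lines, from, to) trimws(substring(lines, from, to))

.pdb_num <- function(txt, linenos, what) {
  v <- suppressWarnings(as.numeric(txt))
  bad <- which(is.na(v) & trimws(txt) != "")
  if (length(bad))
    stop("malformed ", what, " field on line ", linenos[bad[1]],
         ": '", txt[bad[1]], "'", call. = FALSE)
  v
}

.infer_element <- function(name_field) {
  # name_field is the raw 4-char atom-name column block (cols 13-16)
  letters_only <- gsub("[^A-Za-z]", "", name_field)
  first2 <- toupper(substr(letters_only, 1, 2))
  # two-letter symbols are only trusted when the name starts in column 13
  starts_col13 <- substr(name_field, 1, 1) != " "
  two <- starts_col13 & first2 %in% .TWO_LETTER_ELEMENTS
  out <- substr(letters_only, 1, 1)
  out[two] <- first2[two]
  .normalize_element(out)
}

#' Read a PDB-format structure
#'
#' @param text PDB text (single string or character vector of lines), or a
#'   file path to read.
#' @return a [molecule_system()] with radii assigned; models become frames.
#' @export
read_pdb <- function(text) {
  lines <- .as_lines(text)
  rec <- substring(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("no ATOM/HETATM records: empty structure", call. = FALSE)

  model_starts <- which(rec == "MODEL ")
  n_models <- max(1L, length(model_starts))
  model_of <- if (length(model_starts)) {
    findInterval(seq_along(lines), model_starts)
  } else rep(1L, length(lines))
  model_of[model_of == 0L] <- 1L

  ai <- which(is_atom)
  al <- lines[ai]
  altloc <- substring(al, 17, 17)
  keep <- altloc %in% c(" ", "A", "")
  ai <- ai[keep]; al <- al[keep]; altloc <- altloc[keep]

  m <- model_of[ai]
  first_model <- m == min(m)
  a1 <- al[first_model]
  ln1 <- ai[first_model]

  parse_xyz <- function(ll, lns) {
    cbind(.pdb_num(substring(ll, 31, 38), lns, "x"),
          .pdb_num(substring(ll, 39, 46), lns, "y"),
          .pdb_num(substring(ll, 47, 54), lns, "z"))
  }
  name_raw <- substring(a1, 13, 16)
  element <- .pdb_field(a1, 77, 78)
  noel <- element == ""
  element[noel] <- .infer_element(name_raw[noel])

  atoms <- data.frame(
    name = trimws(name_raw),
    element = element,
    chain_id = substring(a1, 22, 22),
    residue_name = .pdb_field(a1, 18, 20),
    residue_seq = {
      rs <- suppressWarnings(as.integer(.pdb_field(a1, 23, 26)))
      rs[is.na(rs)] <- 0L
      rs
    },
    occupancy = { o <- .pdb_num(substring(a1, 55, 60), ln1, "occupancy"); o[is.na(o)] <- 1; o },
    bfactor = { b <- .pdb_num(substring(a1, 61, 66), ln1, "bfactor"); b[is.na(b)] <- 0; b },
    altloc = altloc[first_model],
    stringsAsFactors = FALSE)

  frames <- list(parse_xyz(a1, ln1))
  if (n_models > 1L) {
    for (mm in sort(unique(m))[-1]) {
      sel <- m == mm
      if (sum(sel) != nrow(atoms))
        stop("MODEL block ", mm, " has ", sum(sel), " atoms, expected ",
             nrow(atoms), call. = FALSE)
      frames[[length(frames) + 1L]] <- parse_xyz(al[sel], ai[sel])
    }
  }

  # CONECT -> bonds (serial numbers of first model)
  serial <- suppressWarnings(as.integer(.pdb_field(a1, 7, 11)))
  bonds <- NULL
  con <- lines[rec == "CONECT"]
  if (length(con)) {
    idx_of <- match(seq_len(max(serial, na.rm = TRUE)), serial)
    pairs <- list()
    for (cl in con) {
      f <- suppressWarnings(as.integer(c(substring(cl, 7, 11), substring(cl, 12, 16),
                                         substring(cl, 17, 21), substring(cl, 22, 26),
                                         substring(cl, 27, 31))))
      f <- f[!is.na(f)]
      if (length(f) >= 2)
        for (p in f[-1]) pairs[[length(pairs) + 1L]] <- c(f[1], p)
    }
    if (length(pairs)) {
      pm <- do.call(rbind, pairs)
      pm <- cbind(idx_of[pm[, 1]], idx_of[pm[, 2]])
      pm <- pm[stats::complete.cases(pm), , drop = FALSE]
      if (nrow(pm)) bonds <- pm
    }
  }

  # HELIX/SHEET metadata
  ss <- NULL
  hel <- lines[rec == "HELIX "]
  sht <- lines[rec == "SHEET "]
  recs <- list()
  for (h in hel)
    recs[[length(recs) + 1L]] <- data.frame(
      kind = "helix", chain_id = substring(h, 20, 20),
      res_start = as.integer(trimws(substring(h, 22, 25))),
      res_end = as.integer(trimws(substring(h, 34, 37))),
      stringsAsFactors = FALSE)
  for (s in sht)
    recs[[length(recs) + 1L]] <- data.frame(
      kind = "sheet", chain_id = substring(s, 22, 22),
      res_start = as.integer(trimws(substring(s, 23, 26))),
      res_end = as.integer(trimws(substring(s, 34, 37))),
      stringsAsFactors = FALSE)
  if (length(recs)) ss <- do.call(rbind, recs)

  assign_radii(molecule_system(atoms, frames, bonds = bonds, ss_records = ss))
}

.as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    return(readLines(text, warn = FALSE))
  if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
}
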