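# Direct download of entries from the Protein Data Bank, cached locally so
# that repeat runs stay offline. mmCIF is used as the transfer format (the
# entry coordinate endpoint), which scales to very large structures.

#' Fetch a PDB entry as mmCIF text
#'
#' Downloads `https://files.rcsb.org/download/<ID>.cif` on first use and
#' caches it; later calls read the cache and need no network.
#'
#' @param accession 4-character PDB accession (e.g. `"3JC8"`)
#' @param cache_dir cache directory; defaults to the `MOLRAY_CACHE`
#'   environment variable, else the user cache directory.
#' @return character vector of mmCIF lines (parse with [read_mmcif()])
#' @export
fetch_pdb <- function(accession,
                      cache_dir = Sys.getenv("MOLRAY_CACHE",
                                             tools::R_user_dir("molray", "cache"))) {
  if (!grepl("^[A-Za-z0-9]{4}$", accession))
    stop("not a valid 4-character PDB accession: '", accession, "'", call. = FALSE)
  accession <- toupper(accession)
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  dest <- file.path(cache_dir, paste0(accession, ".cif"))
  if (!file.exists(dest)) {
    url <- sprintf("https://files.rcsb.org/download/%s.cif", accession)
    tmp <- paste0(dest, ".part")
    old_to <- options(timeout = getOption("molray.fetch_timeout", 300))
    on.exit(options(old_to), add = TRUE)
    status <- tryCatch(
      utils::download.file(url, tmp, mode = "wb", quiet = TRUE),
      error = function(e) {
        msg <- conditionMessage(e)
        if (grepl("404", msg))
          stop("PDB entry not found: ", accession, call. = FALSE)
        stop("network failure fetching ", accession, " (retry later): ", msg,
             call. = FALSE)
      })
    if (!identical(status, 0L) || !file.exists(tmp))
      stop("network failure fetching ", accession, " (retry later)", call. = FALSE)
    file.rename(tmp, dest)
  }
  readLines(dest, warn = FALSE)
}
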