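# Headless session state: structure sources, representation specs, camera
# pose, render settings and measurements, serialized as versioned JSON.

.SESSION_SCHEMA <- "1"

#' Create a session
#'
#' @param structures list of structure specs, each a list with `source`
#'   (path or accession), `rep`, `color`
#' @param camera_state list describing the camera pose (see [camera()])
#' @param settings list of render settings (see [render_settings()])
#' @param measurements list of measurement specs
#' @export
new_session <- function(structures = list(), camera_state = list(),
                        settings = list(), measurements = list()) {
  structure(list(schema = .SESSION_SCHEMA, structures = structures,
                 camera = camera_state, settings = settings,
                 measurements = measurements), class = "molsession")
}

#' Save a session to JSON
#' @param session a `molsession`
#' @param path output path
#' @export
save_session <- function(session, path) {
  stopifnot(inherits(session, "molsession"))
  jsonlite::write_json(unclass(session), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a session from JSON
#'
#' Unknown schema versions are an error; unknown top-level keys warn and
#' are dropped, so `load_session(save_session(s)) == s` field for field.
#'
#' @param path JSON session path
#' @export
load_session <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$schema) || !identical(as.character(raw$schema), .SESSION_SCHEMA))
    stop("unsupported session schema version: ",
         if (is.null(raw$schema)) "<missing>" else raw$schema, call. = FALSE)
  known <- c("schema", "structures", "camera", "settings", "measurements")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    warning("ignoring unknown session keys: ", paste(extra, collapse = ", "),
            call. = FALSE)
  new_session(structures = raw$structures %||% list(),
              camera_state = raw$camera %||% list(),
              settings = raw$settings %||% list(),
              measurements = raw$measurements %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
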