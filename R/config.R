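# Key-value configuration files (JSON or YAML) for the CLI and for batch
# parameter studies.

#' Read a configuration file
#'
#' Reads a flat key-value configuration in JSON (`.json`) or YAML
#' (`.yml`/`.yaml`) and returns it as a named list.  Used to populate
#' [topopt_config()], [assess_config()], [phantom_spec()] and material/law
#' selections from disk.
#'
#' @param path File path; the dialect is chosen by extension.
#' @return Named list.
#' @examples
#' p <- tempfile(fileext = ".json")
#' writeLines('{"local_volume_fraction": 0.35, "max_iters": 40}', p)
#' cfg <- do.call(topopt_config, read_config(p))
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  out <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yml = ,
    yaml = yaml::read_yaml(path),
    stop("unsupported config format: .", ext, " (use JSON or YAML)",
         call. = FALSE))
  as.list(out)
}

#' Load set from a configuration file
#'
#' Builds a custom load set from a config with declared units: top-level
#' keys `patient_weight` and `reference_weight` (kg, optional, default 51),
#' and `cases`, a list of entries with `name`, `force_N` (length-3) and/or
#' one of `moment_Nmm` / `moment_Nm` (length-3; Nm values are converted to
#' Nmm).  Case magnitudes are scaled by `patient_weight / reference_weight`.
#'
#' @param config Path to a JSON/YAML file, or an equivalent list.
#' @return A `load_set` (as from [reference_load_set()]).
#' @export
load_set_from_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  pw <- config$patient_weight %||% 51
  rw <- config$reference_weight %||% 51
  s <- pw / rw
  cases_in <- config$cases
  if (is.data.frame(cases_in)) {
    cases_in <- lapply(seq_len(nrow(cases_in)),
                       function(i) as.list(cases_in[i, ]))
  }
  if (length(cases_in) == 0) stop("config has no load cases", call. = FALSE)
  cases <- lapply(cases_in, function(cs) {
    force <- unlist(cs$force_N %||% c(0, 0, 0))
    moment <- if (!is.null(cs$moment_Nmm)) unlist(cs$moment_Nmm)
              else if (!is.null(cs$moment_Nm)) unlist(cs$moment_Nm) * 1000
              else c(0, 0, 0)
    load_case(cs$name %||% "case", force = force * s, moment = moment * s)
  })
  structure(list(cases = cases, patient_weight = pw, reference_weight = rw),
            class = "load_set")
}
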