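#' @useDynLib notchcrypt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate kmeans median runif
#' @importFrom utils write.csv
NULL

#' Load and validate a circuit configuration file
#'
#' Reads a flat key-value configuration (YAML or JSON, keys named after the
#' model symbols: \code{beta_N}, \code{alpha_R}, \code{S_PF}, ...), fills
#' unspecified keys from the named fixture defaults, rejects unknown keys,
#' and returns a validated parameter object. An empty file yields the
#' defaults.
#'
#' @param path configuration file; format chosen by extension
#'   (\code{.json} vs \code{.yaml}/\code{.yml}).
#' @param base fixture name supplying defaults (see [fixture_params()]).
#' @return a \code{circuit_params} object.
#' @export
load_config <- function(path, base = "pfli_default") {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- unclass(fixture_params(base))
  settable <- c("beta_N", "beta_D", "alpha_N", "alpha_D", "alpha_R",
                "k_p", "k_d", "p", "h", "S_PF", "S_LI")
  unknown <- setdiff(names(raw), settable)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         " (settable: ", paste(settable, collapse = ", "), ")")
  merged <- defaults[settable]
  merged[names(raw)] <- raw
  do.call(circuit_params, c(merged, list(model_form = "MODEL3")))
}

#' Write a circuit configuration file
#'
#' Inverse of [load_config()]: serializes the settable fields of a
#' parameter object as canonical JSON (or YAML by extension), so that
#' \code{load_config(write_config(p, f))} round-trips.
#'
#' @param params a \code{circuit_params} object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(params, path) {
  validate_params(params)
  fields <- c("beta_N", "beta_D", "alpha_N", "alpha_D", "alpha_R",
              "k_p", "k_d", "p", "h", "S_PF", "S_LI")
  x <- unclass(params)[fields]
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(x, path)
  invisible(path)
}

#' Write a reproducibility manifest for an analysis stage
#'
#' Records the stage name, master seed, a canonical-JSON hash of the
#' parameter snapshot, the output file list, and the package version, so a
#' run can be reproduced exactly from the manifest alone.
#'
#' @param path manifest file (JSON).
#' @param stage stage label.
#' @param seed master seed used (NA for deterministic stages).
#' @param params parameter object or plain list snapshot.
#' @param outputs character vector of files the stage wrote.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, stage, seed, params, outputs = character(0)) {
  snapshot <- if (inherits(params, "circuit_params")) unclass(params) else params
  canonical <- jsonlite::toJSON(snapshot, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    stage = stage,
    seed = if (is.na(seed)) NULL else as.integer(seed),
    params = snapshot,
    params_hash = sprintf("%08x", sum(utf8ToInt(as.character(canonical)) *
                                        (seq_len(nchar(canonical)) %% 97 + 1)) %% .Machine$integer.max),
    outputs = outputs,
    package_version = as.character(utils::packageVersion("notchcrypt")))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
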