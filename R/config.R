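# Run configuration: YAML/JSON loading with full defaulting, schema
# validation (unknown keys rejected, typed leaves), deterministic seed
# fan-out per pipeline stage, and the JSON run manifest.

#' Default run configuration
#'
#' The packaged defaults reproduce the calibrated reference run: the frozen
#' surrogate geometry, printed-anchor cohort, default materials and loading,
#' and the six target ages under all three bite modes with and without the
#' temporal fascia.
#'
#' @return nested named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    anatomy = list(
      skull = list(pitch = 2, size_scale = 1, shell_thickness = 4,
                   suture_width = 2, growth_s3 = 0.78, face_exponent = 1.35,
                   arch_clearance = 0),
      cohort = list(n = 51L, age_min = 0, age_max = 48, cv = 0.10,
                    seed = 101L)
    ),
    materials = list(E_bone0 = 421, bone_rate = 125, E_joint0 = 30,
                     joint_rate = 100, joint_freeze_age = 12,
                     nu_bone = 0.22, nu_joint = 0.30),
    loading = list(stress_factor = 37, vectors_per_side = 3L,
                   fascia_vectors = 6L, attach_radius = 4),
    pipeline = list(ages = c(3, 6, 12, 24, 36, 48), modes = c(1L, 2L, 3L),
                    fascia = c(FALSE, TRUE), out_dir = "."),
    seed = 1L
  ), class = "run_config")
}

# recursive merge of user values over defaults with schema enforcement:
# unknown keys are an error, and each leaf is coerced to the default's type
.merge_config <- function(default, user, path = "") {
  if (is.null(user)) return(default)
  if (!is.list(default)) {
    # leaf: coerce to the default's storage type
    val <- if (is.integer(default)) {
      v <- suppressWarnings(as.integer(user))
      if (anyNA(v) && !anyNA(user)) stop("schema error: key '", path,
                                         "' must be integer", call. = FALSE)
      v
    } else if (is.numeric(default)) {
      v <- suppressWarnings(as.numeric(user))
      if (anyNA(v) && !anyNA(user)) stop("schema error: key '", path,
                                         "' must be numeric", call. = FALSE)
      v
    } else if (is.logical(default)) {
      v <- as.logical(user)
      if (anyNA(v)) stop("schema error: key '", path, "' must be logical",
                         call. = FALSE)
      v
    } else as.character(user)
    return(val)
  }
  if (!is.list(user))
    stop("schema error: key '", path, "' must be a mapping", call. = FALSE)
  unknown <- setdiff(names(user), names(default))
  if (length(unknown))
    stop("schema error: unknown key '",
         paste0(path, if (nzchar(path)) "." else "", unknown[1L]), "'",
         call. = FALSE)
  for (k in names(user))
    default[[k]] <- .merge_config(default[[k]],
                                  user[[k]],
                                  paste0(path, if (nzchar(path)) "." else "",
                                         k))
  default
}

.validate_config <- function(cfg) {
  s <- cfg$anatomy$skull
  if (s$pitch <= 0) stop("schema error: anatomy.skull.pitch must be > 0",
                         call. = FALSE)
  if (cfg$loading$vectors_per_side < 1L || cfg$loading$vectors_per_side > 3L)
    stop("schema error: loading.vectors_per_side must be in 1..3",
         call. = FALSE)
  if (!cfg$loading$fascia_vectors %in% c(6L, 8L))
    stop("schema error: loading.fascia_vectors must be 6 or 8", call. = FALSE)
  if (cfg$loading$stress_factor <= 0)
    stop("schema error: loading.stress_factor must be > 0", call. = FALSE)
  if (cfg$anatomy$cohort$n < 2L)
    stop("schema error: anatomy.cohort.n must be >= 2", call. = FALSE)
  if (cfg$anatomy$cohort$cv < 0)
    stop("schema error: anatomy.cohort.cv must be >= 0", call. = FALSE)
  if (any(cfg$pipeline$ages < 3 | cfg$pipeline$ages > 48))
    stop("schema error: pipeline.ages must lie in [3, 48]", call. = FALSE)
  if (any(!cfg$pipeline$modes %in% 1:3))
    stop("schema error: pipeline.modes must be among 1, 2, 3", call. = FALSE)
  invisible(cfg)
}

#' Load a run configuration from YAML (or JSON)
#'
#' Missing keys take the packaged defaults; unknown keys and type violations
#' are schema errors naming the offending key.  An empty file yields the
#' full default configuration.
#'
#' @param path file path; `NULL` returns the defaults.
#' @return a validated `run_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(.validate_config(default_config()))
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE) else
      yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- .merge_config(default_config(), user)
  class(cfg) <- "run_config"
  .validate_config(cfg)
  cfg
}

#' Write a configuration to YAML
#'
#' `load_config(dump_config(cfg, f))` reproduces `cfg` exactly.
#'
#' @param cfg a `run_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# small non-cryptographic polynomial hash (provenance fingerprints)
.poly_hash <- function(s) {
  v <- utf8ToInt(s)
  h <- 2166136261 %% 2147483647
  for (x in v) h <- (h * 131 + x) %% 2147483647
  sprintf("%08x", h)
}

#' Fingerprint of a configuration
#'
#' @param cfg a `run_config`.
#' @return 8-hex-digit hash of the canonical JSON form.
#' @export
config_hash <- function(cfg) {
  .poly_hash(as.character(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                           digits = 15)))
}

#' Deterministic per-stage seed fan-out
#'
#' Derives a stage seed from the global seed by hashing the stage name, so
#' stages are decoupled but the whole run is reproducible from one seed.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) +
                strtoi(.poly_hash(stage), 16L) %% 100003) %% 2147483647)
}

#' Write a JSON run manifest
#'
#' Records the configuration hash, global seed, package version, and
#' per-stage status/timings of a (possibly failed) run.
#'
#' @param path output file.
#' @param cfg the `run_config` used.
#' @param stages named list; each entry a list with `status`
#'   (`"ok"`/`"error"`), optional `error` message and `seconds`.
#' @param seed global seed of the run.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, cfg, stages = list(), seed = cfg$seed) {
  man <- list(
    manifest_version = "1.0",
    package = "cranioload",
    version = tryCatch(as.character(packageVersion("cranioload")),
                       error = function(e) "dev"),
    config_hash = config_hash(cfg),
    seed = as.integer(seed),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = stages
  )
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir,
                             call. = FALSE)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}

#' Validate a manifest against the packaged schema
#'
#' @param path manifest JSON file.
#' @return `TRUE` if valid, otherwise an error naming the violation.
#' @export
validate_manifest <- function(path) {
  man <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  schema <- jsonlite::fromJSON(system.file("manifest-schema.json",
                                           package = "cranioload",
                                           mustWork = TRUE),
                               simplifyVector = FALSE)
  for (k in names(schema$required)) {
    if (is.null(man[[k]]))
      stop("manifest missing required field '", k, "'", call. = FALSE)
    want <- schema$required[[k]]
    ok <- switch(want, string = is.character(man[[k]]),
                 integer = is.numeric(man[[k]]),
                 object = is.list(man[[k]]), TRUE)
    if (!ok) stop("manifest field '", k, "' must be ", want, call. = FALSE)
  }
  TRUE
}
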