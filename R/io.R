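#' Load a run configuration
#'
#' Reads a YAML key/value file whose keys mirror the model parameter names
#' (plus the seed entries \code{map_seed}, \code{dynamics_seed},
#' \code{velocity_seed} and the \code{preset} selector).  Unknown keys are
#' rejected; unspecified keys take the published defaults.
#'
#' @param path configuration file path; an empty or missing-keys file
#'   yields the full default parameter set.
#' @param overrides named list applied after the file (e.g. from CLI
#'   flags).
#' @return a list with elements \code{params} (a \code{gp_params}) and
#'   \code{seeds}.
#' @export
load_config <- function(path, overrides = list()) {
  cfg <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("config file not found: ", path)
  if (is.null(cfg)) cfg <- list()
  cfg[names(overrides)] <- overrides
  seed_keys <- c("map_seed", "dynamics_seed", "velocity_seed")
  seeds <- cfg[intersect(names(cfg), seed_keys)]
  preset <- if (!is.null(cfg$preset)) cfg$preset else "full"
  cfg <- cfg[setdiff(names(cfg), c(seed_keys, "preset"))]
  allowed <- names(formals(model_params))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (key in names(cfg))
    if (!is.numeric(cfg[[key]]) && !is.character(cfg[[key]]) &&
        !is.null(cfg[[key]]))
      stop("config key ", key, " has an unsupported type")
  params <- do.call(preset_params, c(list(preset = preset), cfg))
  defaults <- list(map_seed = 1L, dynamics_seed = 1L, velocity_seed = 1L)
  defaults[names(seeds)] <- lapply(seeds, as.integer)
  list(params = params, seeds = defaults)
}

#' Save an experiment result bundle
#'
#' Writes every tabular/array component of an experiment result as CSV
#' (full precision) together with a JSON-like manifest listing files and
#' MD5 checksums.
#'
#' @param result a list (e.g. a \code{gp_experiment}).
#' @param path output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
save_result <- function(result, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(result)) {
    x <- result[[nm]]
    f <- file.path(path, paste0(nm, ".csv"))
    if (is.data.frame(x)) {
      utils::write.csv(x, f, row.names = FALSE)
    } else if (is.matrix(x)) {
      utils::write.table(x, f, sep = ",", row.names = FALSE,
                         col.names = FALSE)
    } else if (is.atomic(x) && length(x) > 0) {
      utils::write.table(data.frame(value = as.vector(x)), f, sep = ",",
                         row.names = FALSE)
    } else next
    files <- c(files, f)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(path, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Reload and verify a saved result bundle
#'
#' @param path directory written by [save_result()].
#' @return a named list of data frames; errors if a checksum mismatches.
#' @export
load_result <- function(path) {
  manifest <- utils::read.csv(file.path(path, "manifest.csv"))
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(path, manifest$file[i])
    if (unname(tools::md5sum(f)) != manifest$md5[i])
      stop("checksum mismatch for ", manifest$file[i])
    out[[sub("\\.csv$", "", manifest$file[i])]] <-
      utils::read.csv(f, header = grepl("trials|decoded|msd", f))
  }
  out
}
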