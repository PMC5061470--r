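#' Gas constant in kcal/(mol K)
#'
#' Value used throughout for free-energy arithmetic, chosen so that
#' \eqn{\Delta G = RT \ln K_D} reproduces published panel thermodynamics at
#' 288.15 K to the printed 0.01 kcal/mol.
#' @export
R_KCAL <- 1.9872e-3

#' Celsius to kelvin
#' @param temp_C temperature in degrees Celsius
#' @return temperature in kelvin
#' @export
celsius_to_kelvin <- function(temp_C) temp_C + 273.15

#' Derive a child RNG seed from a top-level seed
#'
#' Deterministic splitting rule so that each simulated dataset gets its own
#' stream: `(seed * 48271 + stream) mod (2^31 - 1)`, kept strictly positive.
#' Adding a new dataset (a new `stream` index) never perturbs existing ones.
#'
#' @param seed top-level integer seed
#' @param stream non-negative integer stream index
#' @return an integer seed in `[1, 2^31 - 2]`
#' @export
child_seed <- function(seed, stream = 0L) {
  s <- (as.numeric(seed) * 48271 + as.numeric(stream)) %% 2147483647
  as.integer(s) + 1L
}

#' Run-wide configuration with every documented tunable
#'
#' Returns the default configuration list consumed by the fitting and
#' reporting functions. Every tunable named in the package documentation has
#' an entry here; `load_config()` reads a JSON file with the same keys and
#' merges it over these defaults.
#'
#' @param ... named overrides of individual defaults
#' @return a named list of class `run_config`
#' @export
#' @examples
#' cfg <- default_config(itc_n_baseline = 1)
#' cfg$itc_n_baseline
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    gas_constant = R_KCAL,
    itc_temperature_C = 15,
    itc_n_baseline = 2L,
    itc_min_signal_ucal = 0.5,
    weak_kd_nM = 5e4,
    weak_c_value = 1,
    affinity_edges_nM = c(100, 1000, 10000),
    dsf_noise_floor_mult = 5,
    dsf_truncate_margin_C = 5,
    dsf_dh_init = 100,
    frap_halftime_method = "exponential", # or "interpolation"
    frap_paired = FALSE,
    ci_cross_term = FALSE,
    me_fa_clip = c(0.01, 0.99),
    viability_clip = c(0, 1.5)
  )
  user <- list(...)
  if (length(user)) {
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, user)
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Read a configuration file (JSON)
#'
#' @param path path to a flat JSON object whose keys match [default_config()]
#' @return a `run_config` list (file values merged over defaults)
#' @export
load_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, as.list(vals))
}

#' Write a configuration to JSON
#' @param config a `run_config` list
#' @param path output path
#' @return `path`, invisibly
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# internal: stop with a consistent prefix
abort_pt <- function(...) stop(..., call. = FALSE)

# internal: read '# key: value' metadata header lines from a delimited file
read_metadata_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    body <- sub("^#\\s*", "", ln)
    if (!grepl(":", body, fixed = TRUE)) next
    key <- trimws(sub(":.*$", "", body))
    val <- trimws(sub("^[^:]*:", "", body))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else val
  }
  meta
}

# internal: write metadata header then a data frame as CSV
write_csv_with_metadata <- function(df, meta, path) {
  header <- vapply(names(meta), function(key) {
    sprintf("# %s: %s", key, format(meta[[key]], scientific = FALSE))
  }, character(1))
  body <- readr::format_csv(df)
  writeLines(c(header, sub("\n$", "", body)), path)
  invisible(path)
}
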