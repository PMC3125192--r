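#' Screen parameters
#'
#' Collects every numeric constant used by the screening pipeline in one
#' validated object. Defaults are the values used throughout the antisense
#' screening literature this package implements: an intensity detection
#' threshold of 100, a twofold expression-change cut-off, a threefold
#' antisense-dominance cut-off, a 10% balance margin with support required in
#' at least 3 of 6 patients, and 60-mer probes tiled every 500 bases.
#'
#' @param ... named overrides of the defaults. Unknown names are an error.
#'
#' Fields and defaults:
#' \describe{
#'   \item{detection_threshold}{intensity at or above which a probe is called
#'     expressed (default 100; the comparison is inclusive).}
#'   \item{fold_change}{cancer/normal ratio beyond which a probe is called
#'     changed; applied strictly (`> fold` or `< 1/fold`; default 2).}
#'   \item{dominance_fold}{antisense/sense median ratio at or above which a
#'     pair is antisense-dominant (inclusive; default 3).}
#'   \item{margin}{minimum relative difference ("at least 10%") used by the
#'     balance-reversal conditions, as a fraction in (0, 1) (default 0.10).}
#'   \item{min_support}{patients that must individually satisfy all screen
#'     conditions for a pair to be reported (default 3).}
#'   \item{n_patients}{patients in the paired design (default 6).}
#'   \item{tile_step}{antisense probe tiling step along the spliced
#'     transcript, in bases (default 500).}
#'   \item{probe_length}{probe length in bases (default 60).}
#'   \item{intensity_floor}{pseudocount applied to numerator and denominator
#'     of every ratio so ratios stay finite (default 1.0).}
#'   \item{n_shuffles}{default shuffle count for the permutation null
#'     (default 1000).}
#'   \item{seed}{default RNG seed recorded with permutation results.}
#' }
#'
#' @return an object of class `screen_params` (a named list).
#' @examples
#' screen_params()
#' screen_params(margin = 0.2, n_shuffles = 500)
#' @export
screen_params <- function(...) {
  defaults <- list(
    detection_threshold = 100,
    fold_change = 2,
    dominance_fold = 3,
    margin = 0.10,
    min_support = 3L,
    n_patients = 6L,
    tile_step = 500L,
    probe_length = 60L,
    intensity_floor = 1.0,
    n_shuffles = 1000L,
    seed = 1L
  )
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == ""))) {
    abort_input("screen_params(): all arguments must be named")
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    abort_input("screen_params(): unknown parameter(s): %s",
                paste(unknown, collapse = ", "))
  }
  p <- utils::modifyList(defaults, over)
  int_keys <- c("min_support", "n_patients", "tile_step", "probe_length",
                "n_shuffles", "seed")
  for (k in int_keys) p[[k]] <- as.integer(p[[k]])
  validate_screen_params(p)
  structure(p, class = "screen_params")
}

validate_screen_params <- function(p) {
  num_keys <- setdiff(names(p), "seed")
  for (k in num_keys) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      abort_input("invalid screen parameter '%s': must be a single positive number", k)
    }
  }
  if (p$margin >= 1) {
    abort_input("invalid screen parameter 'margin': must be in (0, 1), got %g", p$margin)
  }
  if (p$min_support > p$n_patients) {
    abort_input("invalid screen parameter 'min_support': %d exceeds n_patients = %d",
                p$min_support, p$n_patients)
  }
  if (p$probe_length > p$tile_step) {
    abort_input("invalid screen parameter 'probe_length': %d exceeds tile_step = %d",
                p$probe_length, p$tile_step)
  }
  invisible(p)
}

#' @export
print.screen_params <- function(x, ...) {
  cat("Screen parameters:\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}

# Parse "key = value" lines (TOML-like subset: comments with '#', optional
# quoting of values). Returns a named list of character values.
parse_kv_lines <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      abort_input("config line is not 'key = value': '%s'", ln)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    if (!nzchar(key)) abort_input("config line has empty key: '%s'", ln)
    if (key %in% names(out)) abort_input("duplicate config key '%s'", key)
    out[[key]] <- val
  }
  out
}

#' Read screen parameters from a key = value config file
#'
#' Accepts a TOML-style text file (or a character vector of lines) with one
#' `key = value` entry per line and `#` comments. Absent keys take the
#' [screen_params()] defaults; unknown keys are rejected.
#'
#' @param config path to a config file, or a character vector of lines
#'   (anything of length > 1, or containing "=", is treated as lines).
#' @return a validated `screen_params` object.
#' @examples
#' parse_config(character(0))                 # all defaults
#' parse_config(c("margin = 0.2", "n_shuffles = 200"))
#' @export
parse_config <- function(config) {
  lines <- if (length(config) == 1L && !grepl("=", config, fixed = TRUE)) {
    if (!file.exists(config)) abort_input("config file not found: %s", config)
    readLines(config, warn = FALSE)
  } else {
    as.character(config)
  }
  kv <- parse_kv_lines(lines)
  num <- lapply(kv, function(v) {
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) abort_input("config value is not numeric: '%s'", v)
    x
  })
  do.call(screen_params, num)
}
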