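#' Run configuration
#'
#' A run config collects the per-run knobs of the pipeline in one
#' human-editable key=value file, so every report can record exactly how it
#' was produced. CLI flags override config values.
#'
#' @param locus locus name (e.g. `"HTT"`).
#' @param spec repeat spec reference: `"cag-cbe"`, `"gaa-abe"` or a path to a
#'   custom spec JSON.
#' @param peak_height_fraction relative peak-height threshold for instability
#'   indices, in \[0, 1\] (default 0.05).
#' @param detection_threshold off-target detection threshold, fraction
#'   (default 0.005).
#' @param substantial_threshold off-target "substantial editing" threshold,
#'   fraction (default 0.05).
#' @param min_coverage minimum read depth for off-target loci; loci with any
#'   position at or below this depth are filtered (default 30).
#' @param contraction_cap largest contraction (repeat units) retained in
#'   instability indices (default 40).
#' @param seed integer random seed.
#' @param out_dir output directory.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(locus = "HTT", spec = "cag-cbe",
                       peak_height_fraction = 0.05,
                       detection_threshold = 0.005,
                       substantial_threshold = 0.05,
                       min_coverage = 30L, contraction_cap = 40L,
                       seed = 1L, out_dir = ".") {
  check_prob(peak_height_fraction, "peak_height_fraction")
  check_prob(detection_threshold, "detection_threshold")
  check_prob(substantial_threshold, "substantial_threshold")
  min_coverage <- as.integer(min_coverage)
  if (is.na(min_coverage) || min_coverage < 0L) {
    stop("min_coverage must be >= 0", call. = FALSE)
  }
  structure(
    list(locus = locus, spec = spec,
         peak_height_fraction = peak_height_fraction,
         detection_threshold = detection_threshold,
         substantial_threshold = substantial_threshold,
         min_coverage = min_coverage,
         contraction_cap = as.integer(contraction_cap),
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a run config from a key=value file
#'
#' @param path config file; `#` lines and blank lines are ignored.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  if (any(lengths(kv) != 3L)) {
    stop("malformed config line: ", lines[which(lengths(kv) != 3L)[1L]],
         call. = FALSE)
  }
  vals <- stats::setNames(trimws(vapply(kv, `[`, "", 3L)),
                          trimws(vapply(kv, `[`, "", 2L)))
  defaults <- run_config()
  numeric_keys <- c("peak_height_fraction", "detection_threshold",
                    "substantial_threshold")
  integer_keys <- c("min_coverage", "contraction_cap", "seed")
  args <- as.list(defaults)
  for (k in names(vals)) {
    if (!k %in% names(args)) {
      stop("unknown config key: ", k, call. = FALSE)
    }
    args[[k]] <- if (k %in% numeric_keys) as.numeric(vals[[k]])
                 else if (k %in% integer_keys) as.integer(vals[[k]])
                 else vals[[k]]
  }
  do.call(run_config, args)
}

#' Write a run config to a key=value file
#'
#' Round-trips losslessly through [read_run_config()].
#'
#' @param config a [run_config()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lines <- vapply(names(config), function(k) {
    paste0(k, "=", format(config[[k]], scientific = FALSE))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' MD5 hash of a run config
#'
#' Used in report headers to tie outputs to the exact configuration.
#'
#' @param config a [run_config()].
#' @return Character MD5 digest.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".cfg")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}
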