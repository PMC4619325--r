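# Flat key-value run configuration for the command-line interface.
#
# Precedence: command-line flags > config file > package defaults. The
# fully resolved configuration is logged so a run can be reproduced.

.CONFIG_DEFAULTS <- list(
  ppm = 5, rt_tol = 30, separator = "_",
  ppm_limits = c(3, 5, 8), rt_limits_s = c(6, 12, 30),
  area_limits_pct = c(20, 30, 50),
  rt_reference = "fixed", mz_reference = "fixed",
  rt_scope = "global", mz_scope = "global", area_scope = "per_sequence",
  ria = FALSE, x_axis = "order", image_format = "png")

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Numeric
#' triples (zone limits) are comma-separated, booleans are
#' `true`/`false`. Unknown keys are an error so that typos do not pass
#' silently.
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @param overrides Named list of values taking precedence over the
#'   file (typically parsed command-line flags).
#' @return Named list with all configuration keys resolved.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- .CONFIG_DEFAULTS
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) < 2L)
        stop(sprintf("malformed config line: '%s'", ln), call. = FALSE)
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      if (!key %in% names(.CONFIG_DEFAULTS))
        stop(sprintf("unknown config key '%s' (known: %s)", key,
                     paste(names(.CONFIG_DEFAULTS), collapse = ", ")), call. = FALSE)
      cfg[[key]] <- .coerce_config_value(key, val)
    }
  }
  for (key in names(overrides)) {
    if (!key %in% names(.CONFIG_DEFAULTS))
      stop(sprintf("unknown config key '%s'", key), call. = FALSE)
    if (!is.null(overrides[[key]])) cfg[[key]] <- overrides[[key]]
  }
  cfg
}

.coerce_config_value <- function(key, val) {
  proto <- .CONFIG_DEFAULTS[[key]]
  if (is.logical(proto)) return(tolower(val) %in% c("true", "1", "yes"))
  if (is.numeric(proto)) {
    out <- as.numeric(strsplit(val, ",", fixed = TRUE)[[1]])
    if (anyNA(out)) stop(sprintf("config key '%s': non-numeric value '%s'", key, val),
                         call. = FALSE)
    return(out)
  }
  val
}

#' Tolerance scheme from a resolved configuration
#' @param cfg A list from [read_run_config()].
#' @return A [tolerance_scheme()].
#' @export
config_scheme <- function(cfg) {
  tolerance_scheme(
    ppm_limits = cfg$ppm_limits, rt_limits_s = cfg$rt_limits_s,
    area_limits_pct = cfg$area_limits_pct,
    reference = list(rt = cfg$rt_reference, mz = cfg$mz_reference,
                     area = "data_mean"),
    scope = list(rt = cfg$rt_scope, mz = cfg$mz_scope, area = cfg$area_scope))
}
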