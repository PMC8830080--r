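`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_named <- function(...) stop(..., call. = FALSE)

# Check a scalar probability / proportion.
check_prop <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_named("'", what, "' must be a single proportion in [0, 1], got ",
               deparse(substitute(x)), " = ", format(x))
  invisible(x)
}

check_pos <- function(x, what, strict = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) && if (strict) all(x > 0) else all(x >= 0)
  if (!ok)
    stop_named("'", what, "' must be ", if (strict) "strictly positive" else "non-negative",
               " and finite")
  invisible(x)
}

# Read a JSON or YAML file by extension (both formats are accepted for
# profiles, price lists, coefficient tables and calibrations).
read_config_file <- function(path) {
  if (!file.exists(path))
    stop_named("file not found: '", path, "'")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

fmt_cny <- function(x) paste0("¥", formatC(round(x), format = "d", big.mark = ","))
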