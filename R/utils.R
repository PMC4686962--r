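# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config("'%s' must be a single finite number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_config("'%s' = %g outside the allowed range %s%g, %g%s", name, x,
                if (strict_lower) "(" else "[", lower, upper,
                if (strict_upper) ")" else "]")
  invisible(x)
}

# fixed 9-significant-digit formatting so text artifacts are byte-stable
fmt_num <- function(x) {
  out <- formatC(x, digits = 9L, format = "g", flag = "")
  out[is.nan(x)] <- "NaN"
  out[is.na(x) & !is.nan(x)] <- "NA"
  trimws(out)
}

write_table_fixed <- function(df, path) {
  stopifnot(is.data.frame(df))
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

write_json_fixed <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# angular difference wrapped to (-pi, pi]
wrap_angle <- function(x) {
  out <- (x + pi) %% (2 * pi) - pi
  out[out <= -pi] <- out[out <= -pi] + 2 * pi
  out
}

vec_norm <- function(m) sqrt(rowSums(m^2))

unit_rows <- function(m) m / pmax(vec_norm(m), .Machine$double.eps)
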