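# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ctb <- function(fmt, ..., class = "ctb_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_ctb("'%s' must be a single finite number", name, class = "ctb_config_error")
  if (x < lo || x > hi)
    stop_ctb("'%s' = %g out of range [%g, %g]", name, x, lo, hi,
             class = "ctb_config_error")
  invisible(x)
}

# Case-insensitive enum canonicalisation; empty string / NA -> NA.
match_enum <- function(x, levels, field, allow_na = TRUE) {
  x <- as.character(x)
  out <- levels[match(tolower(trimws(x)), tolower(levels))]
  missing <- is.na(x) | trimws(x) %in% c("", "NA")
  out[missing] <- NA_character_
  bad <- which(is.na(out) & !missing)
  if (length(bad))
    stop_ctb("field '%s': unrecognised value(s) %s at row(s) %s (allowed: %s)",
             field, paste(unique(x[bad]), collapse = ", "),
             paste(utils::head(bad, 5L), collapse = ", "),
             paste(levels, collapse = "/"), class = "ctb_validation_error")
  if (!allow_na && anyNA(out))
    stop_ctb("field '%s': missing values not allowed", field,
             class = "ctb_validation_error")
  out
}

# Full-precision TSV writer: numerics rendered with %.17g so that a
# write -> read round trip is value-identical.
write_tsv_full <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- ""
      out[[j]] <- v
    } else if (is.logical(out[[j]]) || is.integer(out[[j]])) {
      v <- as.character(as.integer(out[[j]]))
      v[is.na(out[[j]])] <- ""
      out[[j]] <- v
    } else {
      v <- as.character(out[[j]])
      v[is.na(v)] <- ""
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_raw <- function(path) {
  if (!file.exists(path))
    stop_ctb("file not found: %s", path, class = "ctb_io_error")
  utils::read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", na.strings = c("", "NA"),
                    check.names = FALSE, fileEncoding = "UTF-8")
}

as_num <- function(x, field) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop_ctb("field '%s': non-numeric value(s) at row(s) %s", field,
             paste(utils::head(bad, 5L), collapse = ", "),
             class = "ctb_validation_error")
  out
}

as_bool <- function(x, field) {
  x0 <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x0))
  out[x0 %in% c("1", "true", "t", "yes")] <- TRUE
  out[x0 %in% c("0", "false", "f", "no")] <- FALSE
  bad <- which(!(x0 %in% c("1", "0", "true", "false", "t", "f", "yes", "no",
                           "", "na")) & !is.na(x))
  if (length(bad))
    stop_ctb("field '%s': non-boolean value(s) at row(s) %s", field,
             paste(utils::head(bad, 5L), collapse = ", "),
             class = "ctb_validation_error")
  out
}
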