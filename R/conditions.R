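# Structured conditions so the CLI can map failures to exit codes
# (2 = validation, 3 = model fitting) and tests can assert on class.

hx_stop <- function(msg, class = "hx_validation_error", call. = FALSE) {
  cond <- structure(
    class = c(class, "hx_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

hx_stop_fit <- function(msg) hx_stop(msg, class = "hx_fit_error")

# INFO-level logging: every exclusion (filtered cancer types, skipped genes,
# skipped tissues) goes through here so analysis counts stay auditable.
hx_log <- function(...) {
  message("[hypoxscan] ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_columns <- function(df, cols, where = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    hx_stop(sprintf("%s is missing required column(s): %s",
                    where, paste(miss, collapse = ", ")))
  }
  invisible(df)
}
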