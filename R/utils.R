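# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a master seed
#'
#' Stages of the synthetic generator (clinical, molecular, survival, ...)
#' draw from independent substreams so that each stage is reproducible on
#' its own. The substream seed is a deterministic arithmetic hash of the
#' master seed and the stream name, kept below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stream character stream name.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  codes <- utf8ToInt(stream)
  h <- as.double(master) %% 2147483647
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

# stop() with a classed condition so callers/tests can discriminate
stop_icb <- function(msg, class) {
  stop(structure(
    class = c(class, "icbcombo_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_icb(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      "icbcombo_schema_error"
    )
  }
  invisible(df)
}
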