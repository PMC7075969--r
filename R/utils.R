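# Internal helpers: structured errors, seeded evaluation, logging, TSV output.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# All package errors carry a condition class "sigconnect_<kind>_error" so
# callers (and the CLI) can distinguish input problems from configuration
# problems without parsing messages.
sc_error <- function(kind, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(sprintf("sigconnect_%s_error", kind),
                                "sigconnect_error")))
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Structured diagnostics: LEVEL<TAB>stage<TAB>message on stderr.
log_msg <- function(level, stage, msg, ...) {
  message(sprintf("%s\t%s\t%s", level, stage, sprintf(msg, ...)))
}

# Floats in result tables are written at 6 significant digits.
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6L, format = "g"))
}

# Open a path for reading/writing, transparently gzip when it ends in .gz.
open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
}

write_tsv <- function(df, path) {
  con <- open_out(path)
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) sc_error("input", "file not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}
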