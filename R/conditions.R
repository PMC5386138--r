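#' @keywords internal
"_PACKAGE"

# Classed conditions: every data-level failure inherits from "obokit_error"
# so callers (and the CLI) can distinguish data errors from usage errors.
obk_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "obokit_error", "error")))
}

obk_usage <- function(msg) {
  stop(errorCondition(msg, class = c("obokit_usage", "error")))
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Accept a file path, a single string with embedded newlines, or a character
# vector of lines; return a character vector of lines.
as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    x <- readLines(x, warn = FALSE)
  } else {
    x <- unlist(strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE))
  }
  # tolerate Windows line endings and trailing whitespace on tag lines
  sub("[ \t\r]+$", "", x)
}
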