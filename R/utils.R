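# internal helpers shared across modules

# classed errors so callers can distinguish failure modes programmatically
abort <- function(code, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("sonatar_", code), "sonatar_error",
                                "error", "condition")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

# run expr with a private RNG stream; the caller's .Random.seed is untouched
with_rng <- function(seed, expr) {
  if (!is_count(seed)) abort("bad_seed", "seed must be a non-negative integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# render a value so that parsing it back is exact, preserving the
# integer/double distinction (integral doubles gain a ".0" suffix)
format_value <- function(x) {
  if (is.character(x)) return(x)
  if (is.integer(x)) return(format(x, scientific = FALSE))
  s <- sprintf("%.17g", x)
  if (grepl("^[+-]?[0-9]+$", s)) s <- paste0(s, ".0")
  s
}

# classify one CSV token: integer-looking -> integer, numeric-looking -> double,
# otherwise text; the reserved token "NONE" is handled by the caller
parse_value <- function(tok) {
  if (grepl("^[+-]?[0-9]+$", tok) && abs(as.numeric(tok)) <= .Machine$integer.max) {
    return(as.integer(tok))
  }
  num <- suppressWarnings(as.numeric(tok))
  if (!is.na(num) && grepl("^[+-]?([0-9]*\\.?[0-9]+)([eE][+-]?[0-9]+)?$", tok)) {
    return(num)
  }
  tok
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# atomic file write: produce into a temp file in the same directory, then rename
write_atomically <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) abort("io", "directory does not exist: %s", dir)
  tmp <- tempfile(tmpdir = dir, fileext = paste0(".tmp.", basename(path)))
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) abort("io", "cannot rename %s to %s", tmp, path)
  ok <- TRUE
  invisible(path)
}
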