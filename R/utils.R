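# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Canonical slug: lowercase, apostrophes dropped, other non-alphanumeric runs
# collapsed to a single underscore ("Hair/nail" -> "hair_nail",
# "Mother's milk" -> "mothers_milk").
slugify <- function(x) {
  x <- tolower(x)
  x <- gsub("'", "", x, fixed = TRUE)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

# Locale-independent sort used everywhere an ordering must be reproducible.
sort_c <- function(x) sort(x, method = "radix")

# Canonical JSON writer: full double precision, unboxed scalars, no pretty
# indentation drift; write -> read -> write is byte identical.
write_canonical_json <- function(x, path) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = 2L)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stopifnot() with sprintf-style message
check <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
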