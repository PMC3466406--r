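#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not disturb the global RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# identifier grammar shared by parser and validator
is_identifier <- function(x) {
  is.character(x) & nzchar(x) & grepl("^[A-Za-z0-9_]+$", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable named-vector formatting used by serializers ("A=1,B=0")
format_clamps <- function(x) {
  if (length(x) == 0L) return("")
  x <- x[order(names(x))]
  paste(sprintf("%s=%d", names(x), as.integer(x)), collapse = ",")
}

parse_clamps <- function(s) {
  s <- trimws(s)
  if (!nzchar(s)) return(integer(0))
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  kv <- strsplit(trimws(parts), "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed clamp entry: ", parts[bad][1], call. = FALSE)
  vals <- suppressWarnings(as.integer(vapply(kv, `[`, "", 2L)))
  if (anyNA(vals)) stop("non-integer clamp level in: ", s, call. = FALSE)
  stats::setNames(vals, vapply(kv, `[`, "", 1L))
}
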