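# Internal helpers: typed conditions, seeded evaluation, small numeric utilities.

stop_config <- function(...) {
  stop(structure(class = c("nsct_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_invalid <- function(...) {
  stop(structure(class = c("nsct_invalid_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_io <- function(...) {
  stop(structure(class = c("nsct_io_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

check_image <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_invalid(arg, " must be a numeric matrix")
  if (!all(is.finite(x)))
    stop_invalid(arg, " contains non-finite values")
  invisible(x)
}

check_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop_invalid(what, " must have identical dimensions (",
                 paste(dim(a), collapse = "x"), " vs ",
                 paste(dim(b), collapse = "x"), ")")
  invisible(NULL)
}
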