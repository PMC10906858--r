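# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random-number generator seeded to `seed`,
#' then restores the previous RNG state, so seeded pipeline stages do not
#' disturb the caller's stream. With `seed = NULL` the expression runs on
#' the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive per-item child seeds from a master seed, reproducibly and
# independently of how many random draws each item consumes
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# dimensions of a vector/matrix/array, treating a vector as 1-d
arr_dim <- function(x) {
  d <- dim(x)
  if (is.null(d)) length(x) else d
}

same_shape <- function(a, b) identical(as.integer(arr_dim(a)), as.integer(arr_dim(b)))

stop_if_shape_mismatch <- function(a, b, what = "arrays") {
  if (!same_shape(a, b))
    stop(sprintf("shape mismatch between %s: (%s) vs (%s)", what,
                 paste(arr_dim(a), collapse = ","),
                 paste(arr_dim(b), collapse = ",")), call. = FALSE)
  invisible(TRUE)
}
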