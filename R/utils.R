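# internal helpers shared across modules

#' @keywords internal
msg <- function(..., verbose = getOption("nsbquant.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded simulation does not
#' perturb an enclosing random sequence. `seed = NULL` runs in the current
#' stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_input <- function(...) stop(..., call. = FALSE)

is_matrix2d <- function(x) is.matrix(x) && is.numeric(x)

check_finite_image <- function(image, what = "image") {
  if (!all(is.finite(image)))
    stop_input(what, " contains non-finite pixels")
  invisible(TRUE)
}

# closed numeric interval [lo, hi]
check_interval <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) || x[1] > x[2])
    stop_input(name, " must be a nonempty closed interval c(lower, upper)")
  invisible(TRUE)
}

in_interval <- function(v, interval) v >= interval[1] & v <= interval[2]
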