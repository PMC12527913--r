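#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global RNG state so seeded generators do not
#' perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# angular helpers ------------------------------------------------------------

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Fold an orientation angle (degrees) into [0, 90]
#'
#' Orientations are axial (theta and theta + 180 are the same structure), so
#' the acute angle to a reference line lies in [0, 90].
#' @param x Angle(s) in degrees.
#' @return Angle(s) in [0, 90].
#' @keywords internal
fold_angle_90 <- function(x) {
  x <- x %% 180
  ifelse(x > 90, 180 - x, x)
}
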