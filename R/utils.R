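# internal assertion helpers

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fibonacci-lattice directions on the unit (hemi)sphere
#'
#' Quasi-uniform direction sets used by the MIL scan and by the directional
#' modulus sampling.  Directions come in antipodally-unique form (upper
#' hemisphere) since every quantity sampled with them is even in `n`.
#'
#' @param n number of directions
#' @return an `n x 3` matrix of unit vectors with non-negative z
#' @export
fibonacci_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  # map to upper hemisphere: cos(theta) uniform in (0, 1)
  z <- i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}
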