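# Sobol low-discrepancy sequence, 31-bit Gray-code construction with
# Joe-Kuo ("new-joe-kuo-6") direction numbers for dimensions 2..13.
# Dimension 1 is the van der Corput sequence in base 2.
.joe_kuo <- list(
  # each row: s = polynomial degree, a = coefficient bits, m = initial values
  list(s = 1, a = 0, m = c(1)),
  list(s = 2, a = 1, m = c(1, 3)),
  list(s = 3, a = 1, m = c(1, 3, 1)),
  list(s = 3, a = 2, m = c(1, 1, 1)),
  list(s = 4, a = 1, m = c(1, 1, 3, 3)),
  list(s = 4, a = 4, m = c(1, 3, 5, 13)),
  list(s = 5, a = 2, m = c(1, 1, 5, 5, 17)),
  list(s = 5, a = 4, m = c(1, 1, 5, 5, 5)),
  list(s = 5, a = 7, m = c(1, 1, 7, 11, 19)),
  list(s = 5, a = 11, m = c(1, 1, 5, 1, 1)),
  list(s = 5, a = 13, m = c(1, 1, 1, 3, 11)),
  list(s = 5, a = 14, m = c(1, 3, 5, 5, 31))
)

.sobol_maxbit <- 31L

# direction numbers for one dimension: integer vector v[1..31], v[k] < 2^31
sobol_directions <- function(dim) {
  nb <- .sobol_maxbit
  v <- integer(nb)
  if (dim == 1L) {
    for (k in seq_len(nb)) v[k] <- bitwShiftL(1L, nb - k)
    return(v)
  }
  jk <- .joe_kuo[[dim - 1L]]
  s <- jk$s
  for (k in seq_len(s)) v[k] <- bitwShiftL(as.integer(jk$m[k]), nb - k)
  if (nb > s) {
    for (k in (s + 1L):nb) {
      vk <- bitwXor(v[k - s], bitwShiftR(v[k - s], s))
      if (s > 1L) {
        for (i in seq_len(s - 1L)) {
          if (bitwAnd(bitwShiftR(jk$a, s - 1L - i), 1L) == 1L)
            vk <- bitwXor(vk, v[k - i])
        }
      }
      v[k] <- vk
    }
  }
  v
}

#' Sobol quasi-random sequence
#'
#' Generates the first `n` points of the (unscrambled) Sobol sequence in
#' `dim` dimensions, optionally with a Cranley-Patterson random shift modulo
#' one so a seed yields a reproducible randomised sequence. Quasi-random
#' points cover the unit cube far more evenly than pseudo-random draws, which
#' accelerates the convergence of variance-based sensitivity estimators.
#'
#' @param n number of points (a power of two preserves the sequence balance).
#' @param dim dimension (at most 13).
#' @param seed integer seed for the random shift; `NULL` disables the shift
#'   and returns the raw sequence (whose first point is the origin).
#' @return An `n` x `dim` matrix with entries in [0, 1).
#' @examples
#' sobol_sequence(8, 2, seed = NULL)
#' @export
sobol_sequence <- function(n, dim, seed = NULL) {
  if (dim < 1 || dim > length(.joe_kuo) + 1L)
    stop("sobol_sequence supports dimensions 1..", length(.joe_kuo) + 1L)
  if (n < 1) stop("n must be >= 1")
  V <- vapply(seq_len(dim), sobol_directions, integer(.sobol_maxbit))
  X <- matrix(0L, nrow = n, ncol = dim)
  state <- integer(dim)
  if (n > 1) {
    for (i in 2:n) {
      # Gray code: flip the direction of the lowest zero bit of (i - 2)
      cbit <- 1L
      ii <- i - 2L
      while (bitwAnd(ii, 1L) == 1L) {
        ii <- bitwShiftR(ii, 1L)
        cbit <- cbit + 1L
      }
      state <- bitwXor(state, V[cbit, ])
      X[i, ] <- state
    }
  }
  U <- X / 2^.sobol_maxbit
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    shift <- stats::runif(dim)
    U <- sweep(U, 2, shift, "+") %% 1
  }
  U
}
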