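#' Death, birth and colonization kernels
#'
#' The per-mapping probability that a population of the transferable gene
#' suffers death by gene loss, given exposure to the neutral environmental
#' state, decays exponentially with its indispensability:
#' `p_D(y) = exp(-y*s)`. The probability that the gene is fixed after
#' horizontal transfer into a naive microbial population decays the same way
#' with its connectivity: `p_B(z) = exp(-z*s)`. Both equal 1 at 0 and are
#' strictly decreasing for `s > 0`.
#'
#' @param y,z Non-negative integer character values (vectorized).
#' @param params An [hgt_params()] object.
#' @return A probability in `(0, 1]`, same length as the input.
#' @examples
#' p <- hgt_params()
#' p_death(5, p)   # exp(-1): e-fold decrease at y = 5
#' p_birth(10, p)  # exp(-2)
#' @export
p_death <- function(y, params) {
  check_char_values(y, "y")
  exp(-y * params$s)
}

#' @rdname p_death
#' @export
p_birth <- function(z, params) {
  check_char_values(z, "z")
  exp(-z * params$s)
}

#' Density-dependent colonization rate
#'
#' Expected number of naive microbial populations one population of the
#' transferable gene enters by horizontal transfer over one mapping:
#' `beta_N = beta * (1 - N / n_max)`, clamped at 0 so that a metapopulation
#' transiently above carrying capacity produces no new colonizations rather
#' than a negative rate.
#'
#' @param n_current Current total number of populations (vectorized).
#' @param params An [hgt_params()] object.
#' @return A non-negative rate.
#' @export
beta_n <- function(n_current, params) {
  stopifnot(is.numeric(n_current), all(n_current >= 0))
  pmax(0, params$beta * (1 - n_current / params$n_max))
}

#' Fitness components of an ancestral population
#'
#' A population of the transferable gene contributes descendants two ways:
#' by persisting into the next mapping (probability
#' `w_p = 1 - delta * p_D(y)`) and by multiplying through horizontal
#' transfer (expected count `w_m = beta_N * p_B(z)`). Total expected fitness
#' is `w = w_p + w_m`.
#'
#' @param y,z Character state (vectorized, equal length or length 1).
#' @param n_current Total metapopulation size used for density dependence.
#' @param params An [hgt_params()] object.
#' @return A list with components `w_p`, `w_m` and `w`.
#' @examples
#' fitness_components(0, 0, 0, hgt_params(beta = 0.08))
#' @export
fitness_components <- function(y, z, n_current, params) {
  w_p <- 1 - params$delta * p_death(y, params)
  w_m <- beta_n(n_current, params) * p_birth(z, params)
  list(w_p = w_p, w_m = w_m, w = w_p + w_m)
}

#' Per-coordinate mutation distribution for one mapping
#'
#' Gene-host coevolution changes one character coordinate (y or z) by at
#' most one unit per mapping. For `x >= 1` the three outcomes have
#' probabilities `P(-1) = p_minus`, `P(+1) = p_plus` and
#' `P(0) = 1 - p_plus - p_minus`. At the boundary `x = 0` the `-1` outcome
#' is unavailable; its mass is removed and the remaining two outcomes are
#' renormalized (divide by `1 - p_minus`), so the upward probability becomes
#' `p_plus / (1 - p_minus)`.
#'
#' @param x A single non-negative integer character value.
#' @param params An [hgt_params()] object.
#' @return A named numeric vector with elements `"-1"`, `"0"`, `"+1"`
#'   summing to 1; the `"-1"` element is 0 when `x = 0`.
#' @examples
#' mutation_distribution(3, hgt_params())
#' mutation_distribution(0, hgt_params())
#' @export
mutation_distribution <- function(x, params) {
  check_char_values(x, "x")
  stopifnot(length(x) == 1L)
  m <- mut_probs(x, params)
  stats::setNames(as.numeric(m[1L, ]), c("-1", "0", "+1"))
}

#' Expected per-mapping change of one character coordinate
#'
#' The mean of [mutation_distribution()]: `p_plus - p_minus` for `x >= 1`,
#' and `p_plus / (1 - p_minus)` at the boundary `x = 0` where downward moves
#' are impossible.
#'
#' @param x Non-negative integer character value(s).
#' @param params An [hgt_params()] object.
#' @return Expected change, same length as `x`.
#' @export
expected_delta <- function(x, params) {
  check_char_values(x, "x")
  ifelse(x >= 1, params$p_plus - params$p_minus,
         params$p_plus / (1 - params$p_minus))
}

# Vectorized mutation probabilities: a matrix with one row per element of x
# and columns (down, stay, up). Boundary rows (x == 0) drop the down
# outcome and renormalize.
mut_probs <- function(x, params) {
  k <- length(x)
  up <- rep.int(params$p_plus, k)
  dn <- rep.int(params$p_minus, k)
  st <- 1 - up - dn
  at0 <- x == 0
  if (any(at0)) {
    denom <- 1 - params$p_minus
    up[at0] <- params$p_plus / denom
    st[at0] <- (1 - params$p_plus - params$p_minus) / denom
    dn[at0] <- 0
  }
  cbind(down = dn, stay = st, up = up)
}

# Character values must be non-negative whole numbers (y, z are counts of
# dependencies / interactions). Kept permissive about storage mode: 10 and
# 10L are both fine.
check_char_values <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) ||
      any(x < 0) || any(x != floor(x))) {
    stop(name, " must contain non-negative integers", call. = FALSE)
  }
  invisible(x)
}
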