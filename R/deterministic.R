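#' Expected lifetime of one population of the transferable gene
#'
#' Each mapping, a population at indispensability `y` dies with probability
#' `p = delta * p_D(y)` (exposure to the neutral environment followed by
#' gene loss). The number of mappings survived before death is geometric,
#' with mean `(1 - p) / p`.
#'
#' @param y Non-negative integer indispensability.
#' @param params An [hgt_params()] object.
#' @return Expected number of mappings survived; `Inf` when `delta = 0`
#'   (the gene is never exposed to the neutral state, so it cannot be lost).
#' @examples
#' expected_lifetime(0, hgt_params())   # 99
#' expected_lifetime(10, hgt_params())  # ~738
#' @export
expected_lifetime <- function(y, params) {
  p <- params$delta * p_death(y, params)
  ifelse(p == 0, Inf, (1 - p) / p)
}

#' Expected elimination time of a homogeneous cohort
#'
#' With per-mapping death probability `p = delta * p_D(y)` and no births
#' into the cohort's own class, the expected count decays geometrically:
#' `n0 * (1 - p)^t`. Returns the smallest integer `t` at which that falls
#' strictly below `threshold`.
#'
#' @param n0 Initial number of populations (> 0).
#' @param y Indispensability of the cohort.
#' @param params An [hgt_params()] object.
#' @param threshold Expected-count extinction threshold (default 1: fewer
#'   than one population expected to remain).
#' @return Number of mappings (integer); `Inf` when the cohort does not
#'   decay (`delta = 0`).
#' @examples
#' expected_elimination_time(1000, 10, hgt_params())  # ~5100
#' @export
expected_elimination_time <- function(n0, y, params, threshold = 1) {
  stopifnot(n0 > 0, threshold > 0)
  p <- params$delta * p_death(y, params)
  if (p == 0) return(Inf)
  if (n0 < threshold) return(0L)
  # smallest integer t with n0 * (1-p)^t < threshold; at an exact boundary
  # the inequality is strict, so one more mapping is needed
  r <- log(threshold / n0) / log(1 - p)
  as.integer(floor(r) + 1L)
}

#' Analytic equilibrium size of a single-class metapopulation
#'
#' For a metapopulation held at one class `(y, z)`, deaths balance births
#' when `delta * p_D(y) = beta * (1 - N / n_max) * p_B(z)`, giving
#' `N* = n_max * (1 - delta * p_D(y) / (beta * p_B(z)))`. Used as a
#' cross-check on the long-run value of the expected-count recursion.
#'
#' @param y,z Character class.
#' @param params An [hgt_params()] object.
#' @return The fixed point in `(0, n_max]`, or `NA` when none exists (the
#'   per-capita birth rate never exceeds the death rate, so the class can
#'   only decay).
#' @examples
#' equilibrium_size(0, 10, hgt_params(beta = 0.08))  # ~764
#' @export
equilibrium_size <- function(y, z, params) {
  d <- params$delta * p_death(y, params)
  b <- params$beta * p_birth(z, params)
  if (d == 0) return(params$n_max)
  if (b <= d) return(NA_real_)
  params$n_max * (1 - d / b)
}

#' One expected-value (deterministic) mapping
#'
#' Advances the expected class counts by one ancestor-descendant mapping.
#' For each occupied class `(y, z)` with count `n`:
#' * survivors `n * (1 - delta * p_D(y))` stay associated with `(y, z)`;
#' * births `n * beta_N * p_B(z)` enter class `(0, z)` — horizontal
#'   transfer carries connectivity along but resets indispensability, since
#'   a naive host has accumulated no dependencies;
#' * with `mutation = TRUE`, surviving mass is redistributed over
#'   `(y + dy, z + dz)` using the outer product of the two independent
#'   per-coordinate [mutation_distribution()]s. Newborns are not mutated in
#'   the mapping of their birth: coevolution starts only after fixation.
#'
#' Births are computed from the full ancestral counts, not from survivors —
#' a population eliminated during a mapping may still have colonized first —
#' and `beta_N` is evaluated once from the ancestral total `N`.
#'
#' @param state A [metapop()] state (real-valued counts allowed).
#' @param params An [hgt_params()] object.
#' @param mutation Logical; apply the coevolutionary transmission bias?
#' @return The descendant [metapop()] state.
#' @examples
#' step_expected(metapop(10, 10, 1000), hgt_params(beta = 0.06),
#'               mutation = FALSE)
#' @export
step_expected <- function(state, params, mutation = TRUE) {
  v <- state_vectors(state)
  out <- step_expected_core(v$y, v$z, v$count, params, mutation)
  new_metapop(out$y, out$z, out$count)
}

step_expected_core <- function(y, z, count, params, mutation) {
  if (length(y) == 0L) return(list(y = y, z = z, count = count))
  n_tot <- sum(count)
  bn <- beta_n(n_tot, params)
  surv <- count * (1 - params$delta * exp(-y * params$s))
  births <- count * (bn * exp(-z * params$s))

  if (mutation && (params$p_plus > 0 || params$p_minus > 0)) {
    py <- mut_probs(y, params)
    pz <- mut_probs(z, params)
    oy <- integer(0); oz <- integer(0); oc <- numeric(0)
    for (dy in -1:1) {
      for (dz in -1:1) {
        w <- py[, dy + 2L] * pz[, dz + 2L] * surv
        keep <- w > 0
        if (any(keep)) {
          oy <- c(oy, y[keep] + dy)
          oz <- c(oz, z[keep] + dz)
          oc <- c(oc, w[keep])
        }
      }
    }
  } else {
    oy <- y; oz <- z; oc <- surv
  }

  bkeep <- births > 0
  if (any(bkeep)) {
    oy <- c(oy, integer(sum(bkeep)))
    oz <- c(oz, z[bkeep])
    oc <- c(oc, births[bkeep])
  }
  aggregate_classes(oy, oz, oc)
}

#' Run the expected-value dynamics
#'
#' Iterates [step_expected()] for `mappings` steps, recording total `N` and
#' mean character state after every mapping. The run is declared extinct at
#' the first mapping where total expected `N` drops below
#' `extinction_threshold` (fewer than one population expected to remain, by
#' default) and, if `stop_at_extinction`, is truncated there.
#'
#' @param state Initial [metapop()] state.
#' @param params An [hgt_params()] object.
#' @param mappings Number of ancestor-descendant mappings to iterate.
#' @param mutation Logical; apply the transmission bias each mapping?
#' @param extinction_threshold Expected-count threshold (> 0, default 1).
#' @param stop_at_extinction Truncate the trajectory at extinction?
#' @return An [hgt_trajectory] data frame (see [run_summary()]).
#' @examples
#' tr <- run_expected(metapop(10, 10, 1000), hgt_params(beta = 0.06),
#'                    mappings = 200, mutation = FALSE)
#' tail(tr)
#' @export
run_expected <- function(state, params, mappings, mutation = TRUE,
                         extinction_threshold = 1, stop_at_extinction = TRUE) {
  stopifnot(mappings >= 0, extinction_threshold > 0)
  v <- state_vectors(state)
  mat <- matrix(NA_real_, nrow = mappings + 1L, ncol = 4L)
  rec <- function(i, v) {
    n <- sum(v$count)
    my <- if (n > 0) sum(v$count * v$y) / n else NA_real_
    mz <- if (n > 0) sum(v$count * v$z) / n else NA_real_
    mat[i + 1L, ] <<- c(i, n, my, mz)
  }
  rec(0L, v)
  ext <- NA_integer_
  t_last <- 0L
  if (mappings > 0L) {
    for (t in seq_len(mappings)) {
      v <- step_expected_core(v$y, v$z, v$count, params, mutation)
      rec(t, v)
      t_last <- t
      if (is.na(ext) && sum(v$count) < extinction_threshold) {
        ext <- t
        if (stop_at_extinction) break
      }
    }
  }
  new_trajectory(mat[seq_len(t_last + 1L), , drop = FALSE], params, ext,
                 new_metapop(v$y, v$z, v$count))
}
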