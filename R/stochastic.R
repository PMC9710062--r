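#' One stochastic mapping
#'
#' Random counterpart of [step_expected()]. Per occupied class `(y, z)`
#' with integer count `n`:
#' * survivors are `Binomial(n, 1 - delta * p_D(y))` — the stated two-stage
#'   process (Bernoulli exposure to the neutral state, then Bernoulli death
#'   with probability `p_D(y)`) collapsed into one Bernoulli per population
#'   with success `delta * p_D(y)`, which is distributionally identical;
#' * newborns into class `(0, z)` are `Poisson(n * beta_N * p_B(z))`:
#'   per-population `Poisson(beta_N)` colonization attempts, each fixing
#'   with probability `p_B(z)`, thinned into a single Poisson draw;
#' * with `mutation = TRUE`, survivors are multinomially distributed over
#'   the nine `(y + dy, z + dz)` outcomes, the two coordinates mutating
#'   independently. Newborns are not mutated in the mapping of their birth.
#'
#' `beta_N` is computed once from the ancestral total `N`. Sampling at the
#' class level (Binomial / Poisson / multinomial) rather than population by
#' population is exact because populations within a class are exchangeable,
#' and is what makes 1e4 populations x 1e4 mappings tractable.
#'
#' @param state A [metapop()] state with integer counts.
#' @param params An [hgt_params()] object.
#' @param mutation Logical; apply random coevolutionary changes?
#' @return The descendant [metapop()] state (integer counts). Uses R's
#'   global random number stream; seed with `set.seed()` or use
#'   [run_stochastic()].
#' @export
step_stochastic <- function(state, params, mutation = TRUE) {
  v <- state_vectors(state)
  if (any(v$count != floor(v$count))) {
    stop("stochastic dynamics require integer counts", call. = FALSE)
  }
  out <- step_stochastic_core(v$y, v$z, v$count, params, mutation)
  new_metapop(out$y, out$z, out$count)
}

step_stochastic_core <- function(y, z, count, params, mutation) {
  k <- length(y)
  if (k == 0L) return(list(y = y, z = z, count = count))
  n_tot <- sum(count)
  bn <- beta_n(n_tot, params)
  surv <- stats::rbinom(k, count, 1 - params$delta * exp(-y * params$s))
  births <- stats::rpois(k, count * (bn * exp(-z * params$s)))

  if (mutation && (params$p_plus > 0 || params$p_minus > 0)) {
    # multinomial over {down, stay, up} as two sequential binomials,
    # vectorized across classes; y first, then z within each y outcome
    py <- mut_probs(y, params)
    up_y <- stats::rbinom(k, surv, py[, "up"])
    rem <- surv - up_y
    dn_y <- stats::rbinom(k, rem, safe_cond_prob(py[, "down"], py[, "up"]))
    st_y <- rem - dn_y
    ys <- c(y + 1L, y, y - 1L)
    zs <- c(z, z, z)
    cs <- c(up_y, st_y, dn_y)
    keep <- cs > 0
    ys <- ys[keep]; zs <- zs[keep]; cs <- cs[keep]

    m <- length(cs)
    if (m > 0L) {
      pz <- mut_probs(zs, params)
      up_z <- stats::rbinom(m, cs, pz[, "up"])
      rem <- cs - up_z
      dn_z <- stats::rbinom(m, rem, safe_cond_prob(pz[, "down"], pz[, "up"]))
      st_z <- rem - dn_z
      oy <- c(ys, ys, ys)
      oz <- c(zs + 1L, zs, zs - 1L)
      oc <- c(up_z, st_z, dn_z)
      keep <- oc > 0
      oy <- oy[keep]; oz <- oz[keep]; oc <- oc[keep]
    } else {
      oy <- integer(0); oz <- integer(0); oc <- numeric(0)
    }
  } else {
    oy <- y; oz <- z; oc <- as.numeric(surv)
  }

  bkeep <- births > 0
  if (any(bkeep)) {
    oy <- c(oy, integer(sum(bkeep)))
    oz <- c(oz, z[bkeep])
    oc <- c(oc, as.numeric(births[bkeep]))
  }
  aggregate_classes(oy, oz, oc)
}

# P(down | not up) for the sequential-binomial multinomial draw, guarded
# against p_up = 1.
safe_cond_prob <- function(p_down, p_up) {
  ifelse(p_up < 1, p_down / (1 - p_up), 0)
}

#' Run the stochastic dynamics
#'
#' Iterates [step_stochastic()] for `mappings` steps. Extinction (`N = 0`)
#' is absorbing: the run stops there and records the mapping index. Given
#' the same `seed`, `params` and initial state, the trajectory is fully
#' reproducible.
#'
#' @param state Initial [metapop()] state (integer counts).
#' @param params An [hgt_params()] object.
#' @param mappings Number of ancestor-descendant mappings.
#' @param seed Integer seed for R's random number generator; `NULL` leaves
#'   the current stream untouched.
#' @param mutation Logical; allow random coevolutionary changes?
#' @return An [hgt_trajectory] data frame (see [run_summary()]).
#' @examples
#' tr <- run_stochastic(metapop(10, 10, 200), hgt_params(beta = 0.08),
#'                      mappings = 50, seed = 1)
#' run_summary(tr)$final_n
#' @export
run_stochastic <- function(state, params, mappings, seed = NULL,
                           mutation = TRUE) {
  stopifnot(mappings >= 0)
  if (!is.null(seed)) set.seed(seed)
  v <- state_vectors(state)
  if (any(v$count != floor(v$count))) {
    stop("stochastic dynamics require integer counts", call. = FALSE)
  }
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
  if (mappings > 0L && sum(v$count) > 0) {
    for (t in seq_len(mappings)) {
      v <- step_stochastic_core(v$y, v$z, v$count, params, mutation)
      rec(t, v)
      t_last <- t
      if (sum(v$count) == 0) {
        ext <- t
        break
      }
    }
  }
  new_trajectory(mat[seq_len(t_last + 1L), , drop = FALSE], params, ext,
                 new_metapop(v$y, v$z, v$count), seed = seed)
}

#' Sweep colonization opportunity with replicate stochastic runs
#'
#' Runs `replicates` stochastic simulations at each value of `beta`,
#' deriving one reproducible seed per (beta, replicate) pair from
#' `base_seed`, and collects terminal summaries.
#'
#' @param betas Numeric vector of baseline colonization rates to test.
#' @param replicates Replicate simulations per beta value (>= 1).
#' @param state Initial [metapop()] state shared by all runs.
#' @param params An [hgt_params()] object; its `beta` field is overridden by
#'   each grid value.
#' @param mappings Mappings per run.
#' @param base_seed Integer; per-run seeds are derived deterministically
#'   from it and logged in the output.
#' @param mutation Logical; allow random coevolutionary changes?
#' @return A data frame of class `hgt_sweep` with one row per run and
#'   columns `beta`, `replicate`, `seed`, `final_n`, `final_mean_y`,
#'   `final_mean_z`, `extinct`, `extinction_mapping`. Use [sweep_means()]
#'   for per-beta replicate means.
#' @examples
#' sw <- sweep_beta(c(0.06, 0.08), replicates = 2,
#'                  state = metapop(10, 10, 100), params = hgt_params(),
#'                  mappings = 20, base_seed = 1)
#' sweep_means(sw)
#' @export
sweep_beta <- function(betas, replicates, state, params, mappings,
                       base_seed = 1L, mutation = TRUE) {
  stopifnot(length(betas) >= 1L, all(betas >= 0), replicates >= 1L)
  rows <- vector("list", length(betas) * replicates)
  idx <- 0L
  for (bi in seq_along(betas)) {
    pb <- as_hgt_params(utils::modifyList(unclass(params),
                                          list(beta = betas[bi])))
    for (r in seq_len(replicates)) {
      seed <- derive_seed(base_seed, bi, r)
      tr <- run_stochastic(state, pb, mappings, seed = seed,
                           mutation = mutation)
      s <- run_summary(tr)
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        beta = betas[bi], replicate = r, seed = seed,
        final_n = s$final_n, final_mean_y = s$final_mean_y,
        final_mean_z = s$final_mean_z, extinct = s$extinct,
        extinction_mapping = s$extinction_mapping
      )
    }
  }
  structure(do.call(rbind, rows),
            params = params, base_seed = base_seed,
            class = c("hgt_sweep", "data.frame"))
}

#' Per-beta replicate means of a sweep
#'
#' Terminal mean character states are averaged over non-extinct replicates
#' (an empty metapopulation has no mean character state); `final_n` is
#' averaged over all replicates, extinct runs contributing 0.
#'
#' @param sweep The table returned by [sweep_beta()].
#' @return A data frame with one row per beta: `beta`, `n_replicates`,
#'   `n_extinct`, `mean_final_n`, `mean_final_y`, `mean_final_z`.
#' @export
sweep_means <- function(sweep) {
  stopifnot(is.data.frame(sweep), all(c("beta", "final_n") %in% names(sweep)))
  out <- lapply(split(sweep, sweep$beta), function(d) {
    data.frame(
      beta = d$beta[1L],
      n_replicates = nrow(d),
      n_extinct = sum(d$extinct),
      mean_final_n = mean(d$final_n),
      mean_final_y = mean(d$final_mean_y[!d$extinct]),
      mean_final_z = mean(d$final_mean_z[!d$extinct])
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$beta), , drop = FALSE]
}

# Deterministic per-run seed from (base seed, beta index, replicate index).
# Plain affine mixing kept exact in doubles and reduced below 2^31.
derive_seed <- function(base, beta_index, replicate) {
  as.integer((as.numeric(base) * 48271 + beta_index * 69621 +
                replicate * 16807) %% 2147483647)
}
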