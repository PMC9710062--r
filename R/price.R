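#' Price-equation decomposition of the one-mapping change in mean character
#'
#' For an ancestral metapopulation with class proportions `q_i`, persistence
#' fitness `w_p`, multiplication fitness `w_m` (density dependence evaluated
#' at the current total `N`) and mean fitness `w_bar = sum(q_i * w_i)`, the
#' change in mean connectivity over one mapping decomposes exactly as
#'
#' \deqn{\Delta\bar z = \frac{1}{\bar w}\sum_i q_i (w^m_i - \bar w) z_i
#'   + \frac{1}{\bar w}\sum_i q_i w^p_i (z_i + E(\Delta z_i))}
#'
#' The first sum is selection: `w_m` and `z` are negatively associated
#' through the fixation kernel `p_B(z) = exp(-z*s)`, so colonization
#' opportunity favors lower connectivity. The second sum is transmission:
#' the coevolutionary bias `E(dz) > 0` ratchets connectivity upward in
#' persisting populations.
#'
#' The indispensability analog uses the same ancestor-descendant
#' bookkeeping, with one difference: a population founded by horizontal
#' transfer starts at `y = 0` (a naive host has no accumulated
#' dependencies), so the multiplication offspring contribute zero character
#' value and the selection sum collapses to `-mean(y)`:
#' \deqn{\Delta\bar y = \left(\frac{1}{\bar w}\sum_i q_i w^m_i \cdot 0
#'   - \bar y\right) + \frac{1}{\bar w}\sum_i q_i w^p_i (y_i + E(\Delta y_i))}
#' This analog is an extension constructed here, not a printed equation of
#' the underlying model's original presentation of connectivity change.
#'
#' @param state A non-empty [metapop()] state.
#' @param params An [hgt_params()] object.
#' @param coordinate `"z"` (connectivity) or `"y"` (indispensability).
#' @param mutation Logical; include the transmission bias `E(dx)`? With
#'   `FALSE` the expected per-coordinate change is treated as 0, matching
#'   mutation-free runs of the dynamics.
#' @return An object of class `price_decomposition`: a list with
#'   `coordinate`, `mean_fitness`, `selection_term`, `transmission_term` and
#'   `total` (= selection + transmission = the exact one-mapping change in
#'   the mean).
#' @examples
#' st <- metapop(c(10, 10), c(10, 9), c(500, 500))
#' price_delta_z(st, hgt_params(beta = 0.08), mutation = FALSE)
#' @export
price_decomposition <- function(state, params, coordinate = c("z", "y"),
                                mutation = TRUE) {
  coordinate <- match.arg(coordinate)
  v <- state_vectors(state)
  n_tot <- sum(v$count)
  if (n_tot <= 0) {
    stop("price decomposition is undefined for an empty metapopulation",
         call. = FALSE)
  }
  q <- v$count / n_tot
  fc <- fitness_components(v$y, v$z, n_tot, params)
  w_bar <- sum(q * fc$w)
  x <- if (coordinate == "z") v$z else v$y
  ed <- if (mutation) expected_delta(x, params) else 0
  x_bar <- sum(q * x)
  # character value carried by multiplication offspring: z is inherited,
  # y is reset to 0 in the naive host
  x_off <- if (coordinate == "z") x else 0
  selection <- sum(q * fc$w_m * x_off) / w_bar - x_bar
  transmission <- sum(q * fc$w_p * (x + ed)) / w_bar
  structure(list(coordinate = coordinate,
                 mean_fitness = w_bar,
                 selection_term = selection,
                 transmission_term = transmission,
                 total = selection + transmission),
            class = "price_decomposition")
}

#' @rdname price_decomposition
#' @export
price_delta_z <- function(state, params, mutation = TRUE) {
  price_decomposition(state, params, coordinate = "z", mutation = mutation)
}

#' @rdname price_decomposition
#' @export
price_delta_y <- function(state, params, mutation = TRUE) {
  price_decomposition(state, params, coordinate = "y", mutation = mutation)
}

#' @export
print.price_decomposition <- function(x, ...) {
  cat(sprintf("Price decomposition of one-mapping change in mean %s\n",
              x$coordinate))
  cat(sprintf("  mean fitness      %.10g\n", x$mean_fitness))
  cat(sprintf("  selection term    %+.10g\n", x$selection_term))
  cat(sprintf("  transmission term %+.10g\n", x$transmission_term))
  cat(sprintf("  total change      %+.10g\n", x$total))
  invisible(x)
}

#' Brute-force one-mapping change in a mean character
#'
#' Independent check of [price_decomposition()]: builds the expected
#' descendant mass directly — persisting mass `n * w_p` per class at the
#' mean-shifted character `x + E(dx)`, plus multiplication mass `n * w_m`
#' at `(0, z)` — and returns descendant mean minus ancestral mean. No class
#' proportions or mean-fitness algebra are involved. The mean shift is used
#' rather than the full lattice redistribution because only the mean is
#' compared; the lattice step of [step_expected()] has the same mean, which
#' is asserted by the test suite.
#'
#' @inheritParams price_decomposition
#' @return The change in the count-weighted mean of the chosen coordinate.
#' @export
one_step_mean_change_oracle <- function(state, params,
                                        coordinate = c("z", "y"),
                                        mutation = TRUE) {
  coordinate <- match.arg(coordinate)
  v <- state_vectors(state)
  n_tot <- sum(v$count)
  if (n_tot <= 0) {
    stop("mean change is undefined for an empty metapopulation",
         call. = FALSE)
  }
  fc <- fitness_components(v$y, v$z, n_tot, params)
  x <- if (coordinate == "z") v$z else v$y
  ed <- if (mutation) expected_delta(x, params) else 0
  persist_mass <- v$count * fc$w_p
  persist_char <- x + ed
  birth_mass <- v$count * fc$w_m
  birth_char <- if (coordinate == "z") v$z else rep(0, length(v$y))
  new_mean <- sum(persist_mass * persist_char + birth_mass * birth_char) /
    sum(persist_mass + birth_mass)
  new_mean - sum(v$count * x) / n_tot
}

#' Write a Price decomposition as JSON
#'
#' @param pd A `price_decomposition` object.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_price_json <- function(pd, path) {
  stopifnot(inherits(pd, "price_decomposition"))
  jsonlite::write_json(unclass(pd), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
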