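#' Construct a metapopulation state
#'
#' A metapopulation state records how many populations of the transferable
#' gene occupy each character class `(y, z)`. Counts are real-valued for the
#' expected-value engine and integer for stochastic runs; all model kernels
#' depend only on `(y, z)` and the total `N`, so class-level aggregation is
#' exact. Duplicate classes are merged on construction and zero-count
#' classes dropped, neither of which changes any derived quantity.
#'
#' @param y,z Non-negative integer vectors of equal length: character
#'   classes present.
#' @param count Non-negative counts per class (recycled if length 1).
#' @return A data frame of class `metapop` with columns `y`, `z`, `count`,
#'   one row per occupied class, ordered by `(y, z)`.
#' @examples
#' m <- metapop(c(10, 0), c(10, 10), c(1000, 50))
#' metapop_n(m)
#' metapop_means(m)
#' @export
metapop <- function(y = integer(0), z = integer(0), count = numeric(0)) {
  if (length(count) == 1L && length(y) > 1L) count <- rep(count, length(y))
  if (length(y) != length(z) || length(y) != length(count)) {
    stop("y, z and count must have equal lengths", call. = FALSE)
  }
  if (length(y) > 0L) {
    check_char_values(y, "y")
    check_char_values(z, "z")
    if (!is.numeric(count) || anyNA(count) || any(count < 0)) {
      stop("count must be non-negative and free of NA", call. = FALSE)
    }
  }
  cls <- aggregate_classes(as.integer(y), as.integer(z), as.numeric(count))
  new_metapop(cls$y, cls$z, cls$count)
}

new_metapop <- function(y, z, count) {
  structure(
    data.frame(y = as.integer(y), z = as.integer(z), count = as.numeric(count)),
    class = c("metapop", "data.frame")
  )
}

#' @export
print.metapop <- function(x, ...) {
  cat(sprintf("Metapopulation: N = %g across %d character class(es)\n",
              metapop_n(x), nrow(x)))
  if (nrow(x) > 0L) print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Total number of populations in a metapopulation
#'
#' @param state A [metapop()] object.
#' @return The sum of class counts (0 for an empty state).
#' @export
metapop_n <- function(state) {
  sum(state$count)
}

#' Count-weighted mean character state
#'
#' @param state A [metapop()] object.
#' @return A named numeric vector `c(mean_y, mean_z)`; both `NA` when the
#'   metapopulation is empty (the mean of no populations is undefined).
#' @export
metapop_means <- function(state) {
  n <- metapop_n(state)
  if (n == 0) return(c(mean_y = NA_real_, mean_z = NA_real_))
  c(mean_y = sum(state$count * state$y) / n,
    mean_z = sum(state$count * state$z) / n)
}

# Merge duplicate (y, z) classes and drop empty ones. Encodes each class as
# a single numeric key (exact for y, z well below 2^26) so rowsum() can do
# the grouping.
aggregate_classes <- function(y, z, count) {
  keep <- count > 0
  if (!all(keep)) {
    y <- y[keep]; z <- z[keep]; count <- count[keep]
  }
  if (length(y) == 0L) {
    return(list(y = integer(0), z = integer(0), count = numeric(0)))
  }
  m <- max(z) + 1
  key <- as.numeric(y) * m + as.numeric(z)
  agg <- rowsum(count, key)
  k <- as.numeric(rownames(agg))
  list(y = as.integer(k %/% m), z = as.integer(k %% m),
       count = as.numeric(agg[, 1L]))
}

# Internal: pull the class vectors out of a metapop (or metapop-like data
# frame) for the simulation cores.
state_vectors <- function(state) {
  stopifnot(is.data.frame(state), all(c("y", "z", "count") %in% names(state)))
  list(y = as.integer(state$y), z = as.integer(state$z),
       count = as.numeric(state$count))
}
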