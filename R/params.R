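#' Model parameters for transferable-gene metapopulation dynamics
#'
#' Bundles the rate and shape constants of the model. A metapopulation is a
#' collection of populations of a transferable gene T, each carried by one
#' microbial host population and characterized by a state `(y, z)`:
#' indispensability `y` (dependencies the host has accumulated on T) and
#' connectivity `z` (the degree to which T's protein product requires its
#' current host's cellular milieu). Time advances in discrete
#' ancestor-descendant mappings, each standing in for billions of microbial
#' generations.
#'
#' @param p_plus Probability per mapping that one character coordinate
#'   increases by 1 through gene-host coevolution. Default `1e-3`.
#' @param p_minus Probability per mapping that one character coordinate
#'   decreases by 1 (a rare reversion). Default `1e-5`.
#' @param delta Probability per mapping that a host population is exposed to
#'   the neutral environmental state, in which T confers no advantage and
#'   can be lost. Default `0.01`.
#' @param s Exponential scale of the death and birth kernels: the
#'   probability of death by gene loss is `exp(-y*s)` and of fixation after
#'   transfer `exp(-z*s)`. Default `0.20`, an e-fold decrease at y or z = 5.
#' @param beta Baseline expected number of naive microbial populations one
#'   population of T enters by horizontal transfer per mapping, before
#'   density dependence. Default `0.06`.
#' @param n_max Carrying capacity of the metapopulation, in number of
#'   populations of T. Default `1e4`.
#'
#' @return An object of class `hgt_params`: a named list with the six
#'   fields above.
#' @examples
#' p <- hgt_params(beta = 0.08)
#' p_death(10, p)
#' @seealso [p_death()], [p_birth()], [beta_n()], [fitness_components()]
#' @export
hgt_params <- function(p_plus = 1e-3, p_minus = 1e-5, delta = 0.01,
                       s = 0.20, beta = 0.06, n_max = 1e4) {
  validate_hgt_params(list(p_plus = p_plus, p_minus = p_minus, delta = delta,
                           s = s, beta = beta, n_max = n_max))
}

#' Validate a list of model parameters
#'
#' Checks every constraint at once and reports all violations in a single
#' error message, so a config file with several bad values is diagnosed in
#' one pass.
#'
#' @param x A named list with fields `p_plus`, `p_minus`, `delta`, `s`,
#'   `beta`, `n_max`.
#' @return An `hgt_params` object.
#' @export
validate_hgt_params <- function(x) {
  required <- c("p_plus", "p_minus", "delta", "s", "beta", "n_max")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(x), required)
  if (length(extra) > 0L) {
    stop("unknown parameter field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  errs <- character(0)
  chk_num <- function(field) {
    v <- x[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      errs <<- c(errs, paste0(field, " must be a single finite number"))
      FALSE
    } else TRUE
  }
  for (f in required) chk_num(f)
  if (length(errs) == 0L) {
    if (x$p_plus < 0 || x$p_plus > 1) errs <- c(errs, "p_plus must be in [0, 1]")
    if (x$p_minus < 0 || x$p_minus > 1) errs <- c(errs, "p_minus must be in [0, 1]")
    if (x$p_plus + x$p_minus > 1) errs <- c(errs, "p_plus + p_minus must not exceed 1")
    if (x$delta < 0 || x$delta > 1) errs <- c(errs, "delta must be in [0, 1]")
    if (x$s <= 0) errs <- c(errs, "s must be > 0")
    if (x$beta < 0) errs <- c(errs, "beta must be >= 0")
    if (x$n_max < 1) errs <- c(errs, "n_max must be >= 1")
  }
  if (length(errs) > 0L) {
    stop("invalid model parameters:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  structure(x[required], class = "hgt_params")
}

#' @export
print.hgt_params <- function(x, ...) {
  cat("Transferable-gene model parameters\n")
  cat(sprintf("  p_plus  = %g   (P(+1) per coordinate per mapping)\n", x$p_plus))
  cat(sprintf("  p_minus = %g   (P(-1) per coordinate per mapping)\n", x$p_minus))
  cat(sprintf("  delta   = %g   (neutral-state exposure per mapping)\n", x$delta))
  cat(sprintf("  s       = %g   (kernel scale: exp(-y*s), exp(-z*s))\n", x$s))
  cat(sprintf("  beta    = %g   (baseline HGT opportunity per mapping)\n", x$beta))
  cat(sprintf("  n_max   = %g   (metapopulation carrying capacity)\n", x$n_max))
  invisible(x)
}

#' Read model parameters from a config file
#'
#' Accepts YAML (`.yml`/`.yaml`) or JSON (`.json`) with the flat keys
#' `p_plus`, `p_minus`, `delta`, `s`, `beta`, `n_max`. Keys not present fall
#' back to the defaults of [hgt_params()]; unknown keys are an error.
#'
#' @param path Path to the config file.
#' @return An `hgt_params` object.
#' @export
read_params <- function(path) {
  x <- read_structured(path)
  as_hgt_params(x)
}

#' Coerce a named list to model parameters, filling defaults
#'
#' @param x A named list of parameter overrides (possibly empty).
#' @return An `hgt_params` object.
#' @export
as_hgt_params <- function(x) {
  if (inherits(x, "hgt_params")) return(x)
  if (is.null(x)) x <- list()
  stopifnot(is.list(x))
  defaults <- unclass(hgt_params())
  extra <- setdiff(names(x), names(defaults))
  if (length(extra) > 0L) {
    stop("unknown parameter field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(x)] <- x
  validate_hgt_params(defaults)
}

#' Write model parameters to a config file
#'
#' @param params An `hgt_params` object.
#' @param path Output path; the extension (`.yml`, `.yaml` or `.json`)
#'   selects the format.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  params <- as_hgt_params(params)
  write_structured(unclass(params), path)
  invisible(path)
}

# Shared structured-file I/O (YAML or JSON by extension).
read_structured <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config format '.", ext, "' (use .yaml, .yml or .json)",
         call. = FALSE)
  )
  if (is.null(x)) x <- list()
  if (!is.list(x)) stop("config file must contain a mapping of keys to values",
                        call. = FALSE)
  x
}

write_structured <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yml = ,
    yaml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop("unsupported config format '.", ext, "' (use .yaml, .yml or .json)",
         call. = FALSE)
  )
  invisible(path)
}
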