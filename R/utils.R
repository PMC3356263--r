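# Internal helpers: classed conditions, unit conversions, seeding.

# Unit conventions: user-facing volumes in fL, areas in um^2, concentrations
# in mOsM / mM, times in s (incubation in min), temperatures in degC.
# Internal computation is CGS: cm, cm^2, cm^3, s, mol cm^-3.
FL_PER_CM3 <- 1e12      # 1 cm^3 = 1e12 fL
UM2_PER_CM2 <- 1e8      # 1 cm^2 = 1e8 um^2
MOSM_TO_MOL_CM3 <- 1e-6 # 1 mOsM = 1e-3 mol/L = 1e-6 mol/cm^3

aqp_stop <- function(msg, class = "aquaflow_input_error", call. = FALSE) {
  stop(structure(
    class = c(class, "aquaflow_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

fl_to_cm3 <- function(x) x / FL_PER_CM3
cm3_to_fl <- function(x) x * FL_PER_CM3
um2_to_cm2 <- function(x) x / UM2_PER_CM2
mosm_to_mol_cm3 <- function(x) x * MOSM_TO_MOL_CM3
celsius_to_kelvin <- function(x) x + 273.15

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_number <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is_number(x)) aqp_stop(sprintf("'%s' must be a single finite number", name))
  if (strict_lower && x <= lower)
    aqp_stop(sprintf("'%s' must be > %g (got %g)", name, lower, x))
  if (!strict_lower && x < lower)
    aqp_stop(sprintf("'%s' must be >= %g (got %g)", name, lower, x))
  if (x > upper)
    aqp_stop(sprintf("'%s' must be <= %g (got %g)", name, upper, x))
  invisible(x)
}

#' Derive a child random seed from a base seed and index path
#'
#' Deterministic integer mixing rule (multiplicative congruential scramble in
#' the spirit of splitmix) used to give every condition and replicate of a
#' synthetic experiment its own reproducible RNG stream. The rule is
#' `x <- base; for each index k: x <- (x*69069 + (k+1)*2654435761) mod (2^31-1);
#' x <- (x*69069 + 1) mod (2^31-1)`, all in exact double arithmetic.
#'
#' @param seed integer base seed.
#' @param ... integer indices (e.g. condition index, replicate index).
#' @return a single integer in `[0, 2^31-2]`.
#' @export
#' @examples
#' derive_seed(1, 2, 3)
derive_seed <- function(seed, ...) {
  x <- as.double(seed) %% 2147483647
  for (k in c(...)) {
    x <- (x * 69069 + (as.double(k) + 1) * 2654435761) %% 2147483647
    x <- (x * 69069 + 1) %% 2147483647
  }
  as.integer(x)
}

# Evaluate `code` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Centered moving average; width coerced to odd, ends padded by edge values.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L || length(x) < width) return(x)
  half <- (width - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2L))[
    (half + 1L):(half + length(x))]
}

# Robust noise estimate of a (possibly trending) signal: MAD of the residual
# from a 5-sample moving average (variance (1 - 1/5) sigma^2), so smooth
# deterministic structure does not inflate the estimate.
estimate_noise <- function(x) {
  if (length(x) < 8L) {
    if (length(x) < 3L) return(0)
    return(stats::sd(diff(x)) / sqrt(2))
  }
  stats::mad(x - moving_average(x, 5L)) / sqrt(0.8)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Levenberg-Marquardt least squares via minpack.lm::nls.lm with asymptotic
# standard errors (residual variance times the inverse of J'J). Used instead
# of the nls-model wrappers, which reject exact (zero-residual) fits.
# Returns NULL on failure.
nls_lm_fit <- function(resid_fn, start, lower = NULL, maxiter = 400) {
  out <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(out) || out$info == 0) return(NULL)
  par <- unlist(out$par)
  n <- length(out$fvec)
  rss <- out$deviance
  se <- setNames(rep(NA_real_, length(par)), names(par))
  vars <- tryCatch(diag(chol2inv(chol(out$hessian))) *
                     rss / max(n - length(par), 1),
                   error = function(e) NULL)
  if (!is.null(vars)) se <- setNames(sqrt(pmax(vars, 0)), names(par))
  list(par = par, se = se, rss = rss, n = n, info = out$info)
}
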