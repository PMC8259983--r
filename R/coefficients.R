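#' Growth-rate-dependent stoichiometric coefficients
#'
#' ME-model coupling constraints make stoichiometric coefficients functions of
#' the growth rate \eqn{\mu}. Every coupling form used here is a rational
#' function representable as
#' \deqn{a + b\mu + c/\mu + d\mu^2,}
#' where the \eqn{\mu^2} term only arises in the synthetase coupling
#' \eqn{(1+\mu/k_{eff,tRNA})(\mu/k_{eff,charging})} and the \eqn{1/\mu} term
#' only in the mRNA degradation coupling. A coefficient is stored as a
#' length-4 numeric vector `c(const, mu, inv_mu, mu2)`.
#'
#' @param const,mu,inv_mu,mu2 numeric scalars; the four polynomial components.
#' @return an object of class `mu_coef` (numeric length 4).
#' @examples
#' co <- mu_coef(const = 1, mu = 0.5)
#' eval_mu_coef(co, mu = 2) # 2
#' @export
mu_coef <- function(const = 0, mu = 0, inv_mu = 0, mu2 = 0) {
  x <- c(const = as.numeric(const), mu = as.numeric(mu),
         inv_mu = as.numeric(inv_mu), mu2 = as.numeric(mu2))
  if (any(!is.finite(x))) stop("mu_coef components must be finite")
  structure(x, class = "mu_coef")
}

#' Coerce a number or list to a `mu_coef`
#'
#' Plain numbers become constant coefficients; lists may carry any of the
#' fields `const`, `mu`, `inv_mu`, `mu2` (the JSON serialization form).
#' @param x numeric scalar, `mu_coef`, or named list.
#' @return a `mu_coef`.
#' @export
as_mu_coef <- function(x) {
  if (inherits(x, "mu_coef")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(mu_coef(const = x))
  if (is.numeric(x) && length(x) == 4L) {
    return(mu_coef(x[[1]], x[[2]], x[[3]], x[[4]]))
  }
  if (is.list(x)) {
    return(mu_coef(const = x$const %||% 0, mu = x$mu %||% 0,
                   inv_mu = x$inv_mu %||% 0, mu2 = x$mu2 %||% 0))
  }
  stop("cannot interpret object as a mu-dependent coefficient")
}

#' Evaluate a coefficient at a growth rate
#'
#' @param coef a `mu_coef` (or anything `as_mu_coef()` accepts).
#' @param mu growth rate in 1/h; must be > 0 when the coefficient carries an
#'   active `inv_mu` component.
#' @return numeric scalar.
#' @export
eval_mu_coef <- function(coef, mu) {
  co <- as_mu_coef(coef)
  if (mu == 0 && co[["inv_mu"]] != 0) {
    stop("singularity: coefficient has a 1/mu term and mu = 0")
  }
  inv <- if (co[["inv_mu"]] == 0) 0 else co[["inv_mu"]] / mu
  co[["const"]] + co[["mu"]] * mu + inv + co[["mu2"]] * mu * mu
}

#' @export
print.mu_coef <- function(x, ...) {
  parts <- character(0)
  if (x[["const"]] != 0 || all(x == 0)) parts <- format(x[["const"]])
  if (x[["mu"]] != 0) parts <- c(parts, paste0(format(x[["mu"]]), "*mu"))
  if (x[["inv_mu"]] != 0) parts <- c(parts, paste0(format(x[["inv_mu"]]), "/mu"))
  if (x[["mu2"]] != 0) parts <- c(parts, paste0(format(x[["mu2"]]), "*mu^2"))
  cat("<mu_coef>", paste(parts, collapse = " + "), "\n")
  invisible(x)
}

# scale a mu_coef by a plain number
scale_mu_coef <- function(coef, s) {
  co <- as_mu_coef(coef)
  mu_coef(co[["const"]] * s, co[["mu"]] * s, co[["inv_mu"]] * s, co[["mu2"]] * s)
}

add_mu_coef <- function(a, b) {
  ca <- as_mu_coef(a); cb <- as_mu_coef(b)
  mu_coef(ca[["const"]] + cb[["const"]], ca[["mu"]] + cb[["mu"]],
          ca[["inv_mu"]] + cb[["inv_mu"]], ca[["mu2"]] + cb[["mu2"]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
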