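#' Check feasibility of an ME model at a fixed growth rate
#'
#' Builds the numeric LP at `mu` and reports whether
#' \eqn{\{S(\mu)v=0,\ l \le v \le u,\ v_{dilution}=\mu\}} admits a solution.
#' Any valid ME model is feasible at \eqn{\mu = 0} (the zero flux vector);
#' rows carrying \eqn{1/\mu} terms are handled there through their exact
#' limiting form, which forces the coupled translation fluxes to zero.
#'
#' @param model an [me_model()].
#' @param mu growth rate, 1/h (>= 0).
#' @return list with elements `feasible` (logical) and `fluxes` (named
#'   minimum-norm flux vector, or `NULL` when infeasible).
#' @export
feasible_at_mu <- function(model, mu) {
  if (mu < 0) stop("mu must be >= 0")
  num <- assemble_numeric(model, mu, limit_zero = TRUE)
  res <- tryCatch(
    solve_min_norm(num$S, num$lb, num$ub),
    error = function(e) {
      stop("solver error at mu = ", format(mu), ": ", conditionMessage(e))
    })
  list(feasible = res$feasible, fluxes = res$fluxes)
}

new_me_solution <- function(mu_opt, fluxes, status, iterations, bracket) {
  structure(list(mu_opt = mu_opt, fluxes = fluxes, status = status,
                 iterations = iterations, bracket = bracket),
            class = "me_solution")
}

#' @export
print.me_solution <- function(x, ...) {
  cat("<me_solution> mu* = ", format(x$mu_opt, digits = 8),
      " 1/h [", x$status, "], ", x$iterations, " feasibility solves, ",
      "bracket width ", format(diff(x$bracket), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Maximize growth rate by bisection
#'
#' The ME optimization problem \eqn{\max_{v,\mu}\ \mu} is nonlinear in
#' \eqn{\mu} through the coupling coefficients, so it is solved as a binary
#' search over LP feasibility: a bracket (maximum known feasible \eqn{\mu},
#' minimum known infeasible \eqn{\mu}) is halved until its width falls below
#' `tol`, and the flux vector at the last feasible point is returned.
#' Feasibility of these models is monotone in \eqn{\mu} (growing faster only
#' tightens every coupling), which is what makes bisection exact.
#'
#' @param model an [me_model()].
#' @param mu_lo lower bracket start (default 0; any valid model is feasible
#'   there, so it is trusted as feasible without a solve when it verifies).
#' @param mu_hi upper bracket start, 1/h; must be infeasible. Default 4,
#'   comfortably above the growth rates toy networks support.
#' @param tol bracket-width termination tolerance, 1/h.
#' @return an `me_solution` with fields `mu_opt`, `fluxes`, `status`
#'   (`"optimal"` or `"infeasible_at_zero"` when the lower bracket itself
#'   fails), `iterations` (number of feasibility solves) and `bracket`
#'   (last feasible, first infeasible).
#' @export
maximize_growth <- function(model, mu_lo = 0, mu_hi = 4, tol = 1e-6) {
  if (!(mu_hi > mu_lo) || mu_lo < 0) stop("need mu_hi > mu_lo >= 0")
  if (tol <= 0) stop("tol must be > 0")
  iters <- 0L
  hi <- feasible_at_mu(model, mu_hi); iters <- iters + 1L
  if (hi$feasible) {
    stop("model is feasible at mu_hi = ", mu_hi,
         "; increase mu_hi to bracket the optimum")
  }
  lo <- feasible_at_mu(model, mu_lo); iters <- iters + 1L
  if (!lo$feasible) {
    return(new_me_solution(NA_real_, NULL, "infeasible_at_zero", iters,
                           c(NA_real_, mu_lo)))
  }
  best_mu <- mu_lo; best_flux <- lo$fluxes
  lo_mu <- mu_lo; hi_mu <- mu_hi
  while (hi_mu - lo_mu > tol) {
    mid <- (lo_mu + hi_mu) / 2
    f <- feasible_at_mu(model, mid); iters <- iters + 1L
    if (f$feasible) {
      lo_mu <- mid; best_mu <- mid; best_flux <- f$fluxes
    } else {
      hi_mu <- mid
    }
  }
  new_me_solution(best_mu, best_flux, "optimal", iters, c(lo_mu, hi_mu))
}

#' Apply a media condition's exchange bounds to a model
#'
#' @param model an [me_model()].
#' @param media a [media_condition()].
#' @return the model with the media's exchange bounds in place.
#' @export
apply_media <- function(model, media) {
  for (ex in names(media$exchange_bounds)) {
    if (!ex %in% names(model$reactions)) {
      stop("media names unknown exchange reaction: ", ex)
    }
    if (model$reactions[[ex]]$klass != "exchange") {
      stop("media bound target ", ex, " is not an exchange reaction")
    }
    b <- media$exchange_bounds[[ex]]
    model <- set_bounds(model, ex, lb = b[[1]], ub = b[[2]])
  }
  model
}

#' Solve one media condition
#'
#' Sets the condition's exchange bounds (overriding stored bounds), then
#' maximizes growth. The input model is untouched by value semantics, so the
#' caller's model is restored automatically after the solve.
#'
#' @param model an [me_model()].
#' @param media a [media_condition()].
#' @param tol bisection tolerance, 1/h.
#' @param mu_hi upper bracket for the bisection.
#' @return an `me_solution`.
#' @export
solve_condition <- function(model, media, tol = 1e-6, mu_hi = 4) {
  maximize_growth(apply_media(model, media), mu_hi = mu_hi, tol = tol)
}
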