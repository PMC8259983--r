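#' Numeric LP assembly and feasibility backend
#'
#' At a fixed growth rate \eqn{\mu} an ME model is an ordinary linear
#' feasibility problem \eqn{\{S(\mu)v = 0,\ l(\mu) \le v \le u(\mu)\}} with
#' the biomass dilution flux pinned to \eqn{\mu}. Feasibility (and a
#' deterministic flux vector) is obtained from the strictly convex quadratic
#' program \eqn{\min \|v\|^2} subject to those constraints: the program is
#' solvable exactly when the LP is feasible, and its unique minimizer is the
#' minimum-norm flux distribution, which makes reported fluxes reproducible
#' among alternate LP optima. Linearly dependent (homogeneous) equality rows
#' — the coupling rows are deliberately redundant with the inflated mass
#' balances — are removed by a pivoted QR factorization before the solve.
#'
#' @name lp_backend
NULL

# Assemble S(mu), lb(mu), ub(mu). When mu == 0 and `limit_zero` is TRUE,
# any row receiving a coefficient with an active 1/mu term is replaced by
# its mu-rescaled limit (entries become their inv_mu components; all purely
# polynomial entries of that row vanish), which is the exact limiting
# constraint of the row as mu -> 0.
assemble_numeric <- function(model, mu, limit_zero = FALSE) {
  rids <- names(model$reactions)
  n <- length(rids)
  ri <- si <- integer(0); cc <- list()
  for (j in seq_len(n)) {
    st <- model$reactions[[j]]$stoich
    if (length(st) == 0L) next
    si <- c(si, names(st))
    ri <- c(ri, rep.int(j, length(st)))
    cc <- c(cc, unname(st))
  }
  rows <- unique(si)
  comp <- do.call(rbind, lapply(cc, unclass))   # entries x 4
  S <- matrix(0, length(rows), n, dimnames = list(rows, rids))
  rix <- match(si, rows)
  if (mu == 0) {
    sing <- comp[, "inv_mu"] != 0
    if (any(sing) && !limit_zero) {
      bad <- unique(rids[ri[sing]])
      stop("singularity: 1/mu coefficient active at mu = 0 in reaction(s) ",
           paste(bad, collapse = ", "))
    }
    vals <- comp[, "const"]
    if (any(sing)) {
      lim_rows <- unique(rix[sing])
      in_lim <- rix %in% lim_rows
      vals[in_lim] <- comp[in_lim, "inv_mu"]
    }
  } else {
    vals <- comp[, "const"] + comp[, "mu"] * mu + comp[, "inv_mu"] / mu +
      comp[, "mu2"] * mu * mu
  }
  if (any(!is.finite(vals))) {
    bad <- unique(rids[ri[!is.finite(vals)]])
    stop("non-finite coefficient at mu = ", mu, " in reaction(s) ",
         paste(bad, collapse = ", "))
  }
  S[cbind(rix, ri)] <- vals
  bound_at <- function(b) {
    if (inherits(b, "mu_coef") || is.list(b)) eval_mu_coef(b, mu) else b
  }
  lb <- vapply(model$reactions, function(r) bound_at(r$lb), 0)
  ub <- vapply(model$reactions, function(r) bound_at(r$ub), 0)
  # biomass dilution pinned to mu; a stored finite upper bound below mu
  # (an explicit growth cap) leaves the instance infeasible, as intended
  dil <- model$biomass_dilution_id
  ub[dil] <- min(ub[dil], mu)
  lb[dil] <- mu
  list(S = S, lb = lb, ub = ub)
}

#' Evaluate an ME model into a numeric LP at a growth rate
#'
#' Replaces every symbolic coefficient and bound by its numeric value at
#' `mu` and pins both biomass-dilution bounds to `mu`. At `mu = 0` an error
#' is raised if any \eqn{1/\mu} coefficient is active (the mRNA degradation
#' coupling); [feasible_at_mu()] handles that case via the exact limiting
#' system instead.
#'
#' @param model an [me_model()].
#' @param mu growth rate, 1/h (>= 0).
#' @return list with the stoichiometric matrix `S` (species x reactions,
#'   only species that occur in some reaction), and bound vectors `lb`, `ub`.
#' @export
evaluate_at_mu <- function(model, mu) {
  if (mu < 0) stop("mu must be >= 0")
  assemble_numeric(model, mu, limit_zero = FALSE)
}

# Minimum-norm feasibility solve; returns list(feasible, fluxes, residual)
# or propagates a solver error for genuinely numerical failures.
#
# ME matrices are notoriously ill-scaled (fluxes span mmol-scale metabolism
# and nmol-scale machinery formation), so the solve proceeds in three
# numerically defensive steps:
#   1. geometric-mean column equilibration of S (with the bounds rescaled
#      accordingly);
#   2. analytic elimination of the equality block (S rows plus fixed-bound
#      rows): a pivoted QR of its transpose yields an independent row
#      subset, a particular solution x0, a consistency check for the
#      dropped dependent rows, and an orthonormal null-space basis N;
#   3. the small reduced program min ||x0 + N z||^2 s.t. bounds, solved by
#      the dual active-set QP with unit-normalized constraint rows.
# Degenerate active sets can still make the QP declare a feasible system
# inconsistent; in that case the bounds are relaxed by a ladder of tiny
# slacks and the recovered point is accepted only if its true bound
# violation stays within feas_tol. Every verdict is verified against the
# original constraints, never taken from the solver's exit status alone.
solve_min_norm <- function(S, lb, ub, feas_tol = 1e-7) {
  n <- ncol(S)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(feasible = FALSE, fluxes = NULL, residual = NA_real_))
  }
  S0 <- S; lb0 <- lb; ub0 <- ub
  # --- column equilibration ---------------------------------------------
  cs <- rep(1, n)
  A <- S
  if (nrow(A)) {
    for (pass in 1:2) {
      rn <- sqrt(rowSums(A * A)); rn[rn == 0] <- 1
      A <- A / rn
      cmax <- apply(abs(A), 2, max)
      cmin <- apply(abs(A), 2, function(x) {
        if (any(x > 0)) min(x[x > 0]) else 1
      })
      s <- 1 / sqrt(cmax * cmin)
      s[!is.finite(s) | s <= 0] <- 1
      A <- sweep(A, 2, s, `*`)
      cs <- cs * s
    }
  }
  S <- sweep(S, 2, cs, `*`)
  lb <- lb / cs; ub <- ub / cs
  infeasible <- list(feasible = FALSE, fluxes = NULL, residual = NA_real_)
  rn0 <- if (nrow(S0)) sqrt(rowSums(S0 * S0)) else numeric(0)
  rn0[rn0 == 0] <- 1
  # every acceptance decision is made in ORIGINAL units: the equilibration
  # scales are invisible to the caller and must not soften any constraint
  finish <- function(v) {
    # no bound clipping — clipping a component with a large equilibration
    # scale would break the (exactly satisfied) equality rows
    v <- v * cs
    scale <- max(1, max(abs(v)))
    if (max(pmax(lb0 - v, 0), pmax(v - ub0, 0), 0) > feas_tol * scale) {
      return(infeasible)
    }
    names(v) <- colnames(S0)
    resid <- if (nrow(S0)) max(abs(S0 %*% v) / rn0) else 0
    # guard against rank-tolerance row drops: the full equality system must
    # hold at the returned point, not just the retained rows
    if (resid > feas_tol * scale) return(infeasible)
    list(feasible = TRUE, fluxes = v, residual = resid)
  }
  # --- equality block ----------------------------------------------------
  fixed <- which(ub - lb <= 0)
  A <- S
  b <- rep(0, nrow(S))
  if (length(fixed)) {
    E <- matrix(0, length(fixed), n)
    E[cbind(seq_along(fixed), fixed)] <- 1
    A <- rbind(A, E)
    b <- c(b, lb[fixed])
  }
  rn <- sqrt(rowSums(A * A))
  keep <- rn > 0
  if (any(abs(b[!keep]) > feas_tol)) return(infeasible)
  A <- A[keep, , drop = FALSE] / rn[keep]
  b <- b[keep] / rn[keep]
  if (nrow(A) == 0L) {
    return(finish(pmin(pmax(rep(0, n), lb), ub)))
  }
  # deliberate redundancies (coupling rows vs inflated balances) are exact,
  # so a tight rank tolerance separates them from genuinely distinct but
  # nearly parallel constraints
  qa <- qr(t(A), tol = 1e-10)
  r <- qa$rank
  QQ <- qr.Q(qa, complete = TRUE)
  R1 <- qr.R(qa)[seq_len(r), seq_len(r), drop = FALSE]
  b1 <- b[qa$pivot[seq_len(r)]]
  # least-norm particular solution from the factors: A1 = t(R1) t(Q1)
  y1 <- tryCatch(
    backsolve(R1, b1, transpose = TRUE),
    error = function(e) stop("LP backend failure: ", conditionMessage(e)))
  x0 <- as.vector(QQ[, seq_len(r), drop = FALSE] %*% y1)
  # consistency of the dropped (dependent) equality rows
  if (max(abs(A %*% x0 - b)) > feas_tol) return(infeasible)
  if (r == n) return(finish(x0))
  # --- reduced bounded min-norm program ---------------------------------
  N <- QQ[, (r + 1L):n, drop = FALSE]
  k <- ncol(N)
  nrN <- sqrt(rowSums(N * N))
  tiny <- nrN < 1e-9      # variables pinned by the equalities alone
  idx <- seq_len(n)
  il <- which(is.finite(lb) & !(idx %in% fixed) & !tiny)
  iu <- which(is.finite(ub) & !(idx %in% fixed) & !tiny)
  Amat <- cbind(t(N[il, , drop = FALSE] / nrN[il]),
                -t(N[iu, , drop = FALSE] / nrN[iu]))
  bvec <- c((lb[il] - x0[il]) / nrN[il], (x0[iu] - ub[iu]) / nrN[iu])
  dvec <- -as.vector(crossprod(N, x0))
  # Degenerate active sets can make the QP declare a feasible system
  # inconsistent. The escape ladder relaxes every bound by delta in
  # ORIGINAL units (deterministically jittered to break ties), so the
  # accepted point violates no original bound by more than delta, far
  # inside feas_tol; each verdict is still verified by finish().
  conv <- c(1 / (cs[il] * nrN[il]), 1 / (cs[iu] * nrN[iu]))
  jitter <- 1 + 0.5 * sin(seq_along(bvec))
  for (delta in c(0, 1e-12, 1e-11, 1e-10, 1e-9)) {
    res <- tryCatch(
      quadprog::solve.QP(diag(k), dvec, Amat, bvec - delta * conv * jitter),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (grepl("inconsistent", conditionMessage(res))) next
      stop("LP backend failure: ", conditionMessage(res))
    }
    out <- finish(x0 + as.vector(N %*% res$solution))
    if (out$feasible) return(out)
  }
  infeasible
}
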