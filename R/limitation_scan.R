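#' Render a model auxotrophic for a metabolite
#'
#' Sets the listed knockout reactions to zero flux and makes sure an uptake
#' exchange for the metabolite exists (adding a closed one when missing).
#' Auxotrophy is verified: with the exchange closed the model must not grow
#' above `min_growth`, otherwise the knockout list left the model
#' prototrophic and an error is raised.
#'
#' @param model an [me_model()].
#' @param metabolite_id the metabolite the strain should depend on.
#' @param knockout_reactions character vector of reaction ids to disable;
#'   must be non-empty.
#' @param min_growth residual growth above which auxotrophy is considered
#'   not achieved. The default sits above the coupling-resolution floor:
#'   for a knocked-out coenzyme the forced-synthesis flux
#'   \eqn{\mu\,u/k_{activity}} is perturbative, so residual growth is
#'   suppressed to a small value (well under 1% of prototrophic growth)
#'   rather than exactly zero in double precision.
#' @param tol bisection tolerance for the verification solve.
#' @return the modified model, with the exchange still closed and an
#'   `auxotroph` record (`metabolite_id`, `exchange_id`,
#'   `knockout_reactions`) attached.
#' @export
make_auxotroph <- function(model, metabolite_id, knockout_reactions,
                           min_growth = 0.05, tol = 1e-4) {
  if (length(knockout_reactions) == 0L) {
    stop("knockout list is empty; auxotrophy cannot be achieved")
  }
  missing <- setdiff(knockout_reactions, names(model$reactions))
  if (length(missing)) {
    stop("unknown knockout reaction(s): ", paste(missing, collapse = ", "))
  }
  if (!metabolite_id %in% names(model$species)) {
    stop("unknown metabolite: ", metabolite_id)
  }
  for (rid in knockout_reactions) {
    model <- set_bounds(model, rid, lb = 0, ub = 0)
  }
  ex <- NULL
  for (r in model$reactions) {
    if (r$klass == "exchange" && metabolite_id %in% names(r$stoich)) {
      ex <- r$id
      break
    }
  }
  if (is.null(ex)) {
    ex <- paste0("EX_", metabolite_id)
    st <- list(); st[[metabolite_id]] <- -1
    model$reactions[[ex]] <- me_reaction(ex, klass = "exchange",
                                         stoich = st, lb = 0, ub = 1000)
  } else {
    model <- set_bounds(model, ex, lb = 0)   # start closed
  }
  check <- maximize_growth(model, tol = tol)
  if (!is.na(check$mu_opt) && check$mu_opt > min_growth) {
    stop("auxotrophy not achieved: mu* = ", format(check$mu_opt),
         " with the ", metabolite_id, " exchange closed")
  }
  model$auxotroph <- list(metabolite_id = metabolite_id, exchange_id = ex,
                          knockout_reactions = knockout_reactions)
  model
}

#' Nutrient-limitation profile of an auxotroph
#'
#' First the auxotroph is optimized with unconstrained uptake of its
#' essential metabolite and the uptake flux at maximum growth is recorded as
#' `optimal_uptake`. The uptake is then capped at each fraction of that
#' value (an upper bound on the uptake magnitude: the model may always take
#' less) and growth is re-maximized, recording the growth rate, the flux
#' vector and the subsystem protein allocation.
#'
#' @param aux_model a model from [make_auxotroph()].
#' @param fractions decreasing fractions of the optimal uptake (default
#'   1.00 to 0.05 in steps of 0.05, 20 points).
#' @param tol bisection tolerance.
#' @param mu_hi bisection upper bracket.
#' @return a `limitation_profile`: list with `metabolite_id`,
#'   `optimal_uptake`, `fractions`, `growth` (named numeric), `allocation`
#'   (list: fraction -> named subsystem mass-fraction vector), `fluxes`
#'   (list: fraction -> named flux vector).
#' @export
limitation_profile <- function(aux_model,
                               fractions = seq(1, 0.05, by = -0.05),
                               tol = 1e-6, mu_hi = 4) {
  aux <- aux_model$auxotroph
  if (is.null(aux)) stop("model carries no auxotroph record; run make_auxotroph first")
  ex <- aux$exchange_id
  free <- set_bounds(aux_model, ex, lb = -1000)
  sol0 <- maximize_growth(free, mu_hi = mu_hi, tol = tol)
  uptake <- -flux_of(sol0, ex)
  if (!is.finite(uptake) || uptake <= 0) {
    stop("degenerate profile: optimal uptake of ", aux$metabolite_id,
         " is zero")
  }
  keys <- fraction_keys(fractions)
  growth <- stats::setNames(numeric(length(fractions)), keys)
  alloc <- list(); fluxes <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[[i]]
    m <- set_bounds(aux_model, ex, lb = -f * uptake)
    sol <- maximize_growth(m, mu_hi = mu_hi, tol = tol)
    key <- keys[[i]]
    growth[[key]] <- if (is.na(sol$mu_opt)) 0 else sol$mu_opt
    fluxes[[key]] <- sol$fluxes
    alloc[[key]] <- if (growth[[key]] > 0) {
      protein_allocation(sol, aux_model)
    } else NULL
  }
  structure(list(metabolite_id = aux$metabolite_id,
                 optimal_uptake = uptake, fractions = fractions,
                 growth = growth, allocation = alloc, fluxes = fluxes),
            class = "limitation_profile")
}

#' @export
print.limitation_profile <- function(x, ...) {
  cat("<limitation_profile> ", x$metabolite_id, ": optimal uptake ",
      format(x$optimal_uptake, digits = 6), " mmol/gDW/h, growth ",
      format(max(x$growth), digits = 4), " -> ",
      format(min(x$growth), digits = 4), " 1/h over ",
      length(x$fractions), " availability points\n", sep = "")
  invisible(x)
}

fraction_keys <- function(fractions) {
  vapply(fractions, function(f) as.character(signif(f, 6)), "")
}

#' Subsystem protein allocation of a solution
#'
#' The steady-state mass of each complex is its formation flux times the
#' grams of protein it deposits per unit flux, divided by the growth rate
#' (dilution). A complex's mass is assigned to the subsystems of the
#' reactions it catalyzes, split proportionally to its usage fluxes when it
#' serves several subsystems; complexes that catalyze nothing (machinery,
#' structural protein) fall back to their formation reaction's subsystem.
#'
#' @param solution an `me_solution` with `mu_opt > 0`.
#' @param model the model it was computed on.
#' @param normalize return mass fractions summing to 1 (default); otherwise
#'   absolute protein mass per subsystem in g/gDW.
#' @param clamp formation fluxes at or below this are ignored.
#' @return named numeric vector, subsystem to protein mass (fraction).
#' @export
protein_allocation <- function(solution, model, normalize = TRUE,
                               clamp = 1e-12) {
  mu <- solution$mu_opt
  if (is.na(mu) || mu <= 0) stop("allocation undefined at mu = 0")
  pb <- protein_pool_id(model)
  out <- numeric(0)
  add <- function(acc, subsystem, mass) {
    s <- subsystem %||% "unassigned"
    acc[s] <- (if (s %in% names(acc)) acc[[s]] else 0) + mass
    acc
  }
  for (r in model$reactions) {
    if (r$klass != "complex_formation") next
    v <- flux_of(solution, r$id)
    if (v <= clamp) next
    w <- r$stoich[[pb]]
    if (is.null(w)) next
    mass <- v * as_mu_coef(w)[["const"]] / mu
    cat_rxns <- Filter(function(x) identical(x$catalyst, r$complex),
                       model$reactions)
    if (r$complex %in% c(model$ribosome_id, model$rnap_id) ||
        length(cat_rxns) == 0L) {
      out <- add(out, r$subsystem, mass)
      next
    }
    usage <- vapply(cat_rxns, function(x) abs(flux_of(solution, x$id)), 0)
    if (sum(usage) <= clamp) {
      out <- add(out, r$subsystem, mass)
      next
    }
    w_us <- usage / sum(usage)
    for (i in seq_along(cat_rxns)) {
      out <- add(out, cat_rxns[[i]]$subsystem, mass * w_us[[i]])
    }
  }
  if (normalize && sum(out) > 0) out <- out / sum(out)
  out[order(names(out))]
}

protein_pool_id <- function(model) {
  summ <- model$reactions[[model$protein_biomass_summary_id]]
  for (sid in names(summ$stoich)) {
    if (as_mu_coef(summ$stoich[[sid]])[["const"]] < 0 &&
        model$species[[sid]]$role == "biomass_pool") {
      return(sid)
    }
  }
  stop("protein biomass pool species not found in summary reaction")
}

#' Rank and group flux responses along a limitation profile
#'
#' For every reaction the growth-normalized flux (\eqn{v/\mu}) is tabulated
#' across availability fractions and divided by its series maximum.
#' Reactions whose normalized series coincide within `group_tol` — perfectly
#' correlated fluxes, e.g. consecutive steps of a linear pathway — are
#' merged into one row carrying a member count. Rows are ranked by the
#' standard deviation of the normalized series and the `top_n` most variable
#' are returned; constant and all-zero series never make the cut.
#'
#' @param profile a [limitation_profile()] with at least 3 fractions.
#' @param top_n number of rows to return.
#' @param group_tol series-identity tolerance for grouping.
#' @param min_flux reactions whose growth-normalized flux never exceeds
#'   this are excluded before normalization (otherwise solver noise on
#'   closed reactions would normalize to spurious full-scale series).
#' @return data.frame with columns `reaction_id` (representative),
#'   `n_members`, `members` (comma-separated), `sd`, and one `f_<fraction>`
#'   column per availability fraction.
#' @export
flux_response_summary <- function(profile, top_n = 15, group_tol = 1e-6,
                                  min_flux = 1e-6) {
  if (length(profile$fractions) < 3L) {
    stop("profile needs at least 3 availability fractions")
  }
  keys <- fraction_keys(profile$fractions)
  rids <- names(profile$fluxes[[keys[[1]]]])
  series <- sapply(keys, function(k) {
    mu <- profile$growth[[k]]
    v <- profile$fluxes[[k]][rids]
    if (mu > 0) v / mu else rep(NA_real_, length(rids))
  })
  rownames(series) <- rids
  series <- series[stats::complete.cases(series), , drop = FALSE]
  mx <- apply(abs(series), 1, max)
  series <- series[mx > min_flux, , drop = FALSE] / mx[mx > min_flux]
  sds <- apply(series, 1, stats::sd)
  series <- series[sds > 0, , drop = FALSE]
  sds <- sds[sds > 0]
  ord <- order(-sds)
  series <- series[ord, , drop = FALSE]; sds <- sds[ord]
  groups <- list()
  for (i in seq_len(nrow(series))) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      rep_row <- series[groups[[g]][[1]], ]
      if (max(abs(series[i, ] - rep_row)) <= group_tol) {
        groups[[g]] <- c(groups[[g]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- i
  }
  groups <- groups[seq_len(min(top_n, length(groups)))]
  rows <- lapply(groups, function(g) {
    ids <- rownames(series)[unlist(g)]
    cbind(data.frame(reaction_id = ids[[1]], n_members = length(ids),
                     members = paste(ids, collapse = ","),
                     sd = sds[[g[[1]]]], stringsAsFactors = FALSE),
          stats::setNames(as.data.frame(t(series[g[[1]], ])),
                          paste0("f_", keys)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Proteome response to excess supply of essential nutrients
#'
#' For each auxotroph, its essential metabolite's uptake is opened
#' unbounded, growth is maximized, and the growth-normalized protein mass
#' per subsystem (g/gDW) is compared to the prototroph's as a log2 fold
#' change. Subsystems are retained when at least one auxotroph shows
#' \eqn{|log2fc| >} `lfc_thresh`.
#'
#' @param model the prototrophic model (with its media bounds set).
#' @param aux_models named list of [make_auxotroph()] outputs, named by
#'   metabolite.
#' @param lfc_thresh retention threshold on the absolute log2 fold change.
#' @param tol,mu_hi solver settings.
#' @param eps pseudo-mass guarding the fold change against empty subsystems.
#' @return data.frame with columns `metabolite_id`, `subsystem`, `log2fc`,
#'   filtered to retained subsystems.
#' @export
excess_response <- function(model, aux_models, lfc_thresh = 0.2,
                            tol = 1e-6, mu_hi = 4, eps = 1e-9) {
  proto_sol <- maximize_growth(model, mu_hi = mu_hi, tol = tol)
  proto <- protein_allocation(proto_sol, model, normalize = FALSE)
  rows <- list()
  for (met in names(aux_models)) {
    aux <- aux_models[[met]]
    open <- set_bounds(aux, aux$auxotroph$exchange_id, lb = -1000)
    sol <- maximize_growth(open, mu_hi = mu_hi, tol = tol)
    alloc <- protein_allocation(sol, open, normalize = FALSE)
    subs <- union(names(proto), names(alloc))
    a <- stats::setNames(rep(0, length(subs)), subs); a[names(alloc)] <- alloc
    p <- stats::setNames(rep(0, length(subs)), subs); p[names(proto)] <- proto
    rows[[met]] <- data.frame(metabolite_id = met, subsystem = subs,
                              log2fc = log2((a + eps) / (p + eps)),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  keep_sub <- unique(out$subsystem[abs(out$log2fc) > lfc_thresh])
  out <- out[out$subsystem %in% keep_sub, , drop = FALSE]
  rownames(out) <- NULL
  out
}
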