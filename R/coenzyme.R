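#' Coenzyme specification
#'
#' A coenzyme is a recycled carrier (NAD-like): mass balance keeps the
#' charged/uncharged pool closed, so nothing in a plain ME model forces its
#' biosynthesis. The activity coupling in [apply_coenzyme_coupling()] fixes
#' that.
#'
#' @param id coenzyme identifier (conventionally the uncharged species id).
#' @param uncharged_species,charged_species the two pool members.
#' @param biosynthesis_reaction the designated pathway reaction whose flux is
#'   reported as the coenzyme's synthesis demand.
#' @param formation_reaction the final synthesis step producing the uncharged
#'   species (often equal to `biosynthesis_reaction`).
#' @return a list of class `coenzyme_spec`.
#' @export
coenzyme_spec <- function(id, uncharged_species, charged_species,
                          biosynthesis_reaction,
                          formation_reaction = biosynthesis_reaction) {
  if (identical(uncharged_species, charged_species)) {
    stop("uncharged and charged species of ", id, " must differ")
  }
  structure(list(id = id, uncharged_species = uncharged_species,
                 charged_species = charged_species,
                 biosynthesis_reaction = biosynthesis_reaction,
                 formation_reaction = formation_reaction),
            class = "coenzyme_spec")
}

# reactions in which `uncharged` is consumed while `charged` is produced
charging_reactions_for <- function(model, uncharged, charged) {
  skip <- c("exchange", "demand", "biomass_dilution", "summary")
  out <- character(0)
  for (r in model$reactions) {
    if (r$klass %in% skip) next
    su <- r$stoich[[uncharged]]
    if (is.null(su)) next
    if (as_mu_coef(su)[["const"]] >= 0) next
    sc <- r$stoich[[charged]]
    if (!is.null(sc) && as_mu_coef(sc)[["const"]] > 0) out <- c(out, r$id)
  }
  out
}

#' Identify the species that behave as coenzymes
#'
#' A species qualifies when it meets two criteria: (1) it functions in the
#' network exclusively as a coenzyme — every reaction that consumes it also
#' regenerates its declared charged partner (it is never drawn off as a
#' biosynthetic precursor; exchange, demand and summary reactions are
#' ignored); and (2) it, or a declared close derivative, appears among the
#' biomass objective function members `bof_members`. Candidates are the
#' species with role `coenzyme_uncharged` and a `charged_partner` annotation.
#'
#' @param model an [me_model()].
#' @param bof_members character vector of biomass objective function member
#'   ids (defaults to `model$bof_members`).
#' @param aliases named character vector mapping derivative ids to candidate
#'   ids (e.g. a charged form listed in the biomass function standing in for
#'   its uncharged parent); derivative closeness is declared, not inferred.
#' @return a list of [coenzyme_spec()] ordered by id. Candidates lacking a
#'   charging reaction are dropped with a warning.
#' @export
identify_coenzymes <- function(model, bof_members = model$bof_members,
                               aliases = character(0)) {
  if (length(bof_members) == 0L) return(list())
  bof <- unique(c(bof_members,
                  names(aliases)[aliases %in% bof_members],
                  unname(aliases[names(aliases) %in% bof_members])))
  out <- list()
  for (id in sort(species_ids(model, "coenzyme_uncharged"))) {
    s <- model$species[[id]]
    if (is.null(s$charged_partner)) next
    if (isTRUE(s$biosynthetic_precursor)) next
    # selection criterion (2): membership (or declared derivative membership) in the BOF
    if (!(id %in% bof || s$charged_partner %in% bof)) next
    # selection criterion (1): consumed only by reactions that regenerate the partner
    charging <- charging_reactions_for(model, id, s$charged_partner)
    skip <- c("exchange", "demand", "biomass_dilution", "summary")
    consumers <- Filter(function(r) {
      if (r$klass %in% skip) return(FALSE)
      su <- r$stoich[[id]]
      !is.null(su) && as_mu_coef(su)[["const"]] < 0
    }, model$reactions)
    if (!all(vapply(consumers, `[[`, "", "id") %in% charging)) next
    if (length(charging) == 0L) {
      warning("species ", id, " is flagged as a coenzyme but has no ",
              "charging reaction; skipped")
      next
    }
    if (is.null(s$biosynthesis_reaction) ||
        !s$biosynthesis_reaction %in% names(model$reactions)) {
      stop("coenzyme ", id, " lacks a valid biosynthesis_reaction annotation")
    }
    out[[id]] <- coenzyme_spec(
      id, uncharged_species = id, charged_species = s$charged_partner,
      biosynthesis_reaction = s$biosynthesis_reaction,
      formation_reaction = s$formation_reaction %||% s$biosynthesis_reaction)
  }
  unname(out)
}

#' Couple coenzyme biosynthesis to coenzyme activity
#'
#' Implements the pseudo-kinetic activity coupling: in every reaction where
#' the uncharged coenzyme is a reactant its stoichiometric coefficient is
#' multiplied by \eqn{(1 + \mu/k_{activity})}, so a fraction
#' \eqn{\mu/k_{activity}} of each use must be replaced by fresh synthesis;
#' and a formation-coupling row ties the coenzyme's external supply to its
#' usage, \eqn{v_{formation,j} = \sum_i (\mu/k_{activity,ij}) v_{usage,i}}.
#' The row keeps the original stoichiometric entry of every reaction that
#' produces or consumes the uncharged species outside the charging/discharge
#' cycle (biosynthesis +1, an open uptake exchange -1), so it remains valid
#' for auxotrophs fed the coenzyme rather than synthesizing it; for a
#' prototroph it reduces exactly to the formation/usage balance above.
#'
#' The multiplier is applied to the forward-consuming direction only;
#' reversible charging reactions must be split into irreversible pairs
#' beforehand (the generators here only emit irreversible reactions).
#'
#' @param model an [me_model()].
#' @param coenzymes list of [coenzyme_spec()] from [identify_coenzymes()].
#' @param k_activity global pseudo-first-order activity rate in 1/h
#'   (default 1e4); per-(coenzyme, reaction) overrides are taken from
#'   `model$params$k_activity_overrides`.
#' @return the modified model, with `model$coenzymes` recorded.
#' @export
apply_coenzyme_coupling <- function(model, coenzymes,
                                    k_activity =
                                      model$params$k_activity_default) {
  if (k_activity <= 0) stop("k_activity must be > 0")
  for (cz in coenzymes) {
    u <- cz$uncharged_species
    charging <- charging_reactions_for(model, u, cz$charged_species)
    # any reaction (outside the cycle and bookkeeping klasses) consuming the
    # uncharged form counts as usage; for a true coenzyme these coincide
    # with the charging reactions
    if (length(charging) == 0L) {
      warning("coenzyme ", cz$id, " has no reactant occurrences of its ",
              "uncharged form; coupling is a no-op")
      next
    }
    entries <- list()
    for (rid in charging) {
      ka <- k_activity_for(model$params, cz$id, rid, default = k_activity)
      s0 <- as_mu_coef(model$reactions[[rid]]$stoich[[u]])
      if (s0[["mu"]] != 0 || s0[["inv_mu"]] != 0 || s0[["mu2"]] != 0) {
        stop("uncharged coenzyme ", u, " already has a mu-dependent ",
             "coefficient in ", rid, "; coupling cannot be applied twice")
      }
      mag <- -s0[["const"]]                     # original magnitude (> 0)
      # (a) multiplicative rewrite: -mag -> -mag * (1 + mu/ka)
      model$reactions[[rid]]$stoich[[u]] <-
        mu_coef(const = -mag, mu = -mag / ka)
      # (b) usage term of the formation row
      entries[[rid]] <- mu_coef(mu = -mag / ka)
    }
    # non-cycle producers/consumers keep their native stoichiometric entry
    regen <- charging_reactions_for(model, cz$charged_species, u)
    for (r in model$reactions) {
      if (r$id %in% c(charging, regen)) next
      if (r$klass %in% c("demand", "biomass_dilution", "summary")) next
      su <- r$stoich[[u]]
      if (is.null(su)) next
      entries[[r$id]] <- add_mu_coef(entries[[r$id]] %||% mu_coef(), su)
    }
    if (!cz$formation_reaction %in% names(entries)) {
      stop("formation reaction ", cz$formation_reaction, " of coenzyme ",
           cz$id, " does not touch its uncharged species")
    }
    model <- add_coupling_row(model, paste0("coenzyme_", cz$id), entries)
  }
  model$coenzymes <- coenzymes
  model
}

#' Disable the static biomass-constituent demand
#'
#' ME reconstructions carry a fixed-flux demand reaction accounting for the
#' synthesis of constituents (notably coenzymes) that the activity coupling
#' now models directly; its flux is set to zero. Idempotent; absence of the
#' reaction is a no-op.
#'
#' @param model an [me_model()].
#' @param reaction_id id of the demand reaction; by default the first
#'   reaction of klass `"demand"` whose id contains `"constituent"`, else the
#'   single `"demand"` reaction if there is exactly one.
#' @return the modified model.
#' @export
zero_biomass_constituent_demand <- function(model, reaction_id = NULL) {
  if (is.null(reaction_id)) {
    dem <- reaction_ids(model, "demand")
    hit <- grep("constituent", dem, value = TRUE)
    reaction_id <- if (length(hit)) hit[[1]]
                   else if (length(dem) == 1L) dem
                   else NULL
  }
  if (is.null(reaction_id) || !reaction_id %in% names(model$reactions)) {
    message("no biomass constituent demand reaction present; nothing to do")
    return(model)
  }
  set_bounds(model, reaction_id, lb = 0, ub = 0)
}
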