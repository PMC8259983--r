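#' Biomass constituent demand accounting
#'
#' In an ME model the biomass composition is an output: the synthesis demand
#' of each constituent is read off the optimal flux distribution rather than
#' fixed in a biomass objective function. Amino-acid demand is the
#' translation-flux-weighted sum of peptide compositions; prosthetic-group
#' demand is the sum of complex-formation fluxes weighted by each complex's
#' prosthetic stoichiometry; coenzyme demand is the flux of the designated
#' reaction in the coenzyme's (single, direct) biosynthetic pathway.
#'
#' @name biomass_demand
NULL

# noise floor of the double-precision LP backend is ~1e-9; demands below
# this are solver noise, not biology
demand_clamp_default <- 1e-8

flux_of <- function(solution, id) {
  v <- solution$fluxes[[id]]
  if (is.null(v) || is.na(v)) 0 else v
}

#' Amino-acid synthesis demand of a solution
#'
#' \eqn{demand[aa] = \sum_{i \in Peptide} v_{translation,i} \cdot
#' composition_i[aa]}.
#'
#' @param solution an `me_solution` of `model`.
#' @param model the [me_model()] the solution came from.
#' @param clamp demands below this are set to zero to suppress LP noise.
#' @return named numeric vector, amino-acid id to flux (mmol/gDW/h).
#' @export
amino_acid_demand <- function(solution, model, clamp = demand_clamp_default) {
  out <- numeric(0)
  for (r in model$reactions) {
    if (r$klass != "translation") next
    pep <- model$species[[r$peptide]]
    if (is.null(pep$composition)) next
    v <- flux_of(solution, r$id)
    for (aa in names(pep$composition)) {
      out[aa] <- (if (aa %in% names(out)) out[[aa]] else 0) +
        v * pep$composition[[aa]]
    }
  }
  out[out < clamp] <- 0
  out[order(names(out))]
}

#' Prosthetic-group incorporation demand of a solution
#'
#' \eqn{demand[g] = \sum_{j \in Complex} v_{formation,j} \cdot stoich_j[g]},
#' where the stoichiometry is read from each complex-formation reaction's
#' consumption of species with role `prosthetic_group`.
#'
#' @inheritParams amino_acid_demand
#' @return named numeric vector, prosthetic-group id to flux.
#' @export
prosthetic_demand <- function(solution, model, clamp = demand_clamp_default) {
  groups <- species_ids(model, "prosthetic_group")
  out <- stats::setNames(numeric(length(groups)), groups)
  for (r in model$reactions) {
    if (r$klass != "complex_formation") next
    v <- flux_of(solution, r$id)
    for (g in intersect(names(r$stoich), groups)) {
      s <- as_mu_coef(r$stoich[[g]])[["const"]]
      if (s < 0) out[g] <- out[g] + v * (-s)
    }
  }
  out[out < clamp] <- 0
  out[order(names(out))]
}

#' Coenzyme biosynthesis demand of a solution
#'
#' \eqn{demand[c] = v[\mathrm{biosynthesis\_reaction}(c)]}: each coenzyme has
#' one direct biosynthetic pathway and its designated reaction's flux is the
#' synthesis demand.
#'
#' @param solution an `me_solution`.
#' @param coenzymes list of [coenzyme_spec()].
#' @param clamp demands below this are set to zero.
#' @return named numeric vector, coenzyme id to flux.
#' @export
coenzyme_demand <- function(solution, coenzymes,
                            clamp = demand_clamp_default) {
  out <- numeric(0)
  for (cz in coenzymes) {
    if (!cz$biosynthesis_reaction %in% names(solution$fluxes)) {
      stop("designated biosynthesis reaction ", cz$biosynthesis_reaction,
           " of coenzyme ", cz$id, " is absent from the solution")
    }
    out[cz$id] <- flux_of(solution, cz$biosynthesis_reaction)
  }
  out[out < clamp] <- 0
  out[order(names(out))]
}

#' Normalize raw synthesis demands into a biomass composition
#'
#' Two normalizations are supported: `per_growth` divides by the computed
#' growth rate (the convention for comparison against a static biomass
#' objective function, giving mmol/gDW), and `per_protein_biomass` divides by
#' the flux of the protein-biomass summary reaction (the convention for
#' cross-condition composition analysis, since amino-acid and
#' prosthetic-group demands are strongly tied to total protein content).
#'
#' @param demands named numeric vector of raw demands (fluxes).
#' @param solution the `me_solution` the demands were computed from.
#' @param model the model (for the summary-reaction id).
#' @param mode `"per_growth"`, `"per_protein_biomass"`, or `"raw"`.
#' @param condition_id,aerobic,element_class metadata carried through.
#' @return a `biomass_composition`: data.frame with columns `component_id`
#'   and `demand` plus metadata attributes (`condition_id`, `aerobic`,
#'   `element_class`, `growth_rate`, `normalization`).
#' @export
normalize_composition <- function(demands, solution, model,
                                  mode = c("per_growth",
                                           "per_protein_biomass", "raw"),
                                  condition_id = NA_character_,
                                  aerobic = NA, element_class = NA_character_) {
  mode <- match.arg(mode)
  denom <- switch(mode,
    raw = 1,
    per_growth = solution$mu_opt,
    per_protein_biomass = flux_of(solution, model$protein_biomass_summary_id))
  if (mode != "raw" && (!is.finite(denom) || denom <= 0)) {
    stop("normalization error in condition '", condition_id, "': ",
         if (mode == "per_growth") "growth rate" else "protein biomass flux",
         " is not positive")
  }
  out <- data.frame(component_id = names(demands),
                    demand = as.numeric(demands) / denom,
                    stringsAsFactors = FALSE)
  structure(out, class = c("biomass_composition", "data.frame"),
            condition_id = condition_id, aerobic = aerobic,
            element_class = element_class, growth_rate = solution$mu_opt,
            normalization = mode)
}

#' Full constituent demand table for one solution
#'
#' Convenience wrapper combining [amino_acid_demand()],
#' [prosthetic_demand()] and [coenzyme_demand()] into one tidy table.
#'
#' @inheritParams normalize_composition
#' @param coenzymes list of [coenzyme_spec()] (defaults to
#'   `model$coenzymes`).
#' @return data.frame with columns `component_id`, `component_class`
#'   (`amino_acid`, `prosthetic`, `coenzyme`) and `demand`, normalized per
#'   `mode`; metadata as in [normalize_composition()].
#' @export
constituent_demands <- function(solution, model,
                                coenzymes = model$coenzymes,
                                mode = "per_protein_biomass",
                                condition_id = NA_character_,
                                aerobic = NA,
                                element_class = NA_character_) {
  aa <- amino_acid_demand(solution, model)
  pg <- prosthetic_demand(solution, model)
  cz <- if (length(coenzymes)) coenzyme_demand(solution, coenzymes)
        else numeric(0)
  raw <- c(aa, pg, cz)
  comp <- normalize_composition(raw, solution, model, mode = mode,
                                condition_id = condition_id,
                                aerobic = aerobic,
                                element_class = element_class)
  cls <- c(stats::setNames(rep("amino_acid", length(aa)), names(aa)),
           stats::setNames(rep("prosthetic", length(pg)), names(pg)),
           stats::setNames(rep("coenzyme", length(cz)), names(cz)))
  out <- data.frame(component_id = comp$component_id,
                    component_class = unname(cls[comp$component_id]),
                    demand = comp$demand, stringsAsFactors = FALSE)
  structure(out, class = c("biomass_composition", "data.frame"),
            condition_id = condition_id, aerobic = aerobic,
            element_class = element_class, growth_rate = solution$mu_opt,
            normalization = mode)
}
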