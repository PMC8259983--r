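#' Read and write ME models as JSON
#'
#' The schema has top-level keys `species`, `reactions`, `params`, plus the
#' model-level ids (`biomass_dilution_id`, `protein_biomass_summary_id`,
#' `ribosome_id`, `rnap_id`), `bof_members` and `nutrient_exchanges`.
#' Growth-rate-dependent coefficients are serialized as objects
#' `{"const": a, "mu": b, "inv_mu": c}` (plus `"mu2"` for the quadratic
#' synthetase term), zero components omitted; plain numbers stand for
#' constant coefficients. Numbers are written with 17 significant digits, so
#' a write/read round trip reproduces the stoichiometric matrices
#' bit-identically.
#'
#' @param model an [me_model()].
#' @param path file path.
#' @return `write_me_model` returns `path` invisibly; `read_me_model`
#'   returns the reconstructed [me_model()].
#' @name me_model_json
NULL

coef_to_json <- function(co) {
  co <- as_mu_coef(co)
  if (co[["mu"]] == 0 && co[["inv_mu"]] == 0 && co[["mu2"]] == 0) {
    return(co[["const"]])
  }
  out <- list(const = co[["const"]])
  for (f in c("mu", "inv_mu", "mu2")) if (co[[f]] != 0) out[[f]] <- co[[f]]
  out
}

drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

#' @rdname me_model_json
#' @export
write_me_model <- function(model, path) {
  species <- lapply(unname(model$species), function(s) {
    drop_null(list(
      id = s$id, role = s$role, compartment = s$compartment,
      molecular_weight = s$molecular_weight, subsystem = s$subsystem,
      length = s$length,
      composition = if (!is.null(s$composition)) as.list(s$composition),
      part_of = if (!is.null(s$part_of)) as.list(s$part_of),
      encoded_mRNAs = s$encoded_mRNAs,
      charged_partner = s$charged_partner,
      biosynthesis_reaction = s$biosynthesis_reaction,
      formation_reaction = s$formation_reaction,
      biosynthetic_precursor =
        if (isTRUE(s$biosynthetic_precursor)) TRUE))
  })
  reactions <- lapply(unname(model$reactions), function(r) {
    drop_null(list(
      id = r$id, klass = r$klass,
      stoich = lapply(r$stoich, coef_to_json),
      lb = coef_to_json(r$lb), ub = coef_to_json(r$ub),
      catalyst = r$catalyst, subsystem = r$subsystem,
      peptide = r$peptide, tu = r$tu, mrna = r$mrna,
      synthetase = r$synthetase, trna = r$trna, complex = r$complex))
  })
  p <- model$params
  params <- list(
    kappa_tau = p$kappa_tau, r0 = p$r0, c_ribo = p$c_ribo,
    c_mRNA = p$c_mRNA, c_tRNA = as.list(p$c_tRNA),
    k_deg = as.list(p$k_deg), k_deg_default = p$k_deg_default,
    k_eff_default = p$k_eff_default,
    k_eff_overrides = as.list(p$k_eff_overrides),
    k_eff_tRNA = p$k_eff_tRNA, k_eff_charging = p$k_eff_charging,
    k_activity_default = p$k_activity_default,
    k_activity_overrides = as.list(p$k_activity_overrides),
    unmodeled_protein_fraction = p$unmodeled_protein_fraction)
  doc <- drop_null(list(
    format = "me-model-json-1",
    species = species, reactions = reactions, params = params,
    biomass_dilution_id = model$biomass_dilution_id,
    protein_biomass_summary_id = model$protein_biomass_summary_id,
    ribosome_id = model$ribosome_id, rnap_id = model$rnap_id,
    bof_members = model$bof_members,
    nutrient_exchanges = model$nutrient_exchanges))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           null = "null", dataframe = "columns")
  writeLines(json, path)
  invisible(path)
}

unlist1 <- function(x) {
  if (is.null(x) || !length(x)) return(numeric(0))
  unlist(x)
}

#' @rdname me_model_json
#' @export
read_me_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  species <- lapply(doc$species, function(s) {
    me_species(
      id = s$id, role = s$role, compartment = s$compartment %||% "c",
      molecular_weight = s$molecular_weight, subsystem = s$subsystem,
      length = s$length,
      composition = if (!is.null(s$composition)) unlist1(s$composition),
      part_of = if (!is.null(s$part_of)) unlist1(s$part_of),
      encoded_mRNAs = if (!is.null(s$encoded_mRNAs)) {
        unlist(s$encoded_mRNAs)
      },
      charged_partner = s$charged_partner,
      biosynthesis_reaction = s$biosynthesis_reaction,
      formation_reaction = s$formation_reaction,
      biosynthetic_precursor = isTRUE(s$biosynthetic_precursor))
  })
  reactions <- lapply(doc$reactions, function(r) {
    me_reaction(
      id = r$id, klass = r$klass, stoich = lapply(r$stoich, as_mu_coef),
      lb = as_mu_coef(r$lb), ub = as_mu_coef(r$ub),
      catalyst = r$catalyst, subsystem = r$subsystem, peptide = r$peptide,
      tu = r$tu, mrna = r$mrna, synthetase = r$synthetase, trna = r$trna,
      complex = r$complex)
  })
  p <- doc$params
  params <- coupling_params(
    kappa_tau = p$kappa_tau, r0 = p$r0, c_ribo = p$c_ribo,
    c_mRNA = p$c_mRNA, c_tRNA = as.list(unlist1(p$c_tRNA)),
    k_deg = unlist1(p$k_deg), k_deg_default = p$k_deg_default,
    k_eff_default = p$k_eff_default,
    k_eff_overrides = unlist1(p$k_eff_overrides),
    k_eff_tRNA = p$k_eff_tRNA, k_eff_charging = p$k_eff_charging,
    k_activity_default = p$k_activity_default,
    k_activity_overrides = unlist1(p$k_activity_overrides),
    unmodeled_protein_fraction = p$unmodeled_protein_fraction)
  nx <- NULL
  if (!is.null(doc$nutrient_exchanges)) {
    nx <- as.data.frame(lapply(doc$nutrient_exchanges, unlist),
                        stringsAsFactors = FALSE)
  }
  me_model(species, reactions, params,
           biomass_dilution_id = doc$biomass_dilution_id,
           protein_biomass_summary_id = doc$protein_biomass_summary_id,
           ribosome_id = doc$ribosome_id, rnap_id = doc$rnap_id,
           bof_members = unlist(doc$bof_members) %||% character(0),
           nutrient_exchanges = nx)
}
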