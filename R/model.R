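#' Construct an ME-model species
#'
#' Species cover both small metabolites and the expression machinery of a
#' metabolism-and-expression (ME) model. Macromolecule roles (`peptide`,
#' `mRNA`, `tRNA`, `enzyme_complex`, ...) carry extra payload fields used by
#' the coupling-constraint builders.
#'
#' @param id unique species identifier.
#' @param role one of `"metabolite"`, `"peptide"`, `"mRNA"`,
#'   `"transcription_unit"`, `"tRNA"`, `"charged_tRNA"`, `"synthetase"`,
#'   `"enzyme_complex"`, `"coenzyme_uncharged"`, `"coenzyme_charged"`,
#'   `"prosthetic_group"`, `"biomass_pool"`, `"pseudo"`.
#' @param compartment compartment label (default `"c"`).
#' @param molecular_weight g/mmol; required for protein-mass accounting,
#'   must be positive when given.
#' @param subsystem optional annotation.
#' @param length amino-acid count (peptides) or nucleotide count
#'   (transcription units).
#' @param composition named integer vector, amino-acid id to count
#'   (peptides); counts must sum to `length`.
#' @param part_of named numeric vector, complex id to copy number, for
#'   peptides that are complex subunits.
#' @param encoded_mRNAs character vector of mRNA ids (transcription units).
#' @param charged_partner for `coenzyme_uncharged` species, the id of the
#'   charged form.
#' @param biosynthesis_reaction,formation_reaction for coenzymes, the
#'   reaction used for demand accounting and the final synthesis step.
#' @param biosynthetic_precursor logical; whether the species is consumed as
#'   a biosynthetic building block somewhere in the network (used by
#'   [identify_coenzymes()]).
#' @return a list of class `me_species`.
#' @export
me_species <- function(id, role = "metabolite", compartment = "c",
                       molecular_weight = NULL, subsystem = NULL,
                       length = NULL, composition = NULL, part_of = NULL,
                       encoded_mRNAs = NULL, charged_partner = NULL,
                       biosynthesis_reaction = NULL,
                       formation_reaction = NULL,
                       biosynthetic_precursor = FALSE) {
  roles <- c("metabolite", "peptide", "mRNA", "transcription_unit", "tRNA",
             "charged_tRNA", "synthetase", "enzyme_complex",
             "coenzyme_uncharged", "coenzyme_charged", "prosthetic_group",
             "biomass_pool", "pseudo")
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("species id must be a non-empty string")
  }
  role <- match.arg(role, roles)
  if (!is.null(molecular_weight) && molecular_weight <= 0) {
    stop("molecular_weight must be > 0 for species ", id)
  }
  if (!is.null(composition)) {
    if (is.null(length)) stop("peptide ", id, " has composition but no length")
    if (any(composition < 0) || any(composition != round(composition))) {
      stop("composition counts must be non-negative integers (", id, ")")
    }
    if (sum(composition) != length) {
      stop("composition of ", id, " sums to ", sum(composition),
           " but length is ", length)
    }
  }
  structure(list(id = id, role = role, compartment = compartment,
                 molecular_weight = molecular_weight, subsystem = subsystem,
                 length = length, composition = composition,
                 part_of = part_of, encoded_mRNAs = encoded_mRNAs,
                 charged_partner = charged_partner,
                 biosynthesis_reaction = biosynthesis_reaction,
                 formation_reaction = formation_reaction,
                 biosynthetic_precursor = isTRUE(biosynthetic_precursor)),
            class = "me_species")
}

#' Construct an ME-model reaction
#'
#' Stoichiometric coefficients may be plain numbers or [mu_coef()]
#' growth-rate-dependent coefficients; bounds likewise (the biomass dilution
#' reaction has both bounds pinned to \eqn{\mu}).
#'
#' @param id unique reaction identifier.
#' @param klass one of `"metabolic"`, `"translation"`, `"transcription"`,
#'   `"complex_formation"`, `"tRNA_charging"`, `"coenzyme_charging"`,
#'   `"mRNA_degradation"`, `"exchange"`, `"biomass_dilution"`, `"demand"`,
#'   `"summary"`.
#' @param stoich named list, species id to coefficient (numeric or
#'   [mu_coef()]).
#' @param lb,ub flux bounds in mmol/gDW/h (numeric or [mu_coef()]).
#' @param catalyst enzyme-complex id or `NULL`.
#' @param subsystem optional annotation.
#' @param peptide,tu,mrna,synthetase,trna linkage annotations used by the
#'   coupling builders: the peptide made by a translation reaction, the
#'   transcription unit of a transcription reaction, the mRNA a translation
#'   or degradation reaction belongs to, and the synthetase / tRNA of a
#'   charging reaction.
#' @param complex for `complex_formation` reactions, the id of the complex
#'   being assembled.
#' @return a list of class `me_reaction`.
#' @export
me_reaction <- function(id, klass = "metabolic", stoich = list(),
                        lb = 0, ub = 1000, catalyst = NULL, subsystem = NULL,
                        peptide = NULL, tu = NULL, mrna = NULL,
                        synthetase = NULL, trna = NULL, complex = NULL) {
  klasses <- c("metabolic", "translation", "transcription",
               "complex_formation", "tRNA_charging", "coenzyme_charging",
               "mRNA_degradation", "exchange", "biomass_dilution", "demand",
               "summary")
  klass <- match.arg(klass, klasses)
  material <- !grepl("^coupling__", names(stoich))
  if (klass == "exchange" && sum(material) != 1L) {
    stop("exchange reaction ", id, " must touch exactly one species")
  }
  stoich <- lapply(stoich, as_mu_coef)
  structure(list(id = id, klass = klass, stoich = stoich,
                 lb = if (is.numeric(lb)) lb else as_mu_coef(lb),
                 ub = if (is.numeric(ub)) ub else as_mu_coef(ub),
                 catalyst = catalyst, subsystem = subsystem,
                 peptide = peptide, tu = tu, mrna = mrna,
                 synthetase = synthetase, trna = trna, complex = complex),
            class = "me_reaction")
}

#' Coupling parameters of an ME model
#'
#' All rates are stored in 1/h. Inputs quoted per second (effective turnover
#' numbers are conventionally reported in 1/s) should be converted with
#' [per_second()] at load time.
#'
#' @param kappa_tau \eqn{\kappa_\tau}, 1/h; slope parameter of the
#'   RNA-to-protein growth-rate relation used in the expression couplings.
#' @param r0 dimensionless intercept parameter of the same relation.
#' @param c_ribo amino acids per ribosome-hour scale of the ribosome
#'   coupling.
#' @param c_mRNA nucleotides per mRNA scale of the mRNA couplings.
#' @param c_tRNA named numeric, tRNA id to dimensionless \eqn{c_{tRNA,j}}.
#' @param k_deg named numeric, mRNA id to degradation rate constant (1/h);
#'   `k_deg_default` is used for mRNAs not listed.
#' @param k_deg_default default mRNA degradation rate, 1/h.
#' @param k_eff_default default effective turnover rate, 1/h (65 1/s for
#'   expression machinery and transport).
#' @param k_eff_overrides named numeric, reaction id to k_eff in 1/h, for
#'   reactions whose turnover differs from the default (e.g. a
#'   high-turnover pyruvate-dehydrogenase-like step at 1500 1/s).
#' @param k_eff_tRNA,k_eff_charging turnover rates of the synthetase
#'   coupling, 1/h.
#' @param k_activity_default pseudo-first-order coenzyme activity rate, 1/h
#'   (default 1e4).
#' @param k_activity_overrides named numeric, `"coenzyme|reaction"` to
#'   k_activity in 1/h.
#' @param unmodeled_protein_fraction fraction of the proteome assumed outside
#'   the model's scope, in [0, 1); applied as a scaling of the
#'   protein-biomass summary stoichiometry.
#' @return a list of class `coupling_params`.
#' @export
coupling_params <- function(kappa_tau = 4.5, r0 = 0.087, c_ribo = 10000,
                            c_mRNA = 1000, c_tRNA = numeric(0),
                            k_deg = numeric(0), k_deg_default = 8,
                            k_eff_default = per_second(65),
                            k_eff_overrides = numeric(0),
                            k_eff_tRNA = per_second(65),
                            k_eff_charging = per_second(65),
                            k_activity_default = 1e4,
                            k_activity_overrides = numeric(0),
                            unmodeled_protein_fraction = 0) {
  rates <- c(kappa_tau = kappa_tau, c_ribo = c_ribo, c_mRNA = c_mRNA,
             k_eff_default = k_eff_default, k_eff_tRNA = k_eff_tRNA,
             k_eff_charging = k_eff_charging,
             k_activity_default = k_activity_default)
  if (any(rates <= 0)) {
    stop("all coupling rate constants must be > 0: ",
         paste(names(rates)[rates <= 0], collapse = ", "))
  }
  if (r0 < 0) stop("r0 must be >= 0")
  if (any(k_deg < 0) || k_deg_default < 0) stop("k_deg must be >= 0")
  if (length(k_eff_overrides) && any(k_eff_overrides <= 0)) {
    stop("k_eff overrides must be > 0")
  }
  if (unmodeled_protein_fraction < 0 || unmodeled_protein_fraction >= 1) {
    stop("unmodeled_protein_fraction must lie in [0, 1)")
  }
  structure(list(kappa_tau = kappa_tau, r0 = r0, c_ribo = c_ribo,
                 c_mRNA = c_mRNA, c_tRNA = c_tRNA, k_deg = k_deg,
                 k_deg_default = k_deg_default,
                 k_eff_default = k_eff_default,
                 k_eff_overrides = k_eff_overrides,
                 k_eff_tRNA = k_eff_tRNA, k_eff_charging = k_eff_charging,
                 k_activity_default = k_activity_default,
                 k_activity_overrides = k_activity_overrides,
                 unmodeled_protein_fraction = unmodeled_protein_fraction),
            class = "coupling_params")
}

#' Convert a per-second rate constant to per-hour
#'
#' @param x rate in 1/s.
#' @return rate in 1/h.
#' @examples per_second(65) # 234000
#' @export
per_second <- function(x) x * 3600

#' Assemble an ME model
#'
#' @param species list of [me_species()].
#' @param reactions list of [me_reaction()].
#' @param params a [coupling_params()].
#' @param biomass_dilution_id id of the (single) biomass dilution reaction.
#' @param protein_biomass_summary_id id of the protein-biomass summary
#'   reaction whose flux is the total protein synthesis rate in g/gDW/h.
#' @param ribosome_id,rnap_id complex ids of the ribosome and RNA polymerase.
#' @param bof_members character vector: species (or close derivatives)
#'   present in the biomass objective function of the matched M-model;
#'   consulted by [identify_coenzymes()].
#' @param nutrient_exchanges data.frame with columns `nutrient_id`,
#'   `element_class`, `exchange_id` mapping nutrients to their exchange
#'   reactions (used by media construction).
#' @param validate run [validate_me_model()] (default `TRUE`).
#' @return a list of class `me_model`.
#' @export
me_model <- function(species, reactions, params = coupling_params(),
                     biomass_dilution_id, protein_biomass_summary_id,
                     ribosome_id = NULL, rnap_id = NULL,
                     bof_members = character(0),
                     nutrient_exchanges = NULL, validate = TRUE) {
  names(species) <- vapply(species, `[[`, "", "id")
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  m <- structure(list(species = species, reactions = reactions,
                      params = params,
                      biomass_dilution_id = biomass_dilution_id,
                      protein_biomass_summary_id = protein_biomass_summary_id,
                      ribosome_id = ribosome_id, rnap_id = rnap_id,
                      bof_members = bof_members,
                      nutrient_exchanges = nutrient_exchanges,
                      coenzymes = NULL),
                 class = "me_model")
  if (validate) validate_me_model(m)
  m
}

#' Validate the structural invariants of an ME model
#'
#' Checks id uniqueness, stoichiometry/species consistency, bound sanity,
#' peptide composition sums, transcription-unit length consistency and the
#' uniqueness of the biomass dilution reaction.
#'
#' @param model an [me_model()].
#' @return invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validate_me_model <- function(model) {
  sids <- vapply(model$species, `[[`, "", "id")
  rids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(sids)) {
    stop("duplicated species ids: ",
         paste(unique(sids[duplicated(sids)]), collapse = ", "))
  }
  if (anyDuplicated(rids)) {
    stop("duplicated reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  }
  for (r in model$reactions) {
    missing <- setdiff(names(r$stoich), sids)
    if (length(missing)) {
      stop("reaction ", r$id, " references unknown species: ",
           paste(missing, collapse = ", "))
    }
    plain <- function(b) is.numeric(b) && !inherits(b, "mu_coef") &&
      length(b) == 1L
    if (plain(r$lb) && plain(r$ub) && r$lb > r$ub) {
      stop("reaction ", r$id, " has lb > ub")
    }
  }
  dil <- rids[vapply(model$reactions, function(r) r$klass == "biomass_dilution",
                     logical(1))]
  if (length(dil) != 1L) {
    stop("model must contain exactly one biomass_dilution reaction, found ",
         length(dil))
  }
  if (!identical(unname(dil), model$biomass_dilution_id)) {
    stop("biomass_dilution_id does not name the biomass_dilution reaction")
  }
  if (!model$protein_biomass_summary_id %in% rids) {
    stop("protein_biomass_summary_id not found among reactions")
  }
  # transcription-unit / peptide triplet consistency
  for (s in model$species) {
    if (s$role == "transcription_unit" && !is.null(s$encoded_mRNAs)) {
      peps <- unlist(lapply(model$species, function(p) {
        if (p$role == "peptide" && !is.null(p$length)) p$length else NULL
      }))
      linked <- vapply(model$reactions, function(r) {
        identical(r$tu, s$id) && r$klass == "transcription"
      }, logical(1))
      if (any(linked) && !is.null(s$length)) {
        pep_ids <- unlist(lapply(model$reactions, function(r) {
          if (!is.null(r$mrna) && r$klass == "translation" &&
              r$mrna %in% s$encoded_mRNAs) r$peptide else NULL
        }))
        pep_len <- unlist(lapply(model$species[intersect(pep_ids, sids)],
                                 `[[`, "length"))
        if (length(pep_len) && s$length < 3 * max(pep_len)) {
          stop("transcription unit ", s$id, " is shorter than 3x its ",
               "longest encoded peptide")
        }
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.me_model <- function(x, ...) {
  roles <- table(vapply(x$species, `[[`, "", "role"))
  klasses <- table(vapply(x$reactions, `[[`, "", "klass"))
  cat("<me_model> ", length(x$species), " species, ",
      length(x$reactions), " reactions\n", sep = "")
  cat("  species roles:  ",
      paste(names(roles), roles, sep = ":", collapse = " "), "\n", sep = "")
  cat("  reaction kinds: ",
      paste(names(klasses), klasses, sep = ":", collapse = " "), "\n",
      sep = "")
  if (!is.null(x$coenzymes)) {
    cat("  coenzyme coupling applied: ",
        paste(vapply(x$coenzymes, `[[`, "", "id"), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

# ---- small internal accessors -------------------------------------------

reaction_ids <- function(model, klass = NULL) {
  ids <- names(model$reactions)
  if (is.null(klass)) return(ids)
  ids[vapply(model$reactions, function(r) r$klass %in% klass, logical(1))]
}

species_ids <- function(model, role = NULL) {
  ids <- names(model$species)
  if (is.null(role)) return(ids)
  ids[vapply(model$species, function(s) s$role %in% role, logical(1))]
}

#' Set the bounds of a reaction
#'
#' @param model an [me_model()].
#' @param reaction_id reaction id.
#' @param lb,ub new bounds (numeric or [mu_coef()]); `NULL` leaves a bound
#'   unchanged.
#' @return the modified model.
#' @export
set_bounds <- function(model, reaction_id, lb = NULL, ub = NULL) {
  if (!reaction_id %in% names(model$reactions)) {
    stop("unknown reaction: ", reaction_id)
  }
  if (!is.null(lb)) model$reactions[[reaction_id]]$lb <- lb
  if (!is.null(ub)) model$reactions[[reaction_id]]$ub <- ub
  model
}

k_eff_for <- function(params, reaction_id) {
  ov <- params$k_eff_overrides
  if (length(ov) && reaction_id %in% names(ov)) ov[[reaction_id]]
  else params$k_eff_default
}

k_deg_for <- function(params, mrna_id) {
  kd <- params$k_deg
  if (length(kd) && mrna_id %in% names(kd)) kd[[mrna_id]]
  else params$k_deg_default
}

k_activity_for <- function(params, coenzyme_id, reaction_id, default = NULL) {
  key <- paste(coenzyme_id, reaction_id, sep = "|")
  ov <- params$k_activity_overrides
  if (length(ov) && key %in% names(ov)) return(ov[[key]])
  default %||% params$k_activity_default
}
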