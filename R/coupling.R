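#' Growth-coupled expression constraints
#'
#' ME models tie the formation of expression machinery to the fluxes that
#' machinery carries, with coefficients that depend on the growth rate
#' \eqn{\mu}. Each builder below adds one class of coupling row. A row is
#' encoded as a *pseudo-species*: the formation reaction produces one unit of
#' it and every coupled flux consumes the \eqn{\mu}-dependent coefficient, so
#' the whole problem stays a single \eqn{S(\mu)v = 0} system.
#'
#' The coupling coefficients are, per coupled flux:
#' \describe{
#'   \item{ribosome}{\eqn{l_{p,i}(\mu + r_0\kappa_\tau)/(c_{ribo}\kappa_\tau)}
#'     per translation of peptide \eqn{i} of length \eqn{l_{p,i}}.}
#'   \item{RNA polymerase}{\eqn{l_{TU,i}(\mu + r_0\kappa_\tau)/
#'     (3 c_{ribo}\kappa_\tau)} per transcription of unit \eqn{i}.}
#'   \item{synthetase}{\eqn{(1+\mu/k_{eff,tRNA})(\mu/k_{eff,charging})} per
#'     tRNA charging flux.}
#'   \item{enzyme}{\eqn{\mu/k_{eff,ij}} per catalyzed flux.}
#'   \item{tRNA}{\eqn{(\mu + \kappa_\tau r_0)/(\kappa_\tau c_{tRNA,j})} per
#'     charging flux.}
#'   \item{mRNA}{formation \eqn{(\mu + \kappa_\tau r_0)/(3\kappa_\tau
#'     c_{mRNA})} and degradation \eqn{k_{deg,j}(\mu + \kappa_\tau r_0)/
#'     (3\kappa_\tau c_{mRNA}\,\mu)} per translation flux.}
#' }
#'
#' @param model an [me_model()].
#' @return the model with the coupling pseudo-species and stoichiometric
#'   entries added.
#' @name coupling
NULL

coupling_prefix <- "coupling__"

# create the pseudo species (if absent) and wire `entries` (named list of
# mu_coef keyed by reaction id) into the reactions' stoichiometries
add_coupling_row <- function(model, row_id, entries) {
  pid <- paste0(coupling_prefix, row_id)
  if (!pid %in% names(model$species)) {
    sp <- me_species(pid, role = "pseudo")
    model$species[[pid]] <- sp
  }
  for (rid in names(entries)) {
    if (!rid %in% names(model$reactions)) {
      stop("coupling row ", row_id, " references missing reaction ", rid)
    }
    cur <- model$reactions[[rid]]$stoich[[pid]]
    model$reactions[[rid]]$stoich[[pid]] <-
      if (is.null(cur)) as_mu_coef(entries[[rid]])
      else add_mu_coef(cur, entries[[rid]])
  }
  model
}

find_formation <- function(model, complex_id) {
  hits <- Filter(function(r) {
    r$klass == "complex_formation" && identical(r$complex, complex_id)
  }, model$reactions)
  if (length(hits) == 0L) return(NULL)
  hits[[1]]$id
}

# (mu + r0*kappa)/ (c * kappa) as a mu_coef, scaled by `scale`
dilution_coef <- function(kappa_tau, r0, c, scale = 1) {
  mu_coef(const = scale * r0 / c, mu = scale / (c * kappa_tau))
}

#' @describeIn coupling couple ribosome formation to all translation fluxes.
#' @export
build_ribosome_coupling <- function(model) {
  if (is.null(model$ribosome_id)) stop("model has no ribosome_id")
  form <- find_formation(model, model$ribosome_id)
  if (is.null(form)) {
    stop("structural error: no complex_formation reaction for ribosome '",
         model$ribosome_id, "'")
  }
  p <- model$params
  entries <- list()
  entries[[form]] <- mu_coef(const = 1)
  for (r in model$reactions) {
    if (r$klass != "translation") next
    pep <- model$species[[r$peptide]]
    if (is.null(pep) || is.null(pep$length)) {
      stop("translation reaction ", r$id, " lacks a peptide with a length")
    }
    entries[[r$id]] <- scale_mu_coef(
      dilution_coef(p$kappa_tau, p$r0, p$c_ribo, scale = pep$length), -1)
  }
  add_coupling_row(model, "ribosome", entries)
}

#' @describeIn coupling couple RNA polymerase formation to all transcription
#'   fluxes.
#' @export
build_rnap_coupling <- function(model) {
  if (is.null(model$rnap_id)) stop("model has no rnap_id")
  form <- find_formation(model, model$rnap_id)
  if (is.null(form)) {
    stop("structural error: no complex_formation reaction for RNA polymerase '",
         model$rnap_id, "'")
  }
  p <- model$params
  entries <- list()
  entries[[form]] <- mu_coef(const = 1)
  for (r in model$reactions) {
    if (r$klass != "transcription") next
    tu <- model$species[[r$tu]]
    if (is.null(tu) || is.null(tu$length)) {
      stop("transcription reaction ", r$id,
           " lacks a transcription unit with a length")
    }
    entries[[r$id]] <- scale_mu_coef(
      dilution_coef(p$kappa_tau, p$r0, 3 * p$c_ribo, scale = tu$length), -1)
  }
  add_coupling_row(model, "rnap", entries)
}

#' @describeIn coupling couple each synthetase's formation to the charging
#'   fluxes it catalyzes; the coefficient is quadratic in \eqn{\mu}.
#' @export
build_synthetase_coupling <- function(model) {
  p <- model$params
  charg <- Filter(function(r) r$klass == "tRNA_charging", model$reactions)
  if (length(charg) == 0L) return(model)
  by_syn <- split(charg, vapply(charg, function(r) {
    if (is.null(r$synthetase)) {
      stop("structural error: charging reaction ", r$id,
           " has no synthetase annotation")
    }
    r$synthetase
  }, ""))
  coef <- mu_coef(mu = 1 / p$k_eff_charging,
                  mu2 = 1 / (p$k_eff_tRNA * p$k_eff_charging))
  for (syn in names(by_syn)) {
    form <- find_formation(model, syn)
    if (is.null(form)) {
      stop("structural error: no complex_formation reaction for synthetase '",
           syn, "'")
    }
    entries <- list()
    entries[[form]] <- mu_coef(const = 1)
    for (r in by_syn[[syn]]) entries[[r$id]] <- scale_mu_coef(coef, -1)
    model <- add_coupling_row(model, paste0("synthetase_", syn), entries)
  }
  model
}

#' @describeIn coupling couple each enzyme complex's formation to its
#'   catalyzed fluxes via \eqn{\mu/k_{eff}}.
#' @export
build_enzyme_coupling <- function(model) {
  p <- model$params
  machinery <- c(model$ribosome_id, model$rnap_id)
  cat_rxns <- Filter(function(r) {
    !is.null(r$catalyst) && !r$catalyst %in% machinery
  }, model$reactions)
  if (length(cat_rxns) == 0L) return(model)
  by_enz <- split(cat_rxns, vapply(cat_rxns, `[[`, "", "catalyst"))
  syn_ids <- unique(unlist(lapply(model$reactions, function(r) r$synthetase)))
  for (enz in setdiff(names(by_enz), syn_ids)) {
    form <- find_formation(model, enz)
    if (is.null(form)) {
      stop("structural error: no complex_formation reaction for enzyme '",
           enz, "'")
    }
    entries <- list()
    entries[[form]] <- mu_coef(const = 1)
    for (r in by_enz[[enz]]) {
      keff <- k_eff_for(p, r$id)
      if (keff <= 0) stop("k_eff for reaction ", r$id, " must be > 0")
      entries[[r$id]] <- mu_coef(mu = -1 / keff)
    }
    model <- add_coupling_row(model, paste0("enzyme_", enz), entries)
  }
  model
}

#' @describeIn coupling couple each tRNA's formation to its charging flux.
#' @export
build_trna_coupling <- function(model) {
  p <- model$params
  charg <- Filter(function(r) r$klass == "tRNA_charging", model$reactions)
  for (r in charg) {
    if (is.null(r$trna)) {
      stop("structural error: charging reaction ", r$id,
           " has no tRNA annotation")
    }
    ct <- p$c_tRNA[[r$trna]]
    if (is.null(ct) || !is.finite(ct)) {
      stop("missing c_tRNA for tRNA ", r$trna)
    }
    form <- Filter(function(x) identical(x$trna, r$trna) &&
                     x$klass == "metabolic", model$reactions)
    if (length(form) == 0L) {
      stop("structural error: no formation reaction annotated for tRNA ",
           r$trna)
    }
    entries <- list()
    entries[[form[[1]]$id]] <- mu_coef(const = 1)
    entries[[r$id]] <- scale_mu_coef(
      dilution_coef(p$kappa_tau, p$r0, ct), -1)
    model <- add_coupling_row(model, paste0("trna_", r$trna), entries)
  }
  model
}

#' @describeIn coupling add the two mRNA rows (formation and degradation)
#'   per mRNA; the degradation coefficient carries a \eqn{1/\mu} term.
#' @export
build_mrna_coupling <- function(model) {
  p <- model$params
  transl <- Filter(function(r) r$klass == "translation", model$reactions)
  for (r in transl) {
    if (is.null(r$mrna)) {
      stop("structural error: translation reaction ", r$id,
           " is not linked to an mRNA")
    }
    mrna <- r$mrna
    form <- Filter(function(x) x$klass == "transcription" &&
                     mrna %in% (model$species[[x$tu]]$encoded_mRNAs %||% character(0)),
                   model$reactions)
    if (length(form) == 0L) {
      stop("structural error: no transcription reaction encodes mRNA ", mrna)
    }
    deg <- Filter(function(x) x$klass == "mRNA_degradation" &&
                    identical(x$mrna, mrna), model$reactions)
    kdeg <- k_deg_for(p, mrna)
    # formation: (mu + kt*r0) / (3*kt*c)
    fc <- dilution_coef(p$kappa_tau, p$r0, 3 * p$c_mRNA)
    entries <- list()
    entries[[form[[1]]$id]] <- mu_coef(const = 1)
    entries[[r$id]] <- scale_mu_coef(fc, -1)
    model <- add_coupling_row(model, paste0("mrna_form_", mrna), entries)
    if (length(deg)) {
      # degradation: kdeg*(mu + kt*r0) / (3*kt*c*mu) = kdeg/(3*kt*c)
      #              + kdeg*r0/(3*c) * (1/mu)
      dc <- mu_coef(const = kdeg / (3 * p$kappa_tau * p$c_mRNA),
                    inv_mu = kdeg * p$r0 / (3 * p$c_mRNA))
      entries <- list()
      entries[[deg[[1]]$id]] <- mu_coef(const = 1)
      entries[[r$id]] <- scale_mu_coef(dc, -1)
      model <- add_coupling_row(model, paste0("mrna_deg_", mrna), entries)
    }
  }
  model
}

#' Apply every expression coupling class present in a model
#'
#' Convenience wrapper calling, in order, [build_ribosome_coupling()],
#' [build_rnap_coupling()], [build_enzyme_coupling()],
#' [build_mrna_coupling()], and — when a tRNA layer is present —
#' [build_trna_coupling()] and [build_synthetase_coupling()].
#'
#' @param model an [me_model()].
#' @return the coupled model.
#' @export
apply_expression_coupling <- function(model) {
  model <- build_ribosome_coupling(model)
  model <- build_rnap_coupling(model)
  model <- build_enzyme_coupling(model)
  model <- build_mrna_coupling(model)
  if (length(reaction_ids(model, "tRNA_charging"))) {
    model <- build_trna_coupling(model)
    model <- build_synthetase_coupling(model)
  }
  model
}
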