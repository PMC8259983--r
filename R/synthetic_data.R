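#' Configuration for the toy ME-network generator
#'
#' The generator emits a small but complete metabolism-and-expression
#' network: nutrient exchanges for all four element classes, a catabolic
#' core with a fermentative route (NAD-cycled, lower yield) and an optional
#' respiratory route (quinone-cycled, heme-dependent, higher yield, O2
#' consuming), amino-acid synthesis, per-gene mRNA/transcription-unit/
#' peptide/complex chains with ribosome and RNA polymerase machinery,
#' coenzyme biosynthesis and charging, a protein-biomass summary and a
#' biomass dilution reaction. All randomness (peptide lengths, amino-acid
#' compositions, metabolic turnover numbers) flows from the single seed.
#'
#' @param n_amino_acids number of amino acids (>= 2; default 5). The second
#'   is sulfur-containing, the third NAD-dependent, and — with two coenzyme
#'   pairs and at least five amino acids — the fifth has a cheap
#'   folate-dependent route and an expensive folate-independent route.
#' @param n_enzymes optional expected enzyme-complex count; validated
#'   against the realized count when given (the realized count is
#'   determined by the flags and lies in 8-15 for default settings).
#' @param include_tRNA_layer add tRNA species, charging reactions and a
#'   synthetase so that every coupling class is exercised (default `FALSE`;
#'   the pipeline fixtures keep the layer off).
#' @param aerobic_branch include the respiratory route with the quinone
#'   coenzyme pair and the heme prosthetic group (default `TRUE`).
#' @param coenzyme_pairs 1 (NAD only) or 2 (NAD + folate).
#' @param nutrient_panel_size minimum panel size; extra non-catabolizable
#'   decoy carbon sources are added beyond the structured panel if needed.
#' @param seed integer RNG seed; fully determines the model.
#' @return a list of class `toy_config`.
#' @export
toy_config <- function(n_amino_acids = 5, n_enzymes = NULL,
                       include_tRNA_layer = FALSE, aerobic_branch = TRUE,
                       coenzyme_pairs = 1, nutrient_panel_size = NULL,
                       seed = 42) {
  if (n_amino_acids < 2) stop("n_amino_acids must be >= 2")
  if (!coenzyme_pairs %in% 1:2) stop("coenzyme_pairs must be 1 or 2")
  structure(list(n_amino_acids = n_amino_acids, n_enzymes = n_enzymes,
                 include_tRNA_layer = include_tRNA_layer,
                 aerobic_branch = aerobic_branch,
                 coenzyme_pairs = coenzyme_pairs,
                 nutrient_panel_size = nutrient_panel_size,
                 seed = as.integer(seed)),
            class = "toy_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

aa_residue_mass <- 0.109   # g/mmol, average residue

#' Generate a toy ME model
#'
#' See [toy_config()] for the network layout. The returned model has all
#' expression couplings applied; the coenzyme activity coupling is left to
#' [identify_coenzymes()] / [apply_coenzyme_coupling()] (or use
#' [toy_cofactor_model()] for the full pipeline). Default exchange bounds
#' encode aerobic glucose minimal media. A self-check verifies the model is
#' feasible at \eqn{\mu = 0} and supports growth before returning.
#'
#' @param config a [toy_config()].
#' @param check run the feasibility/growth self-check (default `TRUE`).
#' @return an [me_model()].
#' @export
generate_toy_me_model <- function(config = toy_config(), check = TRUE) {
  with_seed(config$seed, build_toy_model(config, check))
}

build_toy_model <- function(config, check) {
  n_aa <- config$n_amino_acids
  aer <- config$aerobic_branch
  fol_on <- config$coenzyme_pairs >= 2 && n_aa >= 5
  aa_ids <- paste0("aa_", seq_len(n_aa))
  sp <- list(); rx <- list()
  add_sp <- function(...) {
    s <- me_species(...)
    sp[[s$id]] <<- s
  }
  add_rx <- function(...) {
    r <- me_reaction(...)
    rx[[r$id]] <<- r
  }

  for (m in c("glc", "ac", "cfh", "glcX", "gln", "nX", "pop", "tau", "nh4",
              "pi", "so4", "lac", "prec", "ntp")) {
    add_sp(m, biosynthetic_precursor = (m == "prec"))
  }
  if (aer) add_sp("o2")
  add_sp("nad", role = "coenzyme_uncharged", charged_partner = "nadh",
         biosynthesis_reaction = "R_nadsyn")
  add_sp("nadh", role = "coenzyme_charged")
  if (aer) {
    add_sp("q8", role = "coenzyme_uncharged", charged_partner = "q8h2",
           biosynthesis_reaction = "R_q8syn")
    add_sp("q8h2", role = "coenzyme_charged")
    add_sp("heme", role = "prosthetic_group")
  }
  if (fol_on) {
    add_sp("fol", role = "coenzyme_uncharged", charged_partner = "folh",
           biosynthesis_reaction = "R_folsyn")
    add_sp("folh", role = "coenzyme_charged")
  }
  add_sp("thm", role = "prosthetic_group")
  for (a in aa_ids) add_sp(a)
  add_sp("protein_biomass", role = "biomass_pool")
  add_sp("biomass", role = "biomass_pool")

  # ---- exchanges; defaults encode aerobic glucose minimal media ---------
  ex_open <- function(id, met, lim) {
    st <- list(); st[[met]] <- -1
    add_rx(id, klass = "exchange", stoich = st, lb = -lim, ub = 1000)
  }
  ex_closed <- function(id, met) {
    st <- list(); st[[met]] <- -1
    add_rx(id, klass = "exchange", stoich = st, lb = 0, ub = 1000)
  }
  # nitrogen is supplied generously so that carbon limits growth on the
  # base media; the respiratory/fermentative yield difference then shows
  ex_open("EX_glc", "glc", 10)
  ex_open("EX_nh4", "nh4", 30)
  ex_open("EX_pi", "pi", 10)
  ex_open("EX_so4", "so4", 10)
  if (aer) ex_open("EX_o2", "o2", 20)
  ex_closed("EX_lac", "lac")
  decoys <- c("glcX", "nX")
  panel_nutrients <- c("glc", "ac", "cfh", "glcX", "nh4", "gln", "nX",
                       "pi", "pop", "so4", "tau")
  extra <- 0L
  if (!is.null(config$nutrient_panel_size)) {
    extra <- max(0L, config$nutrient_panel_size - length(panel_nutrients))
  }
  extra_ids <- if (extra > 0) paste0("decoy_", seq_len(extra)) else character(0)
  for (m in extra_ids) add_sp(m)
  for (m in c("ac", "cfh", "glcX", "gln", "nX", "pop", "tau", extra_ids)) {
    ex_closed(paste0("EX_", m), m)
  }
  ex_closed("EX_nad", "nad")
  if (fol_on) ex_closed("EX_fol", "fol")
  ex_closed("EX_aa_1", "aa_1")

  # ---- catabolic core ---------------------------------------------------
  add_rx("R_gly", stoich = list(glc = -1, nad = -1, prec = 1.8, nadh = 1),
         catalyst = "E_gly", subsystem = "glycolysis")
  if (aer) {
    add_rx("R_glyox",
           stoich = list(glc = -1, q8 = -2, prec = 2, q8h2 = 2),
           catalyst = "E_gly", subsystem = "glycolysis")
    add_rx("R_ndh", stoich = list(nadh = -1, q8 = -1, nad = 1, q8h2 = 1),
           catalyst = "E_ndh", subsystem = "respiration")
    add_rx("R_cyox", stoich = list(q8h2 = -1, o2 = -0.5, q8 = 1),
           catalyst = "E_cyox", subsystem = "respiration")
  }
  add_rx("R_ferm", stoich = list(prec = -1, nadh = -1, nad = 1, lac = 1),
         catalyst = "E_ferm", subsystem = "fermentation")
  add_rx("R_accat", stoich = list(ac = -1, nad = -1, prec = 0.9, nadh = 1),
         catalyst = "E_cat", subsystem = "alternative_catabolism")
  add_rx("R_cfhcat", stoich = list(cfh = -1, nad = -3, prec = 2, nadh = 3),
         catalyst = "E_cat", subsystem = "alternative_catabolism")
  add_rx("R_glncat", stoich = list(gln = -1, nh4 = 1),
         catalyst = "E_cat", subsystem = "alternative_catabolism")
  add_rx("R_popcat", stoich = list(pop = -1, pi = 1),
         catalyst = "E_cat", subsystem = "alternative_catabolism")
  add_rx("R_taucat", stoich = list(tau = -1, so4 = 1),
         catalyst = "E_cat", subsystem = "alternative_catabolism")

  # ---- cofactor biosynthesis -------------------------------------------
  add_rx("R_nadsyn", stoich = list(prec = -1, nh4 = -1, nad = 1),
         catalyst = "E_cofA", subsystem = "cofactor_biosynthesis")
  if (aer) {
    add_rx("R_q8syn", stoich = list(prec = -1, q8 = 1),
           catalyst = "E_cofA", subsystem = "cofactor_biosynthesis")
    add_rx("R_hemsyn", stoich = list(prec = -1, heme = 1),
           catalyst = "E_cofA", subsystem = "cofactor_biosynthesis")
  }
  add_rx("R_thmsyn", stoich = list(prec = -1, so4 = -1, thm = 1),
         catalyst = "E_cofB", subsystem = "cofactor_biosynthesis")
  if (fol_on) {
    add_rx("R_folsyn", stoich = list(prec = -1, nh4 = -1, fol = 1),
           catalyst = "E_cofB", subsystem = "cofactor_biosynthesis")
    add_rx("R_folchg", klass = "coenzyme_charging",
           stoich = list(fol = -1, prec = -1, folh = 1),
           catalyst = "E_fol", subsystem = "one_carbon")
  }

  # ---- amino-acid and nucleotide synthesis ------------------------------
  aa_enzymes <- character(0)
  for (i in seq_len(n_aa)) {
    id <- paste0("R_aa_", i)
    enz <- paste0("E_aa_", i)
    st <- list(prec = -1, nh4 = -1)
    st[[aa_ids[[i]]]] <- 1
    if (i == 2) st$so4 <- -1
    if (i == 3) { st$nad <- -1; st$nadh <- 1 }
    if (i == 5 && fol_on) {
      add_rx("R_aa_5a", stoich = list(prec = -1, folh = -1, aa_5 = 1,
                                      fol = 1),
             catalyst = "E_aa5a", subsystem = "one_carbon")
      # backup route: much cheaper in folate carrier, expensive in carbon,
      # so folate limitation drives a route switch without relieving the
      # folate requirement entirely
      add_rx("R_aa_5b", stoich = list(prec = -3, nh4 = -1, folh = -0.1,
                                      aa_5 = 1, fol = 0.1),
             catalyst = "E_aa5b",
             subsystem = "amino_acid_biosynthesis")
      aa_enzymes <- c(aa_enzymes, "E_aa5a", "E_aa5b")
      next
    }
    add_rx(id, stoich = st, catalyst = enz,
           subsystem = "amino_acid_biosynthesis")
    aa_enzymes <- c(aa_enzymes, enz)
  }
  add_rx("R_ntps", stoich = list(prec = -1, pi = -1, nh4 = -1, ntp = 1),
         catalyst = "E_ntps", subsystem = "nucleotide_biosynthesis")

  # ---- expression machinery ---------------------------------------------
  enzymes <- c("E_gly", "E_ferm", if (aer) c("E_ndh", "E_cyox"), "E_cat",
               "E_cofA", "E_cofB", if (fol_on) "E_fol", aa_enzymes,
               "E_ntps")
  trna_on <- config$include_tRNA_layer
  genes <- c(enzymes, if (trna_on) "E_synth", "ribosome", "rnap",
             "E_struct")
  lengths <- stats::setNames(
    c(sample(250:450, length(enzymes), replace = TRUE),
      if (trna_on) 350, 2000, 1000, 400), genes)
  prosthetics <- list(E_gly = c(thm = 1))
  if (aer) prosthetics$E_cyox <- c(heme = 2)
  subsys <- stats::setNames(rep("expression_machinery", length(genes)),
                            genes)
  subsys["E_struct"] <- "structural_protein"
  k_deg <- numeric(0)
  for (g in genes) {
    l <- lengths[[g]]
    comp <- stats::setNames(
      as.vector(stats::rmultinom(1, l - n_aa,
                                 prob = stats::runif(n_aa) + 0.5)) + 1L,
      aa_ids)
    l_tu <- 3L * l + 60L
    role <- if (g == "E_synth") "synthetase" else "enzyme_complex"
    add_sp(g, role = role, molecular_weight = aa_residue_mass * l,
           subsystem = subsys[[g]])
    add_sp(paste0("pep_", g), role = "peptide", length = l,
           composition = comp, part_of = stats::setNames(1, g))
    add_sp(paste0("mrna_", g), role = "mRNA")
    add_sp(paste0("tu_", g), role = "transcription_unit", length = l_tu,
           encoded_mRNAs = paste0("mrna_", g))
    add_rx(paste0("R_tsc_", g), klass = "transcription",
           stoich = list(ntp = -l_tu), tu = paste0("tu_", g),
           subsystem = "expression")
    tsl <- stats::setNames(as.list(-as.numeric(comp)),
                           if (trna_on) paste0("ctrna_", seq_len(n_aa))
                           else aa_ids)
    tsl[[paste0("pep_", g)]] <- 1
    add_rx(paste0("R_tsl_", g), klass = "translation", stoich = tsl,
           peptide = paste0("pep_", g), mrna = paste0("mrna_", g),
           subsystem = "expression")
    add_rx(paste0("R_degr_", g), klass = "mRNA_degradation",
           stoich = list(), mrna = paste0("mrna_", g),
           subsystem = "expression")
    fst <- list()
    fst[[paste0("pep_", g)]] <- -1
    if (g %in% names(prosthetics)) {
      for (p in names(prosthetics[[g]])) {
        fst[[p]] <- -prosthetics[[g]][[p]]
      }
    }
    fst[["protein_biomass"]] <- aa_residue_mass * l
    add_rx(paste0("R_form_", g), klass = "complex_formation", stoich = fst,
           complex = g, subsystem = subsys[[g]])
    k_deg[paste0("mrna_", g)] <- if (g == "E_struct") 4 else 8
  }

  c_trna <- numeric(0)
  if (trna_on) {
    for (i in seq_len(n_aa)) {
      tr <- paste0("trna_", i)
      add_sp(tr, role = "tRNA")
      add_sp(paste0("ctrna_", i), role = "charged_tRNA")
      add_rx(paste0("R_trnasyn_", i), stoich = list(ntp = -25),
             trna = tr, subsystem = "expression")
      chst <- list()
      chst[[aa_ids[[i]]]] <- -1
      chst[[paste0("ctrna_", i)]] <- 1
      add_rx(paste0("R_chg_", i), klass = "tRNA_charging", stoich = chst,
             synthetase = "E_synth", trna = tr, subsystem = "expression")
      c_trna[tr] <- 0.5
    }
  }

  # ---- summaries --------------------------------------------------------
  add_rx("biomass_constituent_demand", klass = "demand",
         stoich = list(nad = -1, thm = -0.2), lb = 0, ub = 0.01)
  f_unmod <- 0
  add_rx("protein_biomass_to_biomass", klass = "summary",
         stoich = list(protein_biomass = -1 / (1 - f_unmod), biomass = 1))
  add_rx("biomass_dilution", klass = "biomass_dilution",
         stoich = list(biomass = -1), lb = mu_coef(mu = 1),
         ub = mu_coef(mu = 1))

  # metabolic turnover numbers: moderate, seeded; the oxidative glycolytic
  # step is the designated high-turnover reaction (1500 1/s)
  met_rxns <- setdiff(
    names(Filter(function(r) !is.null(r$catalyst) &&
                   !identical(r$catalyst, "E_cat"), rx)),
    "R_glyox")
  keff <- stats::setNames(
    per_second(exp(stats::runif(length(met_rxns), log(10), log(60)))),
    met_rxns)
  if (aer) keff["R_glyox"] <- per_second(1500)
  params <- coupling_params(k_eff_overrides = keff, k_deg = k_deg,
                            c_tRNA = as.list(c_trna),
                            unmodeled_protein_fraction = f_unmod)

  nx <- data.frame(
    nutrient_id = c(panel_nutrients, extra_ids),
    element_class = c("C", "C", "C", "C", "N", "N", "N", "P", "P", "S",
                      "S", rep("C", length(extra_ids))),
    exchange_id = paste0("EX_", c(panel_nutrients, extra_ids)),
    stringsAsFactors = FALSE)

  model <- me_model(
    species = sp, reactions = rx, params = params,
    biomass_dilution_id = "biomass_dilution",
    protein_biomass_summary_id = "protein_biomass_to_biomass",
    ribosome_id = "ribosome", rnap_id = "rnap",
    bof_members = c(aa_ids, "nad", "thm", if (aer) c("q8", "heme"),
                    if (fol_on) "folh"),
    nutrient_exchanges = nx)
  model <- apply_expression_coupling(model)
  if (check) {
    if (!feasible_at_mu(model, 0)$feasible) {
      stop("generator self-check failed: model infeasible at mu = 0")
    }
    sol <- maximize_growth(model, tol = 1e-2)
    if (is.na(sol$mu_opt) || sol$mu_opt <= 1e-2) {
      stop("generator self-check failed: model does not support growth")
    }
  }
  model
}

#' Base media of a toy model
#'
#' Aerobic (or anaerobic) glucose minimal media: glucose, ammonium,
#' phosphate and sulfate open at `uptake`, every alternative nutrient
#' closed, fermentation products secretable, O2 open only when aerobic.
#'
#' @param model a [generate_toy_me_model()] output.
#' @param aerobic logical.
#' @param uptake uptake bound of the carbon, phosphorus and sulfur base
#'   sources, mmol/gDW/h; nitrogen is opened at three times this so that
#'   carbon limits growth on the base media.
#' @param o2_uptake O2 uptake bound under aerobic conditions.
#' @return a [media_condition()].
#' @export
toy_base_media <- function(model, aerobic = TRUE, uptake = 10,
                           o2_uptake = 20) {
  ex <- reaction_ids(model, "exchange")
  bounds <- stats::setNames(rep(list(c(0, 1000)), length(ex)), ex)
  for (b in c("EX_glc", "EX_pi", "EX_so4")) {
    bounds[[b]] <- c(-uptake, 1000)
  }
  bounds[["EX_nh4"]] <- c(-3 * uptake, 1000)
  has_o2 <- "EX_o2" %in% ex
  if (has_o2) bounds[["EX_o2"]] <- c(if (aerobic) -o2_uptake else 0, 1000)
  media_condition(
    condition_id = paste0("glc_base_",
                          if (aerobic) "aerobic" else "anaerobic"),
    exchange_bounds = bounds, aerobic = aerobic, element_class = "C",
    nutrient_id = "glc",
    sources = c(C = "glc", N = "nh4", P = "pi", S = "so4"),
    o2_exchange = if (has_o2) "EX_o2" else NULL)
}

#' Toy model with the full cofactor pipeline applied
#'
#' Convenience constructor running [generate_toy_me_model()],
#' [identify_coenzymes()], [apply_coenzyme_coupling()] and
#' [zero_biomass_constituent_demand()] in sequence.
#'
#' @param config a [toy_config()].
#' @param k_activity coenzyme activity rate, 1/h.
#' @param check forwarded to the generator.
#' @return an [me_model()] with `model$coenzymes` populated.
#' @export
toy_cofactor_model <- function(config = toy_config(), k_activity = 1e4,
                               check = TRUE) {
  model <- generate_toy_me_model(config, check = check)
  cz <- identify_coenzymes(model)
  model <- apply_coenzyme_coupling(model, cz, k_activity = k_activity)
  zero_biomass_constituent_demand(model)
}

#' The one-enzyme analytic fixture
#'
#' A single substrate taken up at rate at most `U` feeds a biomass dilution
#' reaction catalyzed by one enzyme of cost `c_cost` substrate units per
#' complex with turnover `k_eff`. The balances \eqn{U = \mu + c\mu^2/k_{eff}}
#' give the closed-form optimum
#' \deqn{\mu^* = \frac{k_{eff}\left(-1 + \sqrt{1 + 4cU/k_{eff}}\right)}{2c},}
#' available as [one_enzyme_mu_star()], making the fixture an exact oracle
#' for the bisection solver.
#'
#' @param U uptake bound, mmol/gDW/h.
#' @param c_cost substrate units consumed per enzyme complex formed.
#' @param k_eff enzyme turnover, 1/h.
#' @return an [me_model()] with the enzyme coupling applied.
#' @export
one_enzyme_model <- function(U = 10, c_cost = 2, k_eff = 500) {
  sp <- list(
    aa = me_species("aa"),
    pb = me_species("pb", role = "biomass_pool"),
    b = me_species("b", role = "biomass_pool"))
  rx <- list(
    EX_aa = me_reaction("EX_aa", klass = "exchange",
                        stoich = list(aa = -1), lb = -U, ub = 0),
    R_form_E = me_reaction("R_form_E", klass = "complex_formation",
                           stoich = list(aa = -c_cost,
                                         pb = aa_residue_mass * c_cost),
                           complex = "E", subsystem = "core"),
    pb_summary = me_reaction("pb_summary", klass = "summary",
                             stoich = list(pb = -1, b = 1), lb = 0,
                             ub = 1000),
    DM_b = me_reaction("DM_b", klass = "demand", stoich = list(b = -1),
                       lb = 0, ub = 1000),
    biomass_dilution = me_reaction("biomass_dilution",
                                   klass = "biomass_dilution",
                                   stoich = list(aa = -1),
                                   lb = mu_coef(mu = 1),
                                   ub = mu_coef(mu = 1),
                                   catalyst = "E", subsystem = "core"))
  sp$E <- me_species("E", role = "enzyme_complex",
                     molecular_weight = aa_residue_mass * c_cost,
                     subsystem = "core")
  params <- coupling_params(
    k_eff_overrides = stats::setNames(k_eff, "biomass_dilution"))
  m <- me_model(sp, rx, params, biomass_dilution_id = "biomass_dilution",
                protein_biomass_summary_id = "pb_summary")
  build_enzyme_coupling(m)
}

#' @rdname one_enzyme_model
#' @export
one_enzyme_mu_star <- function(U, c_cost, k_eff) {
  k_eff * (-1 + sqrt(1 + 4 * c_cost * U / k_eff)) / (2 * c_cost)
}

#' Generate the toy condition panel
#'
#' The panel covers every nutrient with an exchange in the model's
#' nutrient map: at least two alternatives per element class, at least one
#' non-catabolizable decoy, and the cofactor-heavy carbon source whose
#' catabolism cycles three NAD per substrate (the planted composition
#' outlier).
#'
#' @param model a [generate_toy_me_model()] output.
#' @return data.frame with columns `nutrient_id`, `element_class`.
#' @export
generate_condition_panel <- function(model) {
  nx <- model$nutrient_exchanges
  if (is.null(nx)) stop("model carries no nutrient_exchanges table")
  nx[, c("nutrient_id", "element_class")]
}

#' Generate a synthetic demand table with planted structure
#'
#' Log-normal condition x component tables with known cluster labels,
#' per-group component shifts and optional planted outlier cells, for
#' exercising the composition statistics against ground truth.
#'
#' @param n_conditions,n_components table dimensions.
#' @param cluster_spec list with elements `k` (groups, round-robin
#'   assigned), `shift_log2` (log2 shift applied to each group's designated
#'   components), `components_per_group` (how many components each group
#'   shifts; group g shifts components `(g-1)*cpg + 1:cpg`), `noise_sd`
#'   (log2-scale Gaussian noise), and optionally `outlier_cells`, a
#'   data.frame with columns `condition`, `component`, `log2_shift`.
#' @param seed RNG seed.
#' @return numeric matrix with attributes `labels` (true cluster labels)
#'   and `shifted_components` (list per group).
#' @export
generate_composition_table <- function(n_conditions, n_components,
                                       cluster_spec = list(), seed = 1) {
  spec <- utils::modifyList(
    list(k = 1, shift_log2 = 0, components_per_group = 1, noise_sd = 0.1,
         outlier_cells = NULL), cluster_spec)
  with_seed(seed, {
    base <- stats::runif(n_components, -2, 2)
    labels <- rep(seq_len(spec$k), length.out = n_conditions)
    lg <- matrix(rep(base, each = n_conditions), n_conditions, n_components)
    shifted <- list()
    if (spec$k > 1 || spec$shift_log2 != 0) {
      for (g in seq_len(spec$k)) {
        cols <- (g - 1) * spec$components_per_group +
          seq_len(spec$components_per_group)
        cols <- cols[cols <= n_components]
        shifted[[g]] <- cols
        lg[labels == g, cols] <- lg[labels == g, cols] + spec$shift_log2
      }
    }
    if (spec$noise_sd > 0) {
      lg <- lg + matrix(stats::rnorm(length(lg), sd = spec$noise_sd),
                        nrow(lg))
    }
    oc <- spec$outlier_cells
    if (!is.null(oc)) {
      for (i in seq_len(nrow(oc))) {
        lg[oc$condition[[i]], oc$component[[i]]] <-
          lg[oc$condition[[i]], oc$component[[i]]] + oc$log2_shift[[i]]
      }
    }
    m <- 2^lg
    dimnames(m) <- list(paste0("cond_", seq_len(n_conditions)),
                        paste0("comp_", seq_len(n_components)))
    structure(m, labels = stats::setNames(labels, rownames(m)),
              shifted_components = shifted)
  })
}
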