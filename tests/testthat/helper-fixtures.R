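# Shared fixtures are built once per test run and memoized; everything is
# generated in code from fixed seeds.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# full respiratory toy with both coenzyme pairs and the cofactor pipeline
toy_full <- function() {
  fixture("toy_full", function() {
    toy_cofactor_model(toy_config(seed = 1, coenzyme_pairs = 2),
                       check = FALSE)
  })
}

# small anaerobic-only toy (fast LP) for solver-heavy tests
toy_small <- function() {
  fixture("toy_small", function() {
    toy_cofactor_model(toy_config(seed = 3, n_amino_acids = 3,
                                  aerobic_branch = FALSE,
                                  coenzyme_pairs = 1), check = FALSE)
  })
}

toy_full_base <- function(aerobic = TRUE) {
  fixture(paste0("toy_full_base_", aerobic), function() {
    m <- toy_full()
    apply_media(m, toy_base_media(m, aerobic = aerobic))
  })
}

toy_full_solution <- function(aerobic = TRUE) {
  fixture(paste0("toy_full_sol_", aerobic), function() {
    maximize_growth(toy_full_base(aerobic), tol = 1e-6)
  })
}

toy_full_scan <- function() {
  fixture("toy_full_scan", function() {
    m <- toy_full()
    scan_conditions(m, generate_condition_panel(m),
                    toy_base_media(m, aerobic = TRUE))
  })
}

fol_auxotroph <- function() {
  fixture("fol_auxotroph", function() {
    make_auxotroph(toy_full_base(TRUE), "fol", "R_folsyn")
  })
}

fol_profile_coarse <- function() {
  fixture("fol_profile_coarse", function() {
    limitation_profile(fol_auxotroph(), fractions = c(1, 0.7, 0.4, 0.1),
                       tol = 1e-6)
  })
}

# ---- independent oracles -------------------------------------------------

# exact two-sided rank-sum p-value by complete enumeration of group
# assignments (no ties assumed), mirroring the two-sided rule of the
# exact Mann-Whitney test
perm_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  m <- length(x)
  r <- rank(pooled)
  stat <- function(idx) sum(r[idx]) - m * (m + 1) / 2
  obs <- stat(seq_len(m))
  combs <- utils::combn(n, m)
  ws <- apply(combs, 2, stat)
  p_le <- mean(ws <= obs)
  p_ge <- mean(ws >= obs)
  min(1, 2 * min(p_le, p_ge))
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

# brute-force growth maximization: step a mu-grid upward until infeasible
grid_mu_star <- function(model, delta = 1e-3, mu_max = 4) {
  mu <- 0
  repeat {
    nxt <- mu + delta
    if (nxt > mu_max) break
    if (!feasible_at_mu(model, nxt)$feasible) break
    mu <- nxt
  }
  mu
}

# minimal single-gene expression model for inspecting coupling coefficients
mini_expression_model <- function(params = coupling_params(), l_p = 300,
                                  l_tu = 3 * l_p + 60, kdeg = NULL) {
  if (!is.null(kdeg)) params$k_deg <- c(mrna_g = kdeg)
  sp <- list(
    me_species("aa"), me_species("ntp"),
    me_species("pep_g", role = "peptide", length = l_p,
               composition = c(aa = l_p)),
    me_species("mrna_g", role = "mRNA"),
    me_species("tu_g", role = "transcription_unit", length = l_tu,
               encoded_mRNAs = "mrna_g"),
    me_species("rib", role = "enzyme_complex"),
    me_species("rnap", role = "enzyme_complex"),
    me_species("pb", role = "biomass_pool"),
    me_species("b", role = "biomass_pool"))
  rx <- list(
    me_reaction("R_form_rib", klass = "complex_formation",
                stoich = list(pb = 0.1), complex = "rib"),
    me_reaction("R_form_rnap", klass = "complex_formation",
                stoich = list(pb = 0.1), complex = "rnap"),
    me_reaction("R_tsl_g", klass = "translation",
                stoich = list(aa = -l_p, pep_g = 1),
                peptide = "pep_g", mrna = "mrna_g"),
    me_reaction("R_tsc_g", klass = "transcription",
                stoich = list(ntp = -l_tu), tu = "tu_g"),
    me_reaction("R_degr_g", klass = "mRNA_degradation", stoich = list(),
                mrna = "mrna_g"),
    me_reaction("R_use_pep", stoich = list(pep_g = -1, pb = 1)),
    me_reaction("pb_summary", klass = "summary",
                stoich = list(pb = -1, b = 1)),
    me_reaction("DM_b", klass = "demand", stoich = list(b = -1)),
    me_reaction("biomass_dilution", klass = "biomass_dilution",
                stoich = list(b = -1), lb = mu_coef(mu = 1),
                ub = mu_coef(mu = 1)))
  me_model(sp, rx, params, biomass_dilution_id = "biomass_dilution",
           protein_biomass_summary_id = "pb_summary",
           ribosome_id = "rib", rnap_id = "rnap")
}

coef_at <- function(model, species_row, reaction, mu) {
  num <- evaluate_at_mu(model, mu)
  num$S[species_row, reaction]
}
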