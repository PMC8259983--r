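pars_paper_check <- coupling_params(kappa_tau = 4.5, r0 = 0.087,
                                    c_ribo = 0.25, c_mRNA = 1)

test_that("ribosome coupling coefficient matches the dilution-coupled form", {
  m <- build_ribosome_coupling(mini_expression_model(pars_paper_check))
  # l_p (mu + r0*kt) / (c_ribo*kt) at l_p = 300, mu = 1
  expect_equal(-coef_at(m, "coupling__ribosome", "R_tsl_g", 1),
               300 * (1 + 0.087 * 4.5) / (0.25 * 4.5), tolerance = 1e-12)
  # mu = 0 limit: l_p * r0 / c_ribo
  expect_equal(-coef_at(m, "coupling__ribosome", "R_tsl_g", 0),
               300 * 0.087 / 0.25, tolerance = 1e-12)
  expect_equal(coef_at(m, "coupling__ribosome", "R_form_rib", 1), 1)
  # linear in peptide length
  m2 <- build_ribosome_coupling(
    mini_expression_model(pars_paper_check, l_p = 600))
  expect_equal(coef_at(m2, "coupling__ribosome", "R_tsl_g", 0.7),
               2 * coef_at(m, "coupling__ribosome", "R_tsl_g", 0.7))
})

test_that("RNAP coupling carries the factor-3 symmetry with the ribosome", {
  m <- mini_expression_model(pars_paper_check, l_p = 300, l_tu = 900)
  m <- build_ribosome_coupling(build_rnap_coupling(m))
  expect_equal(-coef_at(m, "coupling__rnap", "R_tsc_g", 1),
               900 * (1 + 0.087 * 4.5) / (3 * 0.25 * 4.5),
               tolerance = 1e-12)
  # l_TU = 3 l_p makes the two coefficients coincide at any mu
  for (mu in c(0, 0.4, 1, 2.3)) {
    expect_equal(coef_at(m, "coupling__rnap", "R_tsc_g", mu),
                 coef_at(m, "coupling__ribosome", "R_tsl_g", mu))
  }
  expect_equal(-coef_at(m, "coupling__rnap", "R_tsc_g", 0),
               900 * 0.087 / (3 * 0.25))
})

test_that("mRNA formation and degradation rows have the printed ratio", {
  m <- mini_expression_model(pars_paper_check, kdeg = 12)
  m <- build_mrna_coupling(m)
  fc <- -coef_at(m, "coupling__mrna_form_mrna_g", "R_tsl_g", 1)
  dc <- -coef_at(m, "coupling__mrna_deg_mrna_g", "R_tsl_g", 1)
  expect_equal(fc, (1 + 4.5 * 0.087) / (3 * 4.5 * 1), tolerance = 1e-12)
  expect_equal(dc, 12 * (1 + 4.5 * 0.087) / (3 * 4.5 * 1 * 1),
               tolerance = 1e-12)
  # ratio degradation / formation = k_deg / mu at any mu > 0
  for (mu in c(0.25, 1, 3)) {
    r <- coef_at(m, "coupling__mrna_deg_mrna_g", "R_tsl_g", mu) /
      coef_at(m, "coupling__mrna_form_mrna_g", "R_tsl_g", mu)
    expect_equal(r, 12 / mu, tolerance = 1e-10)
  }
  # stable mRNA: degradation coefficient identically 0
  m0 <- build_mrna_coupling(mini_expression_model(pars_paper_check,
                                                  kdeg = 0))
  expect_equal(coef_at(m0, "coupling__mrna_deg_mrna_g", "R_tsl_g", 0.8), 0)
})

test_that("enzyme coupling uses mu/k_eff with per-reaction overrides", {
  sp <- list(me_species("s"), me_species("E", role = "enzyme_complex"),
             me_species("pb", role = "biomass_pool"),
             me_species("b", role = "biomass_pool"))
  rx <- list(
    me_reaction("Ra", stoich = list(s = -1), catalyst = "E"),
    me_reaction("Rb", stoich = list(s = 1), catalyst = "E"),
    me_reaction("R_form_E", klass = "complex_formation",
                stoich = list(pb = 0.1), complex = "E"),
    me_reaction("pb_summary", klass = "summary",
                stoich = list(pb = -1, b = 1)),
    me_reaction("biomass_dilution", klass = "biomass_dilution",
                stoich = list(b = -1), lb = mu_coef(mu = 1),
                ub = mu_coef(mu = 1)))
  pars <- coupling_params(
    k_eff_overrides = c(Ra = per_second(1500)))  # high-turnover step
  m <- build_enzyme_coupling(
    me_model(sp, rx, pars, biomass_dilution_id = "biomass_dilution",
             protein_biomass_summary_id = "pb_summary"))
  expect_equal(-coef_at(m, "coupling__enzyme_E", "Ra", 1), 1 / 5.4e6,
               tolerance = 1e-12)
  expect_equal(-coef_at(m, "coupling__enzyme_E", "Rb", 1),
               1 / per_second(65), tolerance = 1e-12)
  # zero growth, zero formation demand
  expect_equal(coef_at(m, "coupling__enzyme_E", "Ra", 0), 0)
  expect_equal(coef_at(m, "coupling__enzyme_E", "Rb", 0), 0)
  # two reactions sharing one enzyme: the formation row sums both terms
  num <- evaluate_at_mu(m, 2)
  v <- c(Ra = 3, Rb = 5)
  expect_equal(num$S["coupling__enzyme_E", "R_form_E"], 1)
  needed <- 2 / 5.4e6 * v[["Ra"]] + 2 / per_second(65) * v[["Rb"]]
  row <- num$S["coupling__enzyme_E", ]
  expect_equal(-(row[["Ra"]] * v[["Ra"]] + row[["Rb"]] * v[["Rb"]]), needed)
})

test_that("tRNA and synthetase couplings follow the charging fluxes", {
  trna_toy <- fixture("toy_trna", function() {
    generate_toy_me_model(toy_config(seed = 5, n_amino_acids = 2,
                                     aerobic_branch = FALSE,
                                     include_tRNA_layer = TRUE),
                          check = FALSE)
  })
  num <- evaluate_at_mu(trna_toy, 1)
  # synthetase: (1 + mu/k_tRNA)(mu/k_charging), defaults 65 1/s -> 234000/h
  expect_equal(-num$S["coupling__synthetase_E_synth", "R_chg_1"],
               (1 + 1 / 234000) * (1 / 234000), tolerance = 1e-15)
  expect_equal(num$S["coupling__synthetase_E_synth", "R_form_E_synth"], 1)
  # vanishes as mu -> 0, strictly increasing in mu
  prev <- -coef_at(trna_toy, "coupling__synthetase_E_synth", "R_chg_1",
                   1e-8)
  expect_lt(prev, 1e-12)
  for (mu in c(0.5, 1, 2, 4)) {
    cur <- -coef_at(trna_toy, "coupling__synthetase_E_synth", "R_chg_1", mu)
    expect_gt(cur, prev)
    prev <- cur
  }
  # tRNA row: (mu + kt*r0)/(kt*c_tRNA), generator c_tRNA = 0.5
  expect_equal(-num$S["coupling__trna_trna_1", "R_chg_1"],
               (1 + 4.5 * 0.087) / (4.5 * 0.5), tolerance = 1e-12)
  expect_equal(-coef_at(trna_toy, "coupling__trna_trna_1", "R_chg_1", 1e-9),
               0.087 / 0.5, tolerance = 1e-8)
  # inverse proportionality in c_tRNA
  half <- trna_toy
  half$params$c_tRNA <- lapply(half$params$c_tRNA, `*`, 2)
  half$species[["coupling__trna_trna_1"]] <- NULL
  half$reactions <- lapply(half$reactions, function(r) {
    r$stoich[["coupling__trna_trna_1"]] <- NULL
    r
  })
  half <- build_trna_coupling(half)
  expect_equal(-coef_at(half, "coupling__trna_trna_1", "R_chg_1", 1),
               0.5 * (1 + 4.5 * 0.087) / (4.5 * 0.5), tolerance = 1e-12)
})

test_that("evaluate_at_mu is deterministic, affine and singular at mu=0", {
  m <- toy_small()
  n1 <- evaluate_at_mu(m, 0.5)
  n2 <- evaluate_at_mu(m, 0.5)
  expect_identical(n1, n2)
  # an affine coefficient a + b*mu evaluated at mu = 2 equals a + 2b
  mm <- build_ribosome_coupling(mini_expression_model(pars_paper_check))
  a <- coef_at(mm, "coupling__ribosome", "R_tsl_g", 0)
  b <- (coef_at(mm, "coupling__ribosome", "R_tsl_g", 1) - a)
  expect_equal(coef_at(mm, "coupling__ribosome", "R_tsl_g", 2), a + 2 * b)
  # mu = 0 with an active 1/mu term names the offending reaction
  expect_error(evaluate_at_mu(m, 0), "singularity.*R_tsl")
})

test_that("a hand-assembled fixture matrix is reproduced exactly", {
  m <- one_enzyme_model(U = 10, c_cost = 2, k_eff = 500)
  num <- evaluate_at_mu(m, 0.5)
  rx <- c("EX_aa", "R_form_E", "pb_summary", "DM_b", "biomass_dilution")
  expected <- matrix(0, 4, 5, dimnames = list(
    c("aa", "pb", "b", "coupling__enzyme_E"), rx))
  expected["aa", "EX_aa"] <- -1
  expected["aa", "R_form_E"] <- -2
  expected["aa", "biomass_dilution"] <- -1
  expected["pb", "R_form_E"] <- 0.109 * 2
  expected["pb", "pb_summary"] <- -1
  expected["b", "pb_summary"] <- 1
  expected["b", "DM_b"] <- -1
  expected["coupling__enzyme_E", "R_form_E"] <- 1
  expected["coupling__enzyme_E", "biomass_dilution"] <- -0.5 / 500
  expect_equal(num$S[rownames(expected), rx], expected)
  expect_equal(unname(num$lb[["biomass_dilution"]]), 0.5)
  expect_equal(unname(num$ub[["biomass_dilution"]]), 0.5)
})

test_that("structural validation catches malformed models", {
  expect_error(me_species("p", role = "peptide", length = 10,
                          composition = c(a = 3, b = 3)),
               "sums to")
  expect_error(me_species("x", molecular_weight = -1), "molecular_weight")
  expect_error(me_reaction("EX", klass = "exchange",
                           stoich = list(a = -1, b = 1)),
               "exactly one species")
  m <- toy_small()
  m$reactions[["bad"]] <- me_reaction("bad", stoich = list(nope = -1))
  expect_error(validate_me_model(m), "unknown species: nope")
  m2 <- toy_small()
  m2$reactions[["R_form_ribosome"]] <- NULL
  expect_error(build_ribosome_coupling(m2), "ribosome")
  expect_error(coupling_params(k_eff_default = -1), "> 0")
  expect_error(coupling_params(unmodeled_protein_fraction = 1), "0, 1")
})

test_that("JSON round trip reproduces the numeric LP bit-identically", {
  m <- toy_full()
  path <- withr::local_tempfile(fileext = ".json")
  write_me_model(m, path)
  m2 <- read_me_model(path)
  for (mu in c(0.3, 1, 1.7)) {
    n1 <- evaluate_at_mu(m, mu)
    n2 <- evaluate_at_mu(m2, mu)
    expect_identical(n1$S[rownames(n1$S), colnames(n1$S)],
                     n2$S[rownames(n1$S), colnames(n1$S)])
    expect_identical(n1$lb, n2$lb)
    expect_identical(n1$ub, n2$ub)
  }
  # re-serialization is byte-stable
  path2 <- withr::local_tempfile(fileext = ".json")
  write_me_model(m2, path2)
  expect_identical(readLines(path), readLines(path2))
})
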