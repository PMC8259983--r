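test_that("coenzyme identification applies both selection criteria", {
  m <- generate_toy_me_model(toy_config(seed = 1, coenzyme_pairs = 2),
                             check = FALSE)
  cz <- identify_coenzymes(m)
  # deterministic id order; q8 present because the aerobic branch is on
  expect_equal(vapply(cz, `[[`, "", "id"), c("fol", "nad", "q8"))
  expect_equal(cz[[2]]$charged_species, "nadh")
  expect_equal(cz[[2]]$biosynthesis_reaction, "R_nadsyn")
  # selection rule (2): an empty biomass objective function excludes everything
  expect_length(identify_coenzymes(m, bof_members = character(0)), 0)
  # fol qualifies through its charged derivative in the BOF
  expect_true("folh" %in% m$bof_members && !"fol" %in% m$bof_members)
  # selection rule (1): a species drawn off as a biosynthetic precursor is out
  m2 <- m
  m2$reactions[["R_drain"]] <- me_reaction(
    "R_drain", stoich = list(nad = -1, prec = 1))
  cz2 <- identify_coenzymes(m2)
  expect_false("nad" %in% vapply(cz2, `[[`, "", "id"))
})

test_that("the activity coupling rewrites uncharged-reactant coefficients", {
  m <- generate_toy_me_model(toy_config(seed = 1), check = FALSE)
  cz <- identify_coenzymes(m)
  cm <- apply_coenzyme_coupling(m, cz, k_activity = 1e4)
  co <- cm$reactions[["R_gly"]]$stoich[["nad"]]
  # (1 + mu/k_activity) multiplier: 1.0001 at mu = 1 for k = 1e4
  expect_equal(eval_mu_coef(co, 1), -1.0001, tolerance = 1e-12)
  # mu = 0: the unmodified stoichiometry
  expect_equal(eval_mu_coef(co, 0), -1)
  # formation row: biosynthesis +1, usage -mu/k, at mu = 0 no demand
  num0 <- meallocate:::assemble_numeric(cm, 1e-12, limit_zero = TRUE)
  expect_equal(-num0$S["coupling__coenzyme_nad", "R_gly"], 1e-16,
               tolerance = 1e-18)
  num <- evaluate_at_mu(cm, 1)
  expect_equal(num$S["coupling__coenzyme_nad", "R_nadsyn"], 1)
  expect_equal(-num$S["coupling__coenzyme_nad", "R_gly"], 1e-4)
  # multi-unit charging: cfh cycles three NAD per substrate
  expect_equal(-num$S["coupling__coenzyme_nad", "R_cfhcat"], 3e-4)
  # an open uptake exchange counts as coenzyme formation too
  expect_equal(num$S["coupling__coenzyme_nad", "EX_nad"], -1)
  expect_error(apply_coenzyme_coupling(m, cz, k_activity = 0), "> 0")
  expect_error(apply_coenzyme_coupling(cm, cz), "applied twice")
})

test_that("doubling k_activity halves the forced biosynthesis flux", {
  m <- generate_toy_me_model(toy_config(seed = 1), check = FALSE)
  cz <- identify_coenzymes(m)
  media <- toy_base_media(m, aerobic = FALSE)
  mu_fix <- 0.3
  synth_at <- function(k) {
    cm <- zero_biomass_constituent_demand(
      apply_coenzyme_coupling(m, cz, k_activity = k))
    f <- feasible_at_mu(apply_media(cm, media), mu_fix)
    usage <- f$fluxes[["R_gly"]] + f$fluxes[["R_accat"]] +
      f$fluxes[["R_cfhcat"]] + f$fluxes[["R_aa_3"]]
    c(synth = f$fluxes[["R_nadsyn"]], usage = usage)
  }
  a <- synth_at(1e4)
  b <- synth_at(2e4)
  expect_equal(a[["synth"]], mu_fix * a[["usage"]] / 1e4, tolerance = 1e-6)
  expect_equal(b[["synth"]], mu_fix * b[["usage"]] / 2e4, tolerance = 1e-6)
})

test_that("zeroing the biomass constituent demand is idempotent", {
  m <- generate_toy_me_model(toy_config(seed = 1), check = FALSE)
  m <- set_bounds(m, "biomass_constituent_demand", lb = 0.1, ub = 0.1)
  z1 <- zero_biomass_constituent_demand(m)
  expect_equal(z1$reactions[["biomass_constituent_demand"]]$lb, 0)
  expect_equal(z1$reactions[["biomass_constituent_demand"]]$ub, 0)
  z2 <- zero_biomass_constituent_demand(z1)
  expect_identical(z1, z2)
  # absence is a logged no-op
  m2 <- m
  m2$reactions[["biomass_constituent_demand"]] <- NULL
  expect_message(z3 <- zero_biomass_constituent_demand(m2), "nothing to do")
  expect_identical(z3, m2)
})

test_that("weak coupling converges to the uncoupled growth optimum", {
  m <- generate_toy_me_model(toy_config(seed = 1), check = FALSE)
  uncoupled <- zero_biomass_constituent_demand(m)
  weak <- zero_biomass_constituent_demand(
    apply_coenzyme_coupling(m, identify_coenzymes(m), k_activity = 1e8))
  mu_u <- maximize_growth(uncoupled, tol = 1e-7)$mu_opt
  mu_w <- maximize_growth(weak, tol = 1e-7)$mu_opt
  expect_lt(abs(mu_w - mu_u) / mu_u, 1e-4)
})
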