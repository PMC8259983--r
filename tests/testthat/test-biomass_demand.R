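mk_sol <- function(mu, fluxes) {
  meallocate:::new_me_solution(mu, fluxes, "optimal", 0L, c(mu, mu))
}

test_that("amino-acid demand is the translation-weighted composition sum", {
  m <- toy_small()
  rx <- names(m$reactions)
  v <- stats::setNames(rep(0, length(rx)), rx)
  sol0 <- mk_sol(0.5, v)
  expect_true(all(amino_acid_demand(sol0, m) == 0))
  # hand summation over three peptides with known compositions
  tsl <- grep("^R_tsl_", rx, value = TRUE)[1:3]
  v[tsl] <- c(0.5, 0.2, 0.1)
  sol <- mk_sol(0.5, v)
  got <- amino_acid_demand(sol, m)
  expected <- numeric(0)
  for (i in seq_along(tsl)) {
    pep <- m$species[[m$reactions[[tsl[i]]]$peptide]]
    for (aa in names(pep$composition)) {
      expected[aa] <- (if (aa %in% names(expected)) expected[[aa]] else 0) +
        v[[tsl[i]]] * pep$composition[[aa]]
    }
  }
  expect_equal(got[sort(names(expected))], expected[sort(names(expected))])
})

test_that("prosthetic demand follows complex formation stoichiometry", {
  m <- toy_full()   # heme enters E_cyox formation with 2 copies
  rx <- names(m$reactions)
  v <- stats::setNames(rep(0, length(rx)), rx)
  v["R_form_E_cyox"] <- 0.1
  got <- prosthetic_demand(mk_sol(1, v), m)
  expect_equal(got[["heme"]], 0.2)
  expect_equal(got[["thm"]], 0)   # no E_gly formation flux
})

test_that("coenzyme demand reads the designated biosynthesis flux", {
  m <- toy_full()
  rx <- names(m$reactions)
  v <- stats::setNames(rep(0, length(rx)), rx)
  v["R_nadsyn"] <- 0.007
  got <- coenzyme_demand(mk_sol(1, v), m$coenzymes)
  expect_equal(got[["nad"]], 0.007)
  expect_equal(got[["q8"]], 0)
  bad <- list(coenzyme_spec("x", "nad", "nadh", "R_missing"))
  expect_error(coenzyme_demand(mk_sol(1, v), bad), "absent")
})

test_that("both normalizations divide by the right denominator", {
  m <- toy_small()
  rx <- names(m$reactions)
  v <- stats::setNames(rep(0, length(rx)), rx)
  v[m$protein_biomass_summary_id] <- 1.6
  sol <- mk_sol(2, v)
  d <- c(a = 0.4, b = 0)
  pg <- normalize_composition(d, sol, m, "per_growth")
  expect_equal(pg$demand, c(0.2, 0))
  pp <- normalize_composition(d, sol, m, "per_protein_biomass")
  expect_equal(pp$demand, c(0.4 / 1.6, 0))
  # the two modes differ exactly by v_protein / mu for every component
  expect_equal(pg$demand[1] / pp$demand[1], 1.6 / 2)
  expect_equal(attr(pp, "normalization"), "per_protein_biomass")
  sol0 <- mk_sol(0, v)
  expect_error(normalize_composition(d, sol0, m, "per_growth",
                                     condition_id = "c0"),
               "normalization error.*c0")
  v0 <- v; v0[m$protein_biomass_summary_id] <- 0
  expect_error(normalize_composition(d, mk_sol(2, v0), m,
                                     "per_protein_biomass"),
               "protein biomass")
})

test_that("translation-based and formation-based amino-acid accounting agree", {
  m <- toy_full()
  sol <- toy_full_solution(TRUE)
  direct <- amino_acid_demand(sol, m)
  # independent route: complex formation fluxes x subunit copies x
  # composition (plus peptides routed through no complex, of which the toy
  # has none) must reproduce the translation-flux accounting, because each
  # peptide balance ties the two layers together
  indirect <- numeric(0)
  for (r in m$reactions) {
    if (r$klass != "complex_formation") next
    v <- sol$fluxes[[r$id]]
    for (sid in names(r$stoich)) {
      sp <- m$species[[sid]]
      if (is.null(sp) || sp$role != "peptide") next
      copies <- -as_mu_coef(r$stoich[[sid]])[["const"]]
      for (aa in names(sp$composition)) {
        indirect[aa] <- (if (aa %in% names(indirect)) indirect[[aa]] else 0) +
          v * copies * sp$composition[[aa]]
      }
    }
  }
  indirect <- indirect[sort(names(indirect))]
  expect_equal(direct[names(indirect)], indirect, tolerance = 1e-8)
})

test_that("demands scale linearly with the flux vector at fixed mu", {
  m <- toy_full()
  sol <- toy_full_solution(TRUE)
  sol2 <- sol
  sol2$fluxes <- 2 * sol$fluxes
  expect_equal(2 * amino_acid_demand(sol, m), amino_acid_demand(sol2, m))
  expect_equal(2 * prosthetic_demand(sol, m), prosthetic_demand(sol2, m))
})

test_that("the respiratory cofactors are unused anaerobically", {
  m <- toy_full()
  sol_an <- toy_full_solution(FALSE)
  expect_equal(prosthetic_demand(sol_an, m)[["heme"]], 0)
  expect_equal(coenzyme_demand(sol_an, m$coenzymes)[["q8"]], 0)
  sol_ae <- toy_full_solution(TRUE)
  expect_gt(prosthetic_demand(sol_ae, m)[["heme"]], 0)
  expect_gt(coenzyme_demand(sol_ae, m$coenzymes)[["q8"]], 0)
})
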