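test_that("auxotroph construction validates the knockout list", {
  bb <- toy_full_base(TRUE)
  expect_error(make_auxotroph(bb, "nad", character(0)), "empty")
  expect_error(make_auxotroph(bb, "nad", "R_nope"), "unknown knockout")
  # a knockout that leaves the network prototrophic is rejected: without
  # heme only respiration dies, fermentative growth continues
  expect_error(make_auxotroph(bb, "heme", "R_hemsyn"),
               "auxotrophy not achieved")
  aux <- make_auxotroph(bb, "nad", "R_nadsyn")
  expect_equal(aux$auxotroph$exchange_id, "EX_nad")
  # closed exchange: growth collapses; open: growth is restored
  closed <- maximize_growth(aux, tol = 1e-4)$mu_opt
  open <- maximize_growth(set_bounds(aux, "EX_nad", lb = -1000),
                          tol = 1e-4)$mu_opt
  expect_lt(closed, 0.05)
  expect_gt(open, 1)
  # a metabolite without a pre-existing exchange gets a fresh closed one
  aux2 <- make_auxotroph(bb, "thm", "R_thmsyn")
  expect_true("EX_thm" %in% names(aux2$reactions))
})

test_that("limitation profiles are monotone with consistent allocations", {
  pr <- fol_profile_coarse()
  expect_gt(pr$optimal_uptake, 0)
  expect_true(all(diff(pr$growth) <= 1e-5))
  expect_true(all(pr$growth > 0))
  sums <- vapply(pr$allocation, sum, 0)
  expect_true(all(abs(sums - 1) <= 1e-6))
  # full availability reproduces the unconstrained optimum
  free <- maximize_growth(set_bounds(fol_auxotroph(),
                                     "EX_fol", lb = -1000), tol = 1e-6)
  expect_equal(unname(pr$growth[["1"]]), free$mu_opt, tolerance = 1e-9)
  expect_equal(pr$fluxes[["1"]], free$fluxes, tolerance = 1e-6)
})

test_that("protein allocation splits mass by catalytic usage", {
  m <- one_enzyme_model(U = 1, c_cost = 2, k_eff = 500)
  sol <- maximize_growth(m, mu_hi = 2, tol = 1e-7)
  al <- protein_allocation(sol, m)
  expect_equal(al, c(core = 1))
  # doubling all fluxes and mu leaves fractions unchanged
  sol2 <- sol
  sol2$mu_opt <- 2 * sol$mu_opt
  sol2$fluxes <- 2 * sol$fluxes
  expect_equal(protein_allocation(sol2, m), al)
  sol0 <- sol; sol0$mu_opt <- 0
  expect_error(protein_allocation(sol0, m), "mu = 0")
  # on the full toy the respiratory complexes carry aerobic protein mass
  alf <- protein_allocation(toy_full_solution(TRUE), toy_full())
  expect_true(all(c("respiration", "structural_protein",
                    "expression_machinery") %in% names(alf)))
  expect_equal(sum(alf), 1, tolerance = 1e-9)
  expect_gt(alf[["structural_protein"]], 0.5)
})

test_that("flux responses rank, normalize and group correlated series", {
  pr <- fol_profile_coarse()
  fr <- flux_response_summary(pr, top_n = 10)
  expect_lte(nrow(fr), 10)
  expect_true(all(diff(fr$sd) <= 0))
  series_cols <- grep("^f_", names(fr))
  expect_true(all(abs(as.matrix(fr[, series_cols])) <= 1 + 1e-9))
  # the two alternative folate-carrier routes respond in opposition
  a <- unlist(fr[fr$members == "R_aa_5a" | grepl("R_aa_5a", fr$members),
                 series_cols][1, ])
  b <- unlist(fr[fr$members == "R_aa_5b" | grepl("R_aa_5b", fr$members),
                 series_cols][1, ])
  expect_lt(stats::cor(a, b), -0.5)
  # translation and formation of one enzyme are stoichiometrically coupled
  # and merge into a single row
  expect_true(any(fr$n_members >= 2))
  expect_error(flux_response_summary(
    limitation_profile(fol_auxotroph(), fractions = c(1, 0.5),
                       tol = 1e-4)), "at least 3")
})

test_that("excess nutrient supply relieves the matching biosynthesis burden", {
  bb <- toy_full_base(TRUE)
  aux <- list(fol = fol_auxotroph(),
              aa_1 = make_auxotroph(bb, "aa_1", "R_aa_1"))
  er <- excess_response(bb, aux, lfc_thresh = 0.1)
  fol_cof <- er$log2fc[er$metabolite_id == "fol" &
                         er$subsystem == "cofactor_biosynthesis"]
  expect_lt(fol_cof, -0.1)
  aa1_aab <- er$log2fc[er$metabolite_id == "aa_1" &
                         er$subsystem == "amino_acid_biosynthesis"]
  expect_lt(aa1_aab, 0)
  # an infinite threshold retains nothing
  expect_equal(nrow(excess_response(bb, aux["fol"], lfc_thresh = Inf)), 0)
})
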