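test_that("stoichiometric matrix follows model ordering and signs", {
  m <- make_textbook_model()
  sm <- build_stoichiometric_matrix(m)
  S <- as.matrix(sm$S)
  expect_equal(dim(S), c(6, 10))
  expect_equal(rownames(S), m$metabolites$id)
  expect_equal(colnames(S), m$reactions$id)
  # A -> B column: -1 at A, +1 at B
  expect_equal(unname(S[c("A_c", "B_c"), "R_hi"]), c(-1, 1))
  # each exchange column has exactly one nonzero
  ex <- exchange_ids(m)
  expect_true(all(colSums(S[, ex] != 0) == 1))
  expect_equal(sm$reaction_index[["BIOMASS"]], 10L)
})

test_that("apply_uptake closes exchanges, opens nutrients and sets carbon lb", {
  m <- make_textbook_model()
  m2 <- apply_uptake(m, list(uptake_constraint("EX_A", 0.1593)),
                     open_nutrients = "EX_N")
  rx <- m2$reactions
  expect_equal(rx$lb[rx$id == "EX_A"], -0.1593)
  expect_gte(rx$ub[rx$id == "EX_A"], 0)
  expect_equal(rx$lb[rx$id == "EX_N"], -1000)
  expect_equal(rx$lb[rx$id == "EX_D"], 0)
  expect_error(apply_uptake(m, list(uptake_constraint("R_hi", 1))),
               "not an exchange reaction")
  expect_error(uptake_constraint("EX_A", -1), "non-negative")
})

test_that("growth is zero with every exchange closed to uptake", {
  m <- apply_uptake(make_textbook_model())
  s <- solve_fba(m)
  expect_equal(s$status, "optimal")
  expect_equal(s$objective_value, 0, tolerance = 1e-9)
})

test_that("single-path chain yields uptake x 1 and growth scales with uptake", {
  s <- solve_fba(textbook_with_uptake(10))
  expect_equal(s$status, "optimal")
  expect_equal(s$objective_value, 10, tolerance = 1e-8)
  # carbon-limited growth equals yield x uptake on the fixture
  s2 <- solve_fba(textbook_with_uptake(0.0845))
  expect_equal(s2$objective_value, 0.0845, tolerance = 1e-9)
  # scale equivariance: doubling the uptake bound doubles growth
  s3 <- solve_fba(textbook_with_uptake(0.169))
  expect_equal(s3$objective_value, 2 * s2$objective_value, tolerance = 1e-9)
})

test_that("optimal FBA solutions satisfy steady state and bounds", {
  for (s in 1:10) {
    m <- generate_model(n_metabolites = sample(4:6, 1),
                        n_reactions = sample(8:12, 1), seed = s)
    m <- apply_uptake(m, list(uptake_constraint("EX_S", runif(1, 1, 10))))
    sol <- solve_fba(m)
    expect_equal(sol$status, "optimal")
    resid <- max(abs(as.matrix(m$stoichiometry) %*% sol$fluxes))
    expect_lt(resid, 1e-6)
    expect_true(all(sol$fluxes >= m$reactions$lb - 1e-9))
    expect_true(all(sol$fluxes <= m$reactions$ub + 1e-9))
  }
})

test_that("growth never decreases along an uptake ladder", {
  for (s in 1:5) {
    m0 <- generate_model(n_metabolites = 5, n_reactions = 9, seed = s)
    prev <- -Inf
    for (rate in c(0.5, 1, 2, 4, 8)) {
      m <- apply_uptake(m0, list(uptake_constraint("EX_S", rate)))
      obj <- solve_fba(m)$objective_value
      expect_gte(obj, prev - 1e-9)
      prev <- obj
    }
  }
})

test_that("two-path diamond picks the high-yield route", {
  # textbook has a 1.0-yield path and a 0.5-yield bypass from the same
  # substrate: the optimum must equal uptake x 1.0
  m <- textbook_with_uptake(7)
  s <- solve_fba(m)
  o <- enumerate_vertices_oracle(m)
  expect_equal(s$objective_value, 7, tolerance = 1e-8)
  expect_equal(o$objective_value, 7, tolerance = 1e-10)
})

test_that("infeasible and unbounded problems are flagged, not zeroed", {
  # forced secretion with nothing producing the metabolite -> infeasible
  m <- textbook_with_uptake(5)
  m$reactions$lb[m$reactions$id == "EX_D"] <- 50
  m$reactions$ub[m$reactions$id == "R_byp"] <- 0
  m$reactions$ub[m$reactions$id == "R_spont"] <- 0
  s <- solve_fba(m)
  o <- enumerate_vertices_oracle(m)
  expect_equal(s$status, "infeasible")
  expect_equal(o$status, "infeasible")

  # a free two-reaction cycle with unbounded capacity in the objective
  mets <- data.frame(id = c("A_c"), name = "A", compartment = "c")
  rxns <- data.frame(
    id = c("CYC1", "CYC2", "BIO"),
    name = c("fwd", "rev", "biomass"),
    lb = c(-Inf, -Inf, 0), ub = c(Inf, Inf, 1000),
    gpr = NA_character_, subsystem = NA_character_,
    kind = c("enzymatic", "enzymatic", "biomass"))
  mc <- metabolic_model(mets, rxns,
                        list(CYC1 = c(A_c = 1), CYC2 = c(A_c = -1),
                             BIO = c(A_c = -1)))
  u <- enumerate_vertices_oracle(mc, "CYC1")
  expect_equal(u$status, "unbounded")
  expect_equal(solve_fba(mc, "CYC1")$status, "unbounded")
})

test_that("vertex oracle refuses oversized models", {
  m <- generate_model(n_metabolites = 6, n_reactions = 13, seed = 1)
  expect_error(enumerate_vertices_oracle(m), "<= 12 reactions")
})

test_that("growth_error_percent matches its definition", {
  expect_equal(growth_error_percent(1.0, 1.0), 0)
  expect_equal(growth_error_percent(0.9836, 1.0), 1.64, tolerance = 1e-12)
  expect_equal(growth_error_percent(2.0, 1.0), 100)
  expect_error(growth_error_percent(1, 0), "positive")
})
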