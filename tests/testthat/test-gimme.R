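test_that("penalties implement max(0, threshold - x) with unscored at zero", {
  re <- structure(data.frame(
    reaction_id = c("r1", "r2", "r3", "r4"),
    x = c(4, 10, 15, NA), scored = c(TRUE, TRUE, TRUE, FALSE)),
    class = c("reaction_expression", "data.frame"))
  p <- compute_penalties(re, 10)
  expect_equal(unname(p), c(6, 0, 0, 0))
  expect_named(p, c("r1", "r2", "r3", "r4"))
  expect_error(compute_penalties(re, Inf), "finite")

  set.seed(5)
  for (i in 1:20) {
    x <- runif(50, 0, 20)
    thr <- runif(1, 0, 20)
    re <- structure(data.frame(reaction_id = sprintf("r%d", 1:50),
                               x = x, scored = TRUE),
                    class = c("reaction_expression", "data.frame"))
    expect_equal(unname(compute_penalties(re, thr)), pmax(0, thr - x))
  }
})

test_that("flux reroutes to a zero-penalty bypass with zero inconsistency", {
  m <- textbook_with_uptake(10)
  pen <- stats::setNames(rep(0, 10), m$reactions$id)
  pen[c("R_hi", "R_lo")] <- 5
  g <- solve_gimme(m, pen, gimme_config(growth_fraction = 0.5))
  expect_equal(g$status, "optimal")
  expect_equal(g$inconsistency_score, 0, tolerance = 1e-8)
  expect_lte(abs(g$fluxes[["R_hi"]]), 1e-6)
  expect_lte(abs(g$fluxes[["R_lo"]]), 1e-6)
  expect_equal(g$fluxes[["R_byp"]], 10, tolerance = 1e-6)
  expect_gte(g$growth_rate, 0.5 * g$fba_maximum - 1e-6)
})

test_that("a forced penalized path accrues exactly penalty x flux", {
  m <- textbook_forced_path(10)
  pen <- stats::setNames(rep(0, 10), m$reactions$id)
  pen["R_hi"] <- 5
  g <- solve_gimme(m, pen, gimme_config(growth_fraction = 1.0))
  expect_equal(g$fluxes[["R_hi"]], 10, tolerance = 1e-8)
  expect_equal(g$inconsistency_score, 50, tolerance = 1e-6)
})

test_that("with all penalties zero GIMME reaches the FBA optimum freely", {
  m <- textbook_with_uptake(4)
  pen <- stats::setNames(rep(0, 10), m$reactions$id)
  g <- solve_gimme(m, pen, gimme_config(growth_fraction = 1.0))
  expect_equal(g$status, "optimal")
  expect_equal(g$inconsistency_score, 0)
  expect_equal(g$growth_rate, solve_fba(m)$objective_value, tolerance = 1e-8)
})

test_that("GIMME solutions respect steady state and the growth floor", {
  for (s in 1:8) {
    m <- generate_model(n_metabolites = 5, n_reactions = 9, seed = s)
    m <- apply_uptake(m, list(uptake_constraint("EX_S", 5)))
    pen <- stats::setNames(runif(9, 0, 4), m$reactions$id)
    f <- runif(1, 0.3, 1)
    g <- solve_gimme(m, pen, gimme_config(growth_fraction = f))
    expect_equal(g$status, "optimal")
    expect_lt(max(abs(as.matrix(m$stoichiometry) %*% g$fluxes)), 1e-6)
    expect_gte(g$growth_rate, f * g$fba_maximum - 1e-6)
    expect_gte(g$inconsistency_score, 0)
  }
})

test_that("inconsistency is non-increasing as the threshold drops", {
  m <- textbook_with_uptake(10)
  prof <- generate_fpkm(m, conditions = "C",
                        planted_low_reactions = c("R_hi", "R_lo", "R_byp"),
                        seed = 4)$C
  re <- map_expression(m, prof)
  prev <- Inf
  for (q in c(90, 75, 50, 25, 10, 0)) {
    thr <- compute_threshold(prof, m, q)
    g <- solve_gimme(m, compute_penalties(re, thr), gimme_config(1.0))
    expect_lte(g$inconsistency_score, prev + 1e-8)
    prev <- g$inconsistency_score
  }
})

test_that("negative penalties and infeasible phase 1 are reported", {
  m <- textbook_with_uptake(10)
  pen <- stats::setNames(rep(-1, 10), m$reactions$id)
  expect_error(solve_gimme(m, pen), "non-negative")

  m$reactions$lb[m$reactions$id == "EX_D"] <- 50
  m$reactions$ub[m$reactions$id %in% c("R_byp", "R_spont")] <- 0
  g <- solve_gimme(m, abs(pen))
  expect_equal(g$status, "infeasible")
})

test_that("reaction states split on the zero tolerance", {
  fake <- list(status = "optimal",
               fluxes = c(a = 1e-9, b = 0.0845, c = 0, d = -2))
  st <- context_reaction_states(fake, 1e-6)
  expect_equal(unname(st), c("inactive", "active", "inactive", "active"))
  expect_equal(active_reactions(fake), c("b", "d"))
  all_zero <- list(status = "optimal", fluxes = c(a = 0, b = 0))
  expect_length(active_reactions(all_zero), 0)
  expect_error(context_reaction_states(list(status = "infeasible")),
               "optimal")
})

test_that("phase-2 optimum matches the brute-force oracle on small models", {
  set.seed(20)
  for (s in 1:15) {
    m <- generate_model(n_metabolites = 4, n_reactions = 7, seed = s + 100)
    m <- apply_uptake(m, list(uptake_constraint("EX_S", runif(1, 1, 8))))
    pen <- stats::setNames(runif(7, 0, 5) * rbinom(7, 1, 0.7),
                           m$reactions$id)
    cfg <- gimme_config(growth_fraction = runif(1, 0.4, 1))
    g <- solve_gimme(m, pen, cfg)
    o <- gimme_oracle(m, pen, cfg)
    expect_equal(g$status, "optimal")
    expect_equal(g$inconsistency_score, o$inconsistency_score,
                 tolerance = 1e-6)
  }
})
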