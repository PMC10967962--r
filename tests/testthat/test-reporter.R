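test_that("directional gene Z-scores match the inverse-normal mapping", {
  # frozen values from the standard normal quantile function
  expect_equal(gene_zscore(0.05, "up", "up"), 1.959964, tolerance = 1e-6)
  expect_equal(gene_zscore(0.01, "down", "up"), -2.575829, tolerance = 1e-6)
  expect_equal(gene_zscore(1.0, "up", "up"), 0)
  expect_equal(gene_zscore(1.0, "down", "up"), 0)
  # symmetry: against-direction is the negation
  set.seed(2)
  for (p in runif(20, 1e-6, 1)) {
    expect_equal(gene_zscore(p, "up", "up"), -gene_zscore(p, "up", "down"),
                 tolerance = 1e-12)
  }
  # extreme p-values stay finite
  expect_true(is.finite(gene_zscore(1e-250, "up", "up")))
  expect_error(gene_zscore(0, "up", "up"), "\\(0, 1\\]")
  expect_error(gene_zscore(1.5, "up", "up"), "\\(0, 1\\]")
})

test_that("neighborhoods union GPR genes over touching reactions", {
  m <- make_textbook_model()
  nb <- build_neighborhoods(m)
  # A_c touched by T_A (CCMX_0004), R_hi (0001), R_lo (0002), R_byp (0003)
  expect_setequal(nb$A_c, sprintf("CCMX_%04d", 1:4))
  expect_setequal(nb$B_c, sprintf("CCMX_%04d", 1:3))
  # D_c is touched by EX_D, R_byp, R_spont: only R_byp carries a gene
  expect_equal(nb$D_c, "CCMX_0003")
  # metabolites with only GPR-less reactions are not scorable: none here,
  # but an excluded metabolite must vanish
  nb2 <- build_neighborhoods(m, exclude = "A_c")
  expect_false("A_c" %in% names(nb2))
  expect_true("B_c" %in% names(nb2))
})

test_that("a constant gene universe gives zero corrected scores", {
  # all genes carry the same Z, so every neighborhood equals the
  # background mean and sigma is floored
  gs <- data.frame(gene_id = sprintf("g%d", 1:5),
                   p_value = rep(0.2, 5), direction = rep("up", 5))
  nb <- list(m1 = c("g1", "g2"), m2 = c("g3", "g4", "g5"))
  r <- reporter_scores(nb, gs, n_samples = 500, seed = 1)
  expect_equal(r$z_corrected_up, c(0, 0), tolerance = 1e-9)
  expect_equal(r$p_up, c(0.5, 0.5), tolerance = 1e-9)
})

test_that("k = 1 corrected scores match exact enumeration by hand", {
  gs <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   p_value = c(0.02, 0.5, 0.8, 0.3),
                   direction = c("up", "up", "down", "down"))
  z <- vapply(seq_len(4), function(i)
    gene_zscore(gs$p_value[i], gs$direction[i], "up"), numeric(1))
  nb <- list(mA = "g1", mB = "g3")
  r <- reporter_scores(nb, gs, seed = 1, background = "exhaustive")
  mu <- mean(z)
  sigma <- sqrt(mean((z - mu)^2))
  expect_equal(r$z_corrected_up[r$metabolite_id == "mA"],
               (z[1] - mu) / sigma, tolerance = 1e-12)
  expect_equal(r$z_corrected_up[r$metabolite_id == "mB"],
               (z[3] - mu) / sigma, tolerance = 1e-12)
  expect_equal(r$p_up, pnorm((z[c(1, 3)] - mu) / sigma, lower.tail = FALSE),
               tolerance = 1e-12)
  # down-direction is the mirror image
  expect_equal(r$z_corrected_down, -r$z_corrected_up, tolerance = 1e-12)
})

test_that("sampled background approaches exhaustive moments", {
  set.seed(77)
  z <- rnorm(20)
  for (k in c(2, 3)) {
    exh <- background_stats(z, k, method = "exhaustive")
    smp <- background_stats(z, k, n_samples = 1e5, method = "sample")
    expect_lt(abs(smp$mu - exh$mu), 0.02 * exh$sigma)
    expect_lt(abs(smp$sigma / exh$sigma - 1), 0.02)
  }
  expect_error(background_stats(z, 25), "exceeds")
})

test_that("a planted hot metabolite gets the smallest up p-value", {
  m <- generate_model(n_metabolites = 8, n_reactions = 14, n_genes = 50,
                      seed = 9)
  gs <- generate_gene_stats(m, hot_metabolites = "M4_c", seed = 13)
  nb <- build_neighborhoods(m)
  r <- reporter_scores(nb, gs, n_samples = 4000, seed = 3)
  expect_equal(r$metabolite_id[which.min(r$p_up)], "M4_c")
  sig <- significant_reporters(r)
  expect_true("M4_c" %in% sig$up)
})

test_that("stronger planted signals never weaken the planted metabolite", {
  m <- generate_model(n_metabolites = 6, n_reactions = 10, n_genes = 30,
                      seed = 5)
  nb <- build_neighborhoods(m)
  prev <- Inf
  for (scale in c(0.5, 0.1, 0.01, 0.001)) {
    gs <- generate_gene_stats(m, hot_metabolites = "M3_c",
                              effect = list(shape = 1, scale = scale),
                              seed = 17)
    r <- reporter_scores(nb, gs, n_samples = 2000, seed = 3)
    p <- r$p_up[r$metabolite_id == "M3_c"]
    expect_lte(p, prev + 1e-12)
    prev <- p
  }
})

test_that("identical seeds reproduce reporter results exactly", {
  m <- generate_model(n_metabolites = 6, n_reactions = 10, seed = 2)
  gs <- generate_gene_stats(m, seed = 4)
  nb <- build_neighborhoods(m)
  r1 <- reporter_scores(nb, gs, n_samples = 1000, seed = 8,
                        background = "sample")
  r2 <- reporter_scores(nb, gs, n_samples = 1000, seed = 8,
                        background = "sample")
  expect_identical(r1, r2)
  r3 <- reporter_scores(nb, gs, n_samples = 1000, seed = 9,
                        background = "sample")
  expect_false(identical(r1$p_up, r3$p_up))
})

test_that("significant reporters honour alpha per direction", {
  r <- structure(data.frame(metabolite_id = c("m1", "m2", "m3"),
                            k = c(2, 2, 2),
                            p_up = c(0.01, 0.2, 0.04),
                            p_down = c(0.9, 0.03, 0.5)),
                 class = c("reporter_result", "data.frame"))
  sig <- significant_reporters(r, alpha = 0.05)
  expect_equal(sig$up, c("m1", "m3"))
  expect_equal(sig$down, "m2")
  expect_length(significant_reporters(r, alpha = 0.001)$up, 0)
})

test_that("reporter subnetwork is the induced bipartite edge list", {
  m <- make_textbook_model()
  edges <- reporter_subnetwork(m, c("A_c", "B_c"))
  # A_c: T_A, R_hi, R_lo, R_byp; B_c: R_hi, R_lo, R_byp, BIOMASS
  expect_equal(nrow(edges), 8)
  deg <- table(edges$reaction_id)
  expect_equal(unname(deg[["R_hi"]]), 2)  # shared by both metabolites
  expect_equal(nrow(reporter_subnetwork(m, character(0))), 0)
  expect_error(reporter_subnetwork(m, "ghost"), "not in model")
})
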