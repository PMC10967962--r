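test_that("textbook fixture census matches its construction", {
  m <- make_textbook_model()
  cs <- census(m)
  expect_equal(cs$n_genes, 4)
  expect_equal(cs$n_metabolites, 6)
  expect_equal(cs$n_reactions, 10)
  expect_equal(cs$n_exchange, 3)
  expect_equal(cs$n_biomass, 1)
  expect_equal(cs$n_spontaneous, 1)
  expect_equal(cs$n_enzymatic + cs$n_nonenzymatic, cs$n_reactions)
})

test_that("census kind counts are conserved on generated models", {
  for (s in 1:10) {
    m <- generate_model(n_metabolites = sample(3:7, 1),
                        n_reactions = sample(8:12, 1), seed = s)
    cs <- census(m)
    expect_equal(cs$n_enzymatic + cs$n_spontaneous + cs$n_transport +
                   cs$n_exchange + cs$n_biomass, cs$n_reactions)
    expect_lte(cs$n_biomass, 1)
  }
})

test_that("empty model has an all-zero census", {
  m0 <- metabolic_model(
    data.frame(id = character(0), name = character(0),
               compartment = character(0)),
    data.frame(id = character(0), name = character(0), lb = numeric(0),
               ub = numeric(0), gpr = character(0),
               subsystem = character(0), kind = character(0)),
    list())
  cs <- census(m0)
  expect_true(all(unlist(cs) == 0))
})

test_that("TSV round-trip preserves ids, stoichiometry, bounds and GPR", {
  for (m in list(make_textbook_model(),
                 generate_model(n_metabolites = 6, n_reactions = 11, seed = 3))) {
    d <- withr::local_tempdir()
    write_model(m, d, "tsv")
    back <- read_model(d, "tsv")
    expect_identical(unclass(census(back)), unclass(census(m)))
    expect_identical(back$reactions$id, m$reactions$id)
    expect_identical(back$metabolites$id, m$metabolites$id)
    expect_equal(back$reactions$lb, m$reactions$lb)
    expect_equal(back$reactions$ub, m$reactions$ub)
    expect_equal(as.matrix(back$stoichiometry), as.matrix(m$stoichiometry))
    expect_identical(back$genes, m$genes)
  }
})

test_that("SBML FBC round-trip preserves the model", {
  for (m in list(make_textbook_model(),
                 generate_model(n_metabolites = 5, n_reactions = 9, seed = 8))) {
    f <- withr::local_tempfile(fileext = ".xml")
    write_model(m, f, "sbml_fbc")
    back <- read_model(f, "sbml_fbc")
    expect_identical(unclass(census(back)), unclass(census(m)))
    expect_lt(max(abs(as.matrix(back$stoichiometry) -
                        as.matrix(m$stoichiometry))), 1e-9)
    expect_equal(back$reactions$lb, m$reactions$lb)
    expect_equal(back$reactions$ub, m$reactions$ub)
    expect_identical(back$biomass_id, m$biomass_id)
    # GPR logic survives (text may be normalized)
    for (i in seq_len(nrow(m$reactions))) {
      a <- m$reactions$gpr[i]; b <- back$reactions$gpr[i]
      expect_equal(is.na(a), is.na(b))
      if (!is.na(a)) {
        ta <- parse_gpr(a); tb <- parse_gpr(b)
        expect_true(gpr_logically_equal(ta, tb, gpr_genes(ta)))
      }
    }
  }
})

test_that("exotic compartment codes survive a round-trip", {
  m <- make_textbook_model()
  m$metabolites$compartment[m$metabolites$id == "D_c"] <- "px9"
  m$compartments <- c(m$compartments, "px9")
  d <- withr::local_tempdir()
  write_model(m, d, "tsv")
  expect_true("px9" %in% read_model(d, "tsv")$metabolites$compartment)
})

test_that("invalid inputs are rejected with informative errors", {
  m <- make_textbook_model()
  d <- withr::local_tempdir()
  write_model(m, d, "tsv")

  # duplicate reaction id
  rx <- readLines(file.path(d, "reactions.tsv"))
  writeLines(c(rx, rx[2]), file.path(d, "reactions.tsv"))
  expect_error(read_model(d, "tsv"), "duplicate reaction id")

  # unresolvable metabolite named in the error
  writeLines(rx, file.path(d, "reactions.tsv"))
  rx2 <- sub("A_e <=>", "GHOST_m <=>", rx)
  writeLines(rx2, file.path(d, "reactions.tsv"))
  expect_error(read_model(d, "tsv"), "EX_A.*GHOST_m")

  # missing biomass reaction
  writeLines(rx[!grepl("^BIOMASS", rx)], file.path(d, "reactions.tsv"))
  expect_error(read_model(d, "tsv"), "biomass")

  expect_error(read_model(file.path(d, "nope"), "tsv"), "does not exist")
})

test_that("bounds absent from a TSV default by reversibility", {
  d <- withr::local_tempdir()
  writeLines(c("id\tequation\tkind",
               "EX_A\tA_e <=>\texchange",
               "T\tA_e --> B_c\ttransport",
               "R\tB_c <=> C_c\tenzymatic",
               "BIO\tC_c -->\tbiomass"),
             file.path(d, "reactions.tsv"))
  writeLines(c("id\tcompartment", "A_e\te", "B_c\tc", "C_c\tc"),
             file.path(d, "metabolites.tsv"))
  m <- read_model(d, "tsv")
  expect_equal(m$reactions$lb, c(-1000, 0, -1000, 0))
  expect_equal(m$reactions$ub, rep(1000, 4))
})
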