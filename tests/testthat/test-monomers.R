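test_that("descriptor-derived formulas match printed species", {
  expect_equal(
    formula_string(monomer_formula(parse_shorthand("10,16-diOH-16:0"))),
    "C16H32O4"
  )
  expect_equal(round_mz(parse_shorthand("10,16-diOH-16:0")$mz), 287.22)
  expect_equal(
    formula_string(monomer_formula(parse_shorthand("16:0"))),
    "C16H32O2"
  )
  expect_equal(
    formula_string(monomer_formula(parse_shorthand("18-OH-9,10-epoxy-18:1"))),
    "C18H32O4"
  )
  expect_equal(round_mz(parse_shorthand("18-OH-9,10-epoxy-18:1")$mz), 311.22)
})

test_that("every catalog formula agrees with an independent hand-built table", {
  # hand-derived from the structures: saturated acid CnH2nO2, -2H per double
  # bond or epoxide or second carboxyl, +1 O per hydroxyl/epoxide, alcohols
  # CnH(2n+2)O
  expected <- c(
    "9,10,18-triOH-18:0" = "C18H36O5",
    "10,16-diOH-16:0" = "C16H32O4",
    "9,10,18-triOH-18:3" = "C18H30O5",
    "9,10,18-triOH-18:2" = "C18H32O5",
    "18-OH-18:2" = "C18H32O3",
    "9,10,18-triOH-18:1" = "C18H34O5",
    "16-OH-16:0" = "C16H32O3",
    "10,16-diOH-16:1" = "C16H30O4",
    "18-OH-18:1" = "C18H34O3",
    "18-OH-18:3" = "C18H30O3",
    "18-OH-9,10-epoxy-18:0" = "C18H34O4",
    "18-OH-9,10-epoxy-18:1" = "C18H32O4",
    "18-OH-9,10-epoxy-18:2" = "C18H30O4",
    "2-OH-16:0" = "C16H32O3",
    "16:0" = "C16H32O2",
    "18:0" = "C18H36O2",
    "18:1" = "C18H34O2",
    "18:2" = "C18H32O2",
    "16:0-DCA" = "C16H30O4",
    "9,10-diOH-18:0-DCA" = "C18H34O6",
    "20:0" = "C20H40O2",
    "20:3" = "C20H34O2",
    "2-OH-22:0" = "C22H44O3",
    "2-OH-24:0" = "C24H48O3",
    "30:0" = "C30H60O2",
    "26:0-ol" = "C26H54O",
    "28:0-ol" = "C28H58O",
    "30:0-ol" = "C30H62O"
  )
  cat <- default_catalog()
  expect_setequal(cat$id, names(expected))
  for (id in cat$id) {
    row <- cat[cat$id == id, ]
    expect_equal(row$formula, unname(expected[id]), label = id)
    expect_equal(
      formula_string(monomer_formula(row)), unname(expected[id]),
      label = id
    )
  }
})

test_that("monomer validation rejects impossible descriptors", {
  expect_error(monomer(16, oh = 17), "positions must lie")
  expect_error(monomer(16, oh = 1), "positions must lie")
  expect_error(monomer(18, oh = 9, epoxy = 9), "disjoint")
  expect_error(monomer(16, carboxyls = c(1, 8)), "restricted to carbons")
  expect_error(parse_shorthand("20-OH-18:0"), "exceeds chain length")
  expect_error(parse_shorthand("banana"), "cannot parse")
})

test_that("shorthand parsing handles spelled-out and compact grammars", {
  m <- parse_shorthand("9,10,18-trihydroxy-18:0")
  expect_equal(m$n, 18L)
  expect_equal(m$d, 0L)
  expect_equal(m$oh[[1]], c(9L, 10L, 18L))

  e <- parse_shorthand("18-hydroxy-9,10-epoxy-18:1")
  expect_equal(e$oh[[1]], 18L)
  expect_equal(e$epoxy[[1]], 9L)
  expect_equal(e$d, 1L)

  plain <- parse_shorthand("16:0")
  expect_equal(length(plain$oh[[1]]), 0L)
  expect_equal(plain$carboxyls[[1]], 1L)
})

test_that("shorthand render/parse is the identity on canonical names", {
  for (id in default_catalog()$id) {
    expect_equal(render_shorthand(parse_shorthand(id)), id, label = id)
  }
})

test_that("catalog mass window and lookup behave as measured", {
  cat <- default_catalog()
  tri <- cat[cat$id == "9,10,18-triOH-18:0", ]
  expect_equal(tri$mz, 331.2485, tolerance = 1e-3)
  # the monocarboxylic C16/C18 acid pool spans the measured monomer window
  acids <- cat[!cat$alcohol & cat$n %in% c(16, 18) &
    vapply(cat$carboxyls, length, integer(1)) == 1, ]
  expect_true(all(acids$mz <= 331.25))
  expect_true(all(acids$mz >= 164))

  hit <- catalog_lookup(cat, mz = 287.222, tol_da = 0.01)
  expect_equal(hit$id, "10,16-diOH-16:0")
  expect_false(hit$isobar)
})

test_that("isobaric species are both returned and flagged, never merged", {
  cat <- default_catalog()
  # a dihydroxy monounsaturated C18 acid shares C18H34O4 with the
  # omega-hydroxy epoxy stearate
  iso <- monomer(18, 1, oh = c(9, 18), id = "9,18-diOH-18:1")
  expect_equal(iso$formula, cat$formula[cat$id == "18-OH-9,10-epoxy-18:0"])
  cat2 <- dplyr::bind_rows(cat, iso)
  hits <- catalog_lookup(cat2, mass = monoisotopic_mass("C18H34O4"), tol_da = 0.001)
  expect_setequal(hits$id, c("18-OH-9,10-epoxy-18:0", "9,18-diOH-18:1"))
  expect_true(all(hits$isobar))
})

test_that("catalog TSV round trips losslessly", {
  tmp <- tempfile(fileext = ".tsv")
  cat <- default_catalog()
  write_catalog(cat, tmp)
  back <- read_catalog(tmp)
  expect_equal(back$id, cat$id)
  expect_equal(back$formula, cat$formula)
  expect_equal(back$mass, cat$mass)
  expect_equal(back$oh, cat$oh)
  expect_equal(back$sim_weight, cat$sim_weight)
})

test_that("symbolic nomenclature renders and parses bit-exactly", {
  cat <- default_catalog()
  expect_equal(
    render_symbolic(cat[cat$id == "10,16-diOH-16:0", ]),
    "[16:0|COOH@1|OH@10,16]"
  )
  dimer <- oligomer(c("16-OH-16:0", "9,10,18-triOH-18:0"))
  expect_equal(
    render_symbolic(dimer),
    "[16:0|COOH@1|OH@16] <=(16)= [18:0|COOH@1|OH@9,10,18]"
  )
  # epoxide and ester site fields
  tri <- oligomer(c("18-OH-9,10-epoxy-18:1", "10,16-diOH-16:0", "18-OH-18:3"))
  expect_match(render_symbolic(tri), "\\[18:1\\|COOH@1\\|OH@18\\|EP@9-10\\]")
  expect_match(render_symbolic(tri), "<=\\(18\\)=.*<=\\(16\\)=")

  # render . parse identity across random catalog monomers and oligomers
  set.seed(7)
  for (i in 1:100) {
    row <- cat[sample(nrow(cat), 1), ]
    expect_equal(render_symbolic(parse_symbolic(render_symbolic(row))), render_symbolic(row))
  }
  for (i in 1:20) {
    hosts <- cat$id[vapply(cat$oh, length, integer(1)) > 0 & !cat$alcohol]
    ids <- c(sample(hosts, 2), sample(cat$id[!cat$alcohol], 1))
    o <- oligomer(ids)
    back <- parse_symbolic(render_symbolic(o))
    expect_equal(render_symbolic(back), render_symbolic(o))
  }
})
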