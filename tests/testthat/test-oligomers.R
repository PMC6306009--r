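fig3c_trimer <- function() {
  oligomer(c("18-OH-9,10-epoxy-18:1", "10,16-diOH-16:0", "18-OH-18:3"))
}

test_that("oligomer precursors reproduce printed molecular ions", {
  dimer <- oligomer(c("16-OH-16:0", "9,10,18-triOH-18:0"))
  expect_equal(round_mz(precursor_mz(dimer)), 585.47)
  expect_equal(round_mz(precursor_mz(fig3c_trimer())), 857.65)
  single <- oligomer("18-OH-18:3")
  expect_equal(round_mz(precursor_mz(single)), 293.21)
  # a length-1 oligomer equals the monomer ion
  expect_equal(
    precursor_mz(single),
    ion_mz(default_catalog()$formula[default_catalog()$id == "18-OH-18:3"])
  )
})

test_that("oligomer construction enforces linkage and direction invariants", {
  expect_error(oligomer(c("16:0", "18-OH-18:3")), "no hydroxyl to host")
  expect_error(
    oligomer(c("16-OH-16:0", "18-OH-18:3"), linkage_sites = 10L),
    "not a hydroxyl"
  )
  expect_error(
    oligomer(c("16-OH-16:0", "26:0-ol"), catalog = default_catalog()),
    "lack a carboxyl"
  )
  # a mid-chain linkage changes no mass, only the free hydroxyl count
  a <- oligomer(c("10,16-diOH-16:0", "18-OH-18:3"), linkage_sites = 16L)
  b <- oligomer(c("10,16-diOH-16:0", "18-OH-18:3"), linkage_sites = 10L)
  expect_equal(precursor_mz(a), precursor_mz(b))
})

test_that("ester fragments of the printed trimer and tetramer are predicted", {
  fr <- predict_ester_fragments(fig3c_trimer())
  got <- round_mz(fr$mz)
  expect_true(581.44 %in% got) # dimer epoxy-18:1 + diOH-16:0
  expect_true(563.43 %in% got) # dimer diOH-16:0 + 18-OH-18:3
  expect_true(275.20 %in% got) # 18-OH-18:3 - H2O
  expect_true(all(c(311.22, 287.22, 293.21) %in% got)) # all three monomers

  tet <- oligomer(c(
    "18-OH-9,10-epoxy-18:1", "18-OH-18:2",
    "18-OH-9,10-epoxy-18:0", "18-OH-18:3"
  ))
  expect_true(589.45 %in% round_mz(predict_ester_fragments(tet)$mz))
})

test_that("every dimer fragment set contains both constituent monomer ions", {
  cat <- default_catalog()
  hosts <- cat$id[vapply(cat$oh, length, integer(1)) > 0 & !cat$alcohol]
  set.seed(5)
  for (i in 1:20) {
    ids <- c(sample(hosts, 1), sample(cat$id[!cat$alcohol], 1))
    o <- oligomer(ids)
    fr <- predict_ester_fragments(o)
    for (f in cat$formula[match(ids, cat$id)]) {
      expect_true(any(abs(fr$mz - ion_mz(f)) < 1e-9))
    }
  }
})

test_that("complementary single-cleavage fragments conserve mass", {
  set.seed(9)
  cat <- default_catalog()
  hosts <- cat$id[vapply(cat$oh, length, integer(1)) > 0 & !cat$alcohol]
  for (i in 1:10) {
    len <- sample(3:5, 1)
    # distinct monomers so that species labels (and hence deduplication)
    # cannot collapse two different spans
    ids <- sample(hosts, len)
    o <- oligomer(ids)
    parent <- monoisotopic_mass(oligomer_formula(o))
    fr <- predict_ester_fragments(o, max_water_loss = 0L, include_internal = FALSE)
    for (cut in seq_len(len - 1)) {
      pre <- fr[fr$start == 1 & fr$end == cut & fr$n_water_loss == 0, ]
      suf <- fr[fr$start == cut + 1 & fr$end == len & fr$n_water_loss == 0, ]
      expect_equal(
        monoisotopic_mass(pre$formula[1]) + monoisotopic_mass(suf$formula[1]),
        parent + monoisotopic_mass("H2O"),
        tolerance = 1e-9
      )
    }
  }
})

test_that("water losses never exceed the fragment's free hydroxyl count", {
  o <- oligomer(c(
    "18-OH-9,10-epoxy-18:1", "10,16-diOH-16:0", "18-OH-18:3"
  ))
  fr <- predict_ester_fragments(o, max_water_loss = 5L)
  cat <- default_catalog()
  for (i in seq_len(nrow(fr))) {
    ids <- stringr::str_split_1(fr$species[i], stringr::fixed("/"))
    free_oh <- sum(vapply(cat$oh[match(ids, cat$id)], length, integer(1))) -
      (length(ids) - 1)
    expect_lte(fr$n_water_loss[i], free_oh)
  }
})

test_that("internal fragments appear only for length >= 4 when enabled", {
  tri <- fig3c_trimer()
  fr3 <- predict_ester_fragments(tri)
  expect_true(all(fr3$start == 1 | fr3$end == 3 | fr3$length == 1))
  tet <- oligomer(c(
    "18-OH-9,10-epoxy-18:1", "18-OH-18:2",
    "18-OH-9,10-epoxy-18:0", "18-OH-18:3"
  ))
  fr4 <- predict_ester_fragments(tet)
  expect_true(any(fr4$start == 2 & fr4$end == 3))
  fr4b <- predict_ester_fragments(tet, include_internal = FALSE)
  expect_false(any(fr4b$start == 2 & fr4b$end == 3))
})

test_that("chain-cleavage candidates cover the printed epoxy diagnostics", {
  cc <- predict_chain_cleavage_ions("18-OH-9,10-epoxy-18:0")
  for (printed in c(171.11, 157.12, 155.12, 141.12, 127.12)) {
    expect_lt(min(abs(cc$mz - printed)), 0.03, label = sprintf("ion %.2f", printed))
  }
  expect_equal(nrow(predict_chain_cleavage_ions(parse_shorthand("16:0"))), 0L)
})

test_that("chain-cleavage candidate count equals the exhaustive enumeration", {
  # independent oracle for 9,10,18-triOH-18:0: 4 flanking bonds x 2 sides x
  # 3 hydrogen offsets x 2 water states, deduplicated by formula, dropping
  # species that cannot lose a proton
  n <- 18L
  oh <- c(9L, 10L, 18L)
  h_per_carbon <- rep(2L, n)
  h_per_carbon[1] <- 1L # carboxyl carbon
  h_per_carbon[18] <- 3L # terminal CH2OH
  o_per_carbon <- rep(0L, n)
  o_per_carbon[1] <- 2L
  o_per_carbon[oh] <- o_per_carbon[oh] + 1L
  bonds <- c(8L, 9L, 10L, 17L)
  seen <- character(0)
  for (b in bonds) {
    sides <- list(
      c(C = b, H = sum(h_per_carbon[1:b]), O = sum(o_per_carbon[1:b])),
      c(C = n - b, H = sum(h_per_carbon[(b + 1):n]), O = sum(o_per_carbon[(b + 1):n]))
    )
    for (s in sides) {
      for (hoff in -1:1) {
        for (w in 0:1) {
          cand <- c(
            C = s[["C"]], H = s[["H"]] + hoff - 2L * w,
            O = s[["O"]] - w
          )
          if (any(cand < 0)) next
          if (cand[["H"]] < 1L) next # cannot form [M-H]-
          seen <- c(seen, paste(cand, collapse = ","))
        }
      }
    }
  }
  oracle_n <- length(unique(seen))
  cc <- predict_chain_cleavage_ions("9,10,18-triOH-18:0")
  expect_equal(nrow(cc), oracle_n)
})
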