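test_that("precursor decomposition finds the printed dimer pair", {
  dc <- decompose_precursor(585.47, min_len = 2, max_len = 2)
  comps <- vapply(dc$composition, paste, character(1), collapse = "+")
  expect_true("16-OH-16:0+9,10,18-triOH-18:0" %in% comps)
})

test_that("isobaric compositions are enumerated and flagged", {
  dc <- decompose_precursor(589.45, min_len = 2, max_len = 2)
  comps <- vapply(dc$composition, paste, character(1), collapse = "+")
  expect_true("18-OH-18:2+18-OH-9,10-epoxy-18:1" %in% comps)
  expect_true("18-OH-18:3+18-OH-9,10-epoxy-18:0" %in% comps)
  iso <- dc[comps %in% c(
    "18-OH-18:2+18-OH-9,10-epoxy-18:1",
    "18-OH-18:3+18-OH-9,10-epoxy-18:0"
  ), ]
  expect_true(all(iso$isobar))
  # both pairs condense to the same neutral dimer formula
  expect_equal(unique(iso$formula), "C36H62O6")
})

test_that("zero tolerance yields no candidates for an off-mass precursor", {
  expect_equal(nrow(decompose_precursor(585.5, tol_da = 0, max_len = 2)), 0L)
})

test_that("decomposition equals brute-force enumeration on random precursors", {
  cat <- default_catalog()
  elig <- cat[!cat$alcohol, ]
  h2o <- monoisotopic_mass("H2O")
  h <- monoisotopic_mass(stats::setNames(1L, "H"))
  # independent oracle: explicit nested loops over non-decreasing index tuples
  oracle_sums <- list()
  n <- nrow(elig)
  for (i in 1:n) {
    oracle_sums[[length(oracle_sums) + 1]] <- c(1, elig$mass[i])
    for (j in i:n) {
      oracle_sums[[length(oracle_sums) + 1]] <- c(2, elig$mass[i] + elig$mass[j])
      for (k in j:n) {
        oracle_sums[[length(oracle_sums) + 1]] <-
          c(3, elig$mass[i] + elig$mass[j] + elig$mass[k])
      }
    }
  }
  tab <- do.call(rbind, oracle_sums)
  oracle_mz <- (tab[, 2] - (tab[, 1] - 1) * h2o) - h
  set.seed(21)
  for (trial in 1:40) {
    mz <- stats::runif(1, 150, 1000)
    got <- decompose_precursor(mz, max_len = 3, tol_da = 0.02)
    expect_equal(nrow(got), sum(abs(oracle_mz - mz) <= 0.02), label = sprintf("mz %.4f", mz))
  }
})

test_that("an empty spectrum scores zero and no composition gives a diagnostic", {
  o <- oligomer(c("16-OH-16:0", "9,10,18-triOH-18:0"))
  sp <- spectrum(585.47, numeric(0))
  expect_equal(score_ordering(o, sp)$score, 0)
  res <- sequence_spectrum(spectrum(400.123, c(100, 200)))
  expect_equal(nrow(res$ranking), 0L)
  expect_match(res$diagnostic, "no monomer composition")
})

test_that("noiseless simulated trimers never score below a wrong ordering", {
  cat <- default_catalog()
  hosts <- cat$id[vapply(cat$oh, length, integer(1)) > 0 & !cat$alcohol &
    cat$sim_weight > 0]
  set.seed(31)
  for (trial in 1:10) {
    ids <- c(sample(hosts, 2), sample(hosts, 1))
    if (length(unique(ids)) < 3) next
    truth <- oligomer(ids)
    sp <- simulate_spectrum(truth)
    truth_score <- score_ordering(truth, sp)$score
    for (p in combinat_perms(ids)) {
      if (identical(p, ids)) next
      expect_lte(score_ordering(oligomer(p), sp)$score, truth_score)
    }
    # and the full pipeline places the truth in the rank-1 set
    res <- sequence_spectrum(sp)
    expect_true(
      paste(ids, collapse = "/") %in% res$ranking$sequence[res$ranking$rank == 1]
    )
  }
})

test_that("a reversal that lacks a linkage hydroxyl is never a candidate", {
  # plain 16:0 can only sit at the omega terminus
  truth <- oligomer(c("16-OH-16:0", "9,10,18-triOH-18:0", "16:0"))
  sp <- simulate_spectrum(truth)
  res <- sequence_spectrum(sp)
  seqs <- res$ranking$sequence
  expect_false("16:0/9,10,18-triOH-18:0/16-OH-16:0" %in% seqs)
  expect_equal(res$ranking$sequence[1], "16-OH-16:0/9,10,18-triOH-18:0/16:0")
  # remaining rank-1 ties can only be positional isobars (e.g. the
  # 2-hydroxy isomer of 16-OH-16:0), never the reversal
  top <- res$ranking$sequence[res$ranking$rank == 1]
  expect_true(all(vapply(strsplit(top, "/", fixed = TRUE), function(s) {
    s[3] == "16:0"
  }, logical(1))))
})

test_that("a homodimer spectrum yields a single unambiguous ordering", {
  truth <- oligomer(c("9,10,18-triOH-18:0", "9,10,18-triOH-18:0"))
  sp <- simulate_spectrum(truth)
  res <- sequence_spectrum(sp)
  top <- res$ranking[res$ranking$rank == 1, ]
  expect_equal(nrow(top), 1L)
  expect_false(res$ambiguity)
  expect_equal(top$sequence, "9,10,18-triOH-18:0/9,10,18-triOH-18:0")
})

test_that("sequencing is deterministic for identical input", {
  sp <- spectrum(857.65, c(581.44, 563.43, 311.21, 287.22, 293.20, 275.20))
  r1 <- sequence_spectrum(sp)
  r2 <- sequence_spectrum(sp)
  expect_identical(
    jsonlite::toJSON(r1$ranking, digits = NA),
    jsonlite::toJSON(r2$ranking, digits = NA)
  )
})

test_that("tidy and glance summarise a sequencing result", {
  sp <- spectrum(857.65, c(581.44, 563.43, 311.21, 287.22, 293.20, 275.20))
  res <- sequence_spectrum(sp)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("rank", "sequence", "symbolic", "score") %in% names(td)))
  expect_true(all(diff(td$score) <= 0)) # non-increasing down the ranking
  gl <- glance(res)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$top_sequence, td$sequence[1])
})

test_that("overlap assembly merges on shared terminal runs", {
  out <- assemble_overlaps(list(c("X", "Y", "Z"), c("Y", "Z", "W")))
  expect_equal(nrow(out), 1L)
  expect_equal(out$overlap, 2L)
  expect_equal(out$merged[[1]], c("X", "Y", "Z", "W"))

  none <- assemble_overlaps(list(c("X", "Y"), c("Z", "W")))
  expect_equal(nrow(none), 0L)

  # longer overlaps sort first
  frags <- list(c("A", "B", "C"), c("B", "C", "D"), c("C", "D"))
  out2 <- assemble_overlaps(frags)
  expect_true(all(diff(out2$overlap) <= 0))
})

test_that("digested windows of a random polymer reassemble a supersequence", {
  set.seed(17)
  cat <- default_catalog()
  hosts <- cat$id[vapply(cat$oh, length, integer(1)) > 0 & !cat$alcohol &
    cat$sim_weight > 0]
  hit <- 0L
  n_trials <- 20L
  for (trial in seq_len(n_trials)) {
    truth <- sample(hosts, 6, replace = TRUE)
    windows <- list(truth[1:4], truth[3:6])
    merged <- assemble_overlaps(windows, min_overlap = 2)
    ok <- any(vapply(merged$merged, function(m) {
      length(m) >= 6 &&
        any(vapply(seq_len(length(m) - 5), function(s) {
          identical(m[s:(s + 5)], truth)
        }, logical(1)))
    }, logical(1)))
    if (ok) hit <- hit + 1L
  }
  expect_gte(hit / n_trials, 0.95)
})
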