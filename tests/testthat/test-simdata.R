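test_that("polymer construction respects size, topology and seeds", {
  p1 <- build_polymer(n_monomers = 1, seed = 1)
  expect_equal(nrow(p1$nodes), 1L)
  expect_equal(nrow(p1$edges), 0L)

  p5 <- build_polymer(n_monomers = 5, branching_prob = 0, seed = 2)
  expect_equal(nrow(p5$edges), 4L) # a path of 4 ester edges
  expect_equal(p5$edges$parent, 1:4)
  expect_equal(p5$edges$child, 2:5)

  a <- build_polymer(n_monomers = 8, seed = 99)
  b <- build_polymer(n_monomers = 8, seed = 99)
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$edges, b$edges)
  expect_error(build_polymer(n_monomers = 0), ">= 1")
})

test_that("terminal bias enriches the favoured monomer at the omega end", {
  omega_hits <- 0L
  internal_hits <- 0L
  internal_slots <- 0L
  n_poly <- 400L
  for (s in seq_len(n_poly)) {
    p <- build_polymer(n_monomers = 6, terminal_bias = 5, seed = s)
    ids <- p$nodes$id
    if (ids[6] == "16-OH-16:0") omega_hits <- omega_hits + 1L
    internal_hits <- internal_hits + sum(ids[2:5] == "16-OH-16:0")
    internal_slots <- internal_slots + 4L
  }
  expect_gt(omega_hits / n_poly, internal_hits / internal_slots)
})

test_that("digestion limiting cases and the tree fragment-count law hold", {
  p <- build_polymer(n_monomers = 10, seed = 4)
  all_mono <- digest_polymer(p, p_cleave = 1, seed = 1)
  expect_equal(length(all_mono$fragments), 10L)
  expect_true(all(vapply(all_mono$fragments, length, integer(1)) == 1L))

  intact <- digest_polymer(p, p_cleave = 0, seed = 1)
  expect_equal(length(intact$fragments), 1L)
  expect_equal(length(intact$fragments[[1]]), 10L)

  # E[fragments] = 1 + p * edges on a 9-edge path
  counts <- vapply(1:2000, function(s) {
    length(digest_polymer(p, p_cleave = 0.5, seed = s)$fragments)
  }, integer(1))
  expect_equal(mean(counts), 1 + 0.5 * 9, tolerance = 0.03)
})

test_that("digestion conserves the monomer multiset on every seed", {
  for (s in 1:25) {
    p <- build_polymer(n_monomers = 8, seed = s)
    d <- digest_polymer(p, p_cleave = 0.4, seed = s + 1000)
    frag_ids <- sort(unlist(lapply(d$fragments, function(f) f$monomers$id)))
    expect_equal(frag_ids, sort(p$nodes$id))
    # every fragment is a contiguous run of the backbone, carboxyl end first
    for (f in d$fragments) {
      ids <- f$monomers$id
      k <- length(ids)
      starts <- which(p$nodes$id == ids[1])
      expect_true(any(vapply(starts, function(st) {
        st + k - 1 <= nrow(p$nodes) && identical(p$nodes$id[st:(st + k - 1)], ids)
      }, logical(1))))
    }
  }
})

test_that("fragment length caps discard or re-digest overlong pieces", {
  p <- build_polymer(n_monomers = 9, seed = 12)
  kept <- digest_polymer(p, p_cleave = 0, max_frag_len = 4, overlong = "discard")
  expect_equal(length(kept$fragments), 0L)
  redig <- digest_polymer(p,
    p_cleave = 0, max_frag_len = 4, overlong = "redigest", seed = 5
  )
  expect_true(all(vapply(redig$fragments, length, integer(1)) <= 4L))
  frag_ids <- sort(unlist(lapply(redig$fragments, function(f) f$monomers$id)))
  expect_equal(frag_ids, sort(p$nodes$id))
})

test_that("noiseless simulated spectra equal the theoretical peak set", {
  o <- oligomer(c("18-OH-9,10-epoxy-18:1", "10,16-diOH-16:0", "18-OH-18:3"))
  sp <- simulate_spectrum(o, mass_error_ppm_sigma = 0, n_noise_peaks = 0)
  theo <- sort(predict_ester_fragments(o)$mz)
  expect_equal(sp$peaks$mz, theo, tolerance = 1e-12)
  expect_equal(sp$precursor_mz, precursor_mz(o))
})

test_that("gaussian ppm mass error is unbiased and bounded", {
  o <- oligomer(c("16-OH-16:0", "9,10,18-triOH-18:0"))
  theo <- predict_ester_fragments(o)$mz
  errs <- c()
  for (s in 1:100) {
    sp <- simulate_spectrum(o, mass_error_ppm_sigma = 5, seed = s)
    errs <- c(errs, (sp$peaks$mz - theo) / theo * 1e6)
  }
  expect_lt(abs(mean(errs)), 1) # no systematic shift
  expect_lt(max(abs(errs)), 4 * 5) # within 4 sigma
})

test_that("simulation is reproducible from its seed", {
  o <- oligomer(c("16-OH-16:0", "9,10,18-triOH-18:0"))
  s1 <- simulate_spectrum(o, mass_error_ppm_sigma = 5, n_noise_peaks = 5, seed = 7)
  s2 <- simulate_spectrum(o, mass_error_ppm_sigma = 5, n_noise_peaks = 5, seed = 7)
  expect_identical(s1$peaks, s2$peaks)
  bench1 <- simulate_trimer_benchmark(n = 3, seed = 5)
  bench2 <- simulate_trimer_benchmark(n = 3, seed = 5)
  expect_identical(bench1$truth, bench2$truth)
})

test_that("noiseless round trips recover the true trimer at rank 1", {
  bench <- simulate_trimer_benchmark(
    n = 15, seed = 8,
    mass_error_ppm_sigma = 0, n_noise_peaks = 0
  )
  for (i in seq_len(nrow(bench))) {
    res <- sequence_spectrum(bench$spectrum[[i]])
    truth_seq <- paste(bench$truth[[i]], collapse = "/")
    top <- res$ranking[res$ranking$rank == 1, ]
    expect_true(truth_seq %in% top$sequence, label = truth_seq)
  }
})
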