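# Synthetic cutin: polymer construction, stochastic partial hydrolysis, and
# noisy spectrum generation. Every stochastic function takes one explicit
# seed; identical seeds give identical output. The generator emulates the
# measured features of apple cutin -- the qualitative monomer abundance
# ranking (six dominant monomers carrying ~80% of the pool, encoded as
# sim_weight in the catalog), hydroxyl-rich monomers at ester-forming
# positions, and the enrichment of particular monomers at chain termini --
# under an independent-cleavage model of partial cutinase hydrolysis.

.sample_one <- function(ids, weights) {
  if (!length(ids)) abort("no eligible monomers to sample from")
  if (length(ids) == 1L) {
    return(ids)
  }
  sample(ids, 1L, prob = weights)
}

#' Build a synthetic cutin polymer
#'
#' Constructs a tree of monomers joined by directed ester edges (child
#' carboxyl to parent hydroxyl). Node 1 is the free-carboxyl root. With
#' `branching_prob = 0` (default) the polymer is a linear path; otherwise
#' each unused secondary hydroxyl may host an extra single-monomer branch.
#' `terminal_bias` multiplies the sampling weight of the designated terminal
#' monomers at the carboxyl root and the omega end, emulating the terminal
#' enrichment seen in labeling experiments.
#'
#' @param catalog Monomer catalog with a `sim_weight` column.
#' @param n_monomers Number of monomers in the backbone (>= 1).
#' @param terminal_bias Weight multiplier for terminal monomers (default 5).
#' @param branching_prob Probability that each spare secondary hydroxyl
#'   hosts a branch (default 0).
#' @param seed Integer seed (optional).
#' @param omega_terminal_ids,carboxyl_terminal_ids Monomers favoured at each
#'   end.
#' @return A `cutin_polymer`: list with `nodes` (tibble `node`, `id`),
#'   `edges` (tibble `parent`, `child`, `site`), `seed`.
#' @export
build_polymer <- function(catalog = default_catalog(), n_monomers,
                          terminal_bias = 5, branching_prob = 0,
                          seed = NULL,
                          omega_terminal_ids = c("16-OH-16:0", "18-OH-18:2"),
                          carboxyl_terminal_ids = c("16-OH-16:0", "18-OH-18:3")) {
  if (n_monomers < 1L) abort("n_monomers must be >= 1")
  if (terminal_bias < 0 || branching_prob < 0 || branching_prob > 1) {
    abort("terminal_bias must be >= 0 and branching_prob in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  has_oh <- vapply(catalog$oh, length, integer(1)) > 0L
  has_cooh <- vapply(catalog$carboxyls, length, integer(1)) > 0L
  w <- catalog$sim_weight
  hosts <- which(has_oh & has_cooh & w > 0)
  acids <- which(has_cooh & w > 0)
  if (!length(hosts)) abort("catalog lacks hydroxyl-bearing acids with sim_weight > 0")
  bias <- function(pool, favoured) {
    wt <- w[pool]
    wt[catalog$id[pool] %in% favoured] <- wt[catalog$id[pool] %in% favoured] * terminal_bias
    wt
  }
  ids <- character(n_monomers)
  if (n_monomers == 1L) {
    ids[1] <- .sample_one(catalog$id[acids], bias(acids, carboxyl_terminal_ids))
  } else {
    ids[1] <- .sample_one(catalog$id[hosts], bias(hosts, carboxyl_terminal_ids))
    if (n_monomers > 2L) {
      for (i in 2:(n_monomers - 1L)) {
        ids[i] <- .sample_one(catalog$id[hosts], w[hosts])
      }
    }
    ids[n_monomers] <- .sample_one(catalog$id[acids], bias(acids, omega_terminal_ids))
  }
  nodes <- tibble(node = seq_len(n_monomers), id = ids)
  edges <- if (n_monomers > 1L) {
    tibble(
      parent = seq_len(n_monomers - 1L),
      child = 2:n_monomers,
      site = vapply(
        catalog$oh[match(ids[-n_monomers], catalog$id)], max, integer(1)
      )
    )
  } else {
    tibble(parent = integer(0), child = integer(0), site = integer(0))
  }
  if (branching_prob > 0) {
    next_node <- n_monomers
    for (i in seq_len(n_monomers)) {
      oh <- catalog$oh[[match(ids[i], catalog$id)]]
      used <- edges$site[edges$parent == i]
      spare <- setdiff(oh, used)
      for (s in spare) {
        if (stats::runif(1) < branching_prob) {
          next_node <- next_node + 1L
          bid <- .sample_one(catalog$id[acids], w[acids])
          nodes <- dplyr::bind_rows(nodes, tibble(node = next_node, id = bid))
          edges <- dplyr::bind_rows(
            edges, tibble(parent = i, child = next_node, site = as.integer(s))
          )
        }
      }
    }
  }
  structure(
    list(nodes = nodes, edges = edges, seed = seed),
    class = "cutin_polymer"
  )
}

#' @export
print.cutin_polymer <- function(x, ...) {
  cat(
    "<cutin_polymer>", nrow(x$nodes), "monomers,",
    nrow(x$edges), "ester bonds\n"
  )
  invisible(x)
}

# linearize one subtree of the forest as an ordered oligomer; branched
# subtrees follow the longest root-to-leaf path (with a warning), since
# downstream sequencing handles linear candidates only
.linearize <- function(root, children, node_ids, catalog) {
  path <- integer(0)
  cur <- root
  branched <- FALSE
  repeat {
    path <- c(path, cur)
    kids <- children[[cur]]
    if (!length(kids)) break
    if (length(kids) > 1L) branched <- TRUE
    depth <- vapply(kids, function(k) {
      d <- 1L
      frontier <- k
      while (length(frontier)) {
        frontier <- unlist(children[frontier])
        if (length(frontier)) d <- d + 1L
      }
      d
    }, integer(1))
    cur <- kids[which.max(depth)]
  }
  if (branched) {
    warn("branched fragment linearized along its longest carboxyl-to-omega path")
  }
  oligomer(node_ids[path], catalog = catalog)
}

#' Partially digest a synthetic polymer
#'
#' Each ester edge is independently cleaved with probability `p_cleave`
#' (hydrolysis form: the child regains its carboxyl, the parent its
#' hydroxyl). The resulting subtrees are linearized to ordered oligomers.
#' The fragment count always equals the number of cleaved edges plus one
#' (tree property). Fragments longer than `max_frag_len` are kept, dropped,
#' or recursively re-digested according to `overlong`; fragments lacking a
#' free carboxyl (alcohol-rooted) are dropped when `negative_mode_filter` is
#' on, mirroring detection in negative ion mode.
#'
#' @param g A `cutin_polymer`.
#' @param p_cleave Cleavage probability per ester bond, in `[0, 1]`.
#' @param max_frag_len Length cap (default `Inf`).
#' @param overlong One of `"keep"`, `"discard"`, `"redigest"`.
#' @param negative_mode_filter Drop fragments with no free carboxyl?
#' @param seed Integer seed (optional).
#' @param catalog Catalog used to rebuild fragment oligomers.
#' @return A `cutin_digest`: list with `fragments` (list of
#'   `cutin_oligomer`), `n_cleaved`, `p_cleave`, `seed`.
#' @export
digest_polymer <- function(g, p_cleave, max_frag_len = Inf,
                           overlong = c("keep", "discard", "redigest"),
                           negative_mode_filter = TRUE, seed = NULL,
                           catalog = default_catalog()) {
  stopifnot(inherits(g, "cutin_polymer"))
  if (p_cleave < 0 || p_cleave > 1) abort("p_cleave must lie in [0, 1]")
  overlong <- match.arg(overlong)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(g$nodes)
  cleave <- if (nrow(g$edges)) stats::runif(nrow(g$edges)) < p_cleave else logical(0)
  parent_of <- rep(NA_integer_, n)
  kept <- g$edges[!cleave, , drop = FALSE]
  parent_of[kept$child] <- kept$parent
  children <- lapply(seq_len(n), function(i) kept$child[kept$parent == i])
  roots <- which(is.na(parent_of))
  node_ids <- g$nodes$id
  frags <- purrr::map(roots, .linearize,
    children = children, node_ids = node_ids, catalog = catalog
  )
  if (is.finite(max_frag_len)) {
    if (overlong == "discard") {
      frags <- purrr::keep(frags, ~ length(.x) <= max_frag_len)
    } else if (overlong == "redigest") {
      out <- list()
      for (f in frags) {
        queue <- list(f$monomers$id)
        while (length(queue)) {
          ids <- queue[[1]]
          queue <- queue[-1]
          if (length(ids) <= max_frag_len) {
            out[[length(out) + 1L]] <- oligomer(ids, catalog = catalog)
          } else {
            cut <- sample(length(ids) - 1L, 1L)
            queue <- c(queue, list(ids[seq_len(cut)], ids[(cut + 1L):length(ids)]))
          }
        }
      }
      frags <- out
    }
  }
  if (negative_mode_filter) {
    frags <- purrr::keep(frags, function(f) {
      length(f$monomers$carboxyls[[1]]) > 0L
    })
  }
  structure(
    list(
      fragments = frags, n_cleaved = sum(cleave),
      p_cleave = p_cleave, seed = seed
    ),
    class = "cutin_digest"
  )
}

#' @export
print.cutin_digest <- function(x, ...) {
  lens <- vapply(x$fragments, length, integer(1))
  cat(
    "<cutin_digest>", length(x$fragments), "fragments (lengths",
    paste(sort(unique(lens)), collapse = ","), ") from",
    x$n_cleaved, "cleaved bonds\n"
  )
  invisible(x)
}

#' Simulate a centroided MS/MS spectrum of an oligomer
#'
#' Theoretical peaks (ester-cleavage fragments for oligomers; the monomer ion
#' and its water losses for single monomers) are perturbed by Gaussian ppm
#' mass error; uniform-random noise peaks are added across the scan window.
#' True peaks have intensity 1; noise intensities are uniform on (0, 1).
#'
#' @param o A `cutin_oligomer`.
#' @param adduct Adduct (default `"[M-H]-"`).
#' @param mass_error_ppm_sigma Gaussian ppm error SD (default 0).
#' @param n_noise_peaks Number of noise peaks (default 0).
#' @param seed Integer seed (optional).
#' @param scan_range m/z window for noise peaks (default `c(100, 1700)`).
#' @param max_water_loss Water-loss cap for the theoretical peaks.
#' @return An `ms2_spectrum`; `source_id` records the true ordering.
#' @export
simulate_spectrum <- function(o, adduct = "[M-H]-", mass_error_ppm_sigma = 0,
                              n_noise_peaks = 0, seed = NULL,
                              scan_range = c(100, 1700), max_water_loss = 2L) {
  stopifnot(inherits(o, "cutin_oligomer"))
  if (mass_error_ppm_sigma < 0) abort("mass_error_ppm_sigma must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  theo <- if (length(o) >= 2L) {
    predict_ester_fragments(o, adduct = adduct, max_water_loss = max_water_loss)$mz
  } else {
    f <- parse_formula(o$monomers$formula[1])
    w <- 0:min(max_water_loss, length(o$monomers$oh[[1]]))
    vapply(w, function(wk) {
      fk <- f
      if (wk > 0) fk <- combine_formulas(fk, c(H = 2L * wk, O = wk), sign = -1L)
      ion_mz(fk, adduct)
    }, numeric(1))
  }
  mz <- theo * (1 + stats::rnorm(length(theo), 0, mass_error_ppm_sigma) * 1e-6)
  peaks <- tibble(mz = mz, intensity = 1)
  if (n_noise_peaks > 0) {
    peaks <- dplyr::bind_rows(peaks, tibble(
      mz = stats::runif(n_noise_peaks, scan_range[1], scan_range[2]),
      intensity = stats::runif(n_noise_peaks, 0, stats::median(peaks$intensity))
    ))
  }
  spectrum(
    precursor_mz = precursor_mz(o, adduct),
    peaks = peaks, adduct = adduct,
    source_id = paste(o$monomers$id, collapse = "/")
  )
}

#' Simulated trimer benchmark set
#'
#' Draws `n` random trimers of three distinct monomers (abundance-weighted,
#' positions 1-2 restricted to hydroxyl-bearing acids) and simulates a noisy
#' spectrum for each; the standard conditions are 5 ppm mass error and 5
#' noise peaks per spectrum.
#'
#' @param n Number of trimers.
#' @param catalog Monomer catalog.
#' @param seed Integer seed.
#' @param mass_error_ppm_sigma,n_noise_peaks Spectrum noise settings.
#' @return A tibble with list-columns `truth` (id vectors) and `spectrum`.
#' @export
simulate_trimer_benchmark <- function(n = 200L, catalog = default_catalog(),
                                      seed = 1L, mass_error_ppm_sigma = 5,
                                      n_noise_peaks = 5L) {
  set.seed(seed)
  has_oh <- vapply(catalog$oh, length, integer(1)) > 0L
  has_cooh <- vapply(catalog$carboxyls, length, integer(1)) > 0L
  w <- catalog$sim_weight
  hosts <- which(has_oh & has_cooh & w > 0)
  acids <- which(has_cooh & w > 0)
  rows <- purrr::map(seq_len(n), function(i) {
    repeat {
      a <- .sample_one(catalog$id[hosts], w[hosts])
      b <- .sample_one(catalog$id[hosts], w[hosts])
      c_ <- .sample_one(catalog$id[acids], w[acids])
      ids <- c(a, b, c_)
      if (length(unique(ids)) == 3L) break
    }
    o <- oligomer(ids, catalog = catalog)
    sp <- simulate_spectrum(o,
      mass_error_ppm_sigma = mass_error_ppm_sigma,
      n_noise_peaks = n_noise_peaks
    )
    tibble(truth = list(ids), spectrum = list(sp))
  })
  dplyr::bind_rows(rows)
}
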