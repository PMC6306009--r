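# A cutin oligomer is an ordered sequence of monomers joined by ester bonds.
# Position 1 is the free-carboxyl terminus; for every i >= 2, monomer i's
# carboxyl esterifies a hydroxyl of monomer i-1 (the omega hydroxyl unless a
# mid-chain linkage site is given). Mid-chain linkages do not change any
# fragment mass -- only free-hydroxyl counts -- which is precisely why MS
# alone cannot fix the regiochemistry of the ester bond.

#' Construct a cutin oligomer
#'
#' @param monomers A character vector of catalog ids (requires `catalog`) or a
#'   monomer tibble in sequence order; position 1 is the free-carboxyl
#'   terminus.
#' @param catalog Catalog used to resolve ids (default [default_catalog()]).
#' @param linkage_sites Integer vector of length `length - 1`: entry `i` is
#'   the hydroxyl position on monomer `i` esterified by monomer `i + 1`'s
#'   carboxyl. Defaults to each host's omega (highest-position) hydroxyl.
#' @param tags Optional tibble of derivatization tags with columns `index`
#'   (monomer position), `tag` (tag name) and `n_sites`.
#' @return A `cutin_oligomer` object.
#' @examples
#' o <- oligomer(c("16-OH-16:0", "9,10,18-triOH-18:0"))
#' round_mz(precursor_mz(o)) # 585.47
#' @export
oligomer <- function(monomers, catalog = default_catalog(),
                     linkage_sites = NULL, tags = NULL) {
  if (is.character(monomers)) {
    missing <- setdiff(monomers, catalog$id)
    if (length(missing)) {
      abort(paste0("monomer id(s) not in catalog: ", paste(missing, collapse = ", ")))
    }
    mono <- catalog[match(monomers, catalog$id), ]
  } else {
    stopifnot(is.data.frame(monomers), nrow(monomers) >= 1L)
    mono <- monomers
  }
  len <- nrow(mono)
  if (is.null(linkage_sites)) {
    linkage_sites <- vapply(seq_len(max(len - 1L, 0L)), function(i) {
      oh <- mono$oh[[i]]
      if (!length(oh)) {
        abort(paste0(
          "monomer ", i, " (", mono$id[i],
          ") has no hydroxyl to host the next ester bond"
        ))
      }
      max(oh)
    }, integer(1))
  }
  if (length(linkage_sites) != len - 1L) {
    abort("linkage_sites must have length(monomers) - 1 entries")
  }
  for (i in seq_along(linkage_sites)) {
    if (!linkage_sites[i] %in% mono$oh[[i]]) {
      abort(paste0(
        "linkage site ", linkage_sites[i], " is not a hydroxyl of monomer ",
        i, " (", mono$id[i], ")"
      ))
    }
  }
  if (len >= 1L && length(mono$carboxyls[[1]]) == 0L) {
    warn("position-1 monomer has no carboxyl; the oligomer lacks a free acid terminus")
  }
  if (len >= 2L) {
    no_acid <- which(vapply(mono$carboxyls[-1], length, integer(1)) == 0L) + 1L
    if (length(no_acid)) {
      abort(paste0(
        "monomer(s) at position(s) ", paste(no_acid, collapse = ", "),
        " lack a carboxyl and cannot acylate the previous monomer"
      ))
    }
  }
  if (!is.null(tags)) {
    stopifnot(all(c("index", "tag", "n_sites") %in% names(tags)))
    for (k in seq_len(nrow(tags))) derivatization_tag(tags$tag[k])
  }
  structure(
    list(
      monomers = mono,
      linkage_sites = as.integer(linkage_sites),
      tags = tags
    ),
    class = "cutin_oligomer"
  )
}

#' @export
print.cutin_oligomer <- function(x, ...) {
  cat("<cutin_oligomer> length", nrow(x$monomers), "\n")
  cat(" ", render_symbolic(x), "\n")
  cat("  neutral:", formula_string(oligomer_formula(x)),
      sprintf("(%.4f Da)", monoisotopic_mass(oligomer_formula(x))), "\n")
  invisible(x)
}

#' @export
length.cutin_oligomer <- function(x) nrow(x$monomers)

#' Neutral elemental formula of an oligomer
#'
#' Sum of the monomer formulas minus one water per ester bond, plus any
#' derivatization tag deltas.
#'
#' @param o A `cutin_oligomer`.
#' @return Named integer vector of element counts.
#' @export
oligomer_formula <- function(o) {
  stopifnot(inherits(o, "cutin_oligomer"))
  f <- Reduce(
    function(acc, fs) combine_formulas(acc, fs),
    o$monomers$formula,
    stats::setNames(integer(0), character(0))
  )
  n_ester <- nrow(o$monomers) - 1L
  if (n_ester > 0) {
    f <- combine_formulas(f, c(H = 2L * n_ester, O = n_ester), sign = -1L)
  }
  if (!is.null(o$tags)) {
    for (k in seq_len(nrow(o$tags))) {
      tg <- derivatization_tag(o$tags$tag[k])
      for (j in seq_len(o$tags$n_sites[k])) f <- combine_formulas(f, tg$delta)
    }
  }
  f
}

#' Precursor m/z of an oligomer
#'
#' @param o A `cutin_oligomer`.
#' @param adduct Adduct name or spec (default `"[M-H]-"`).
#' @return m/z at full precision.
#' @export
precursor_mz <- function(o, adduct = "[M-H]-") {
  ion_mz(oligomer_formula(o), adduct)
}

# free hydroxyl count of the contiguous sub-oligomer i..j in hydrolysis form:
# every internal linkage consumes one hydroxyl of its host; cleaved bonds
# regenerate the hydroxyl/carboxyl they used.
.sub_free_oh <- function(o, i, j) {
  total <- sum(vapply(o$monomers$oh[i:j], length, integer(1)))
  total - (j - i)
}

.sub_formula <- function(o, i, j) {
  f <- Reduce(
    function(acc, fs) combine_formulas(acc, fs),
    o$monomers$formula[i:j],
    stats::setNames(integer(0), character(0))
  )
  k <- j - i
  if (k > 0) f <- combine_formulas(f, c(H = 2L * k, O = k), sign = -1L)
  f
}

#' Predict ester-cleavage MS/MS fragments of an oligomer
#'
#' Every contiguous sub-oligomer obtainable by cleaving ester bonds is emitted
#' in hydrolysis form (full acid + alcohol termini), each with 0 to
#' `min(max_water_loss, free hydroxyls)` additional neutral water losses.
#' Terminal fragments require one cleavage; internal fragments (two
#' cleavages) are generated for oligomers of length >= 4 when
#' `include_internal` is `TRUE` (the default for length <= 6; the
#' combinatorial load grows as the square of the length). The intact
#' precursor itself is not a fragment.
#'
#' @param o A `cutin_oligomer` of length >= 2.
#' @param adduct Adduct for fragment ions (default `"[M-H]-"`).
#' @param max_water_loss Cap on serial water losses per fragment (default 2,
#'   the most ever observed in the spectra this models).
#' @param include_internal Generate two-cleavage internal fragments?
#' @return A tibble sorted by `mz` with columns `mz`, `species` (ids joined by
#'   `/`), `start`, `end`, `length`, `n_water_loss`, `formula`, `cleavage`.
#' @examples
#' tri <- oligomer(c(
#'   "18-OH-9,10-epoxy-18:1", "10,16-diOH-16:0", "18-OH-18:3"
#' ))
#' frags <- predict_ester_fragments(tri)
#' any(round_mz(frags$mz) == 581.44) # prefix dimer
#' @export
predict_ester_fragments <- function(o, adduct = "[M-H]-", max_water_loss = 2L,
                                    include_internal = NULL) {
  stopifnot(inherits(o, "cutin_oligomer"))
  len <- nrow(o$monomers)
  if (len < 2L) abort("predict_ester_fragments requires an oligomer of length >= 2")
  if (max_water_loss < 0L) abort("max_water_loss must be >= 0")
  include_internal <- include_internal %||% (len <= 6L)
  ad <- adduct_spec(adduct)
  z <- abs(ad$charge)
  delta_mass <- monoisotopic_mass(.formula_canonical(ad$delta))
  els <- c("C", "H", "Li", "N", "Na", "O", "S") # Hill order
  am <- .ATOMIC_MASS[els]
  M <- matrix(0L, nrow = len, ncol = length(els), dimnames = list(NULL, els))
  for (i in seq_len(len)) {
    f <- .parse_formula_cached(o$monomers$formula[i])
    M[i, names(f)] <- f
  }
  if (!is.null(o$tags)) {
    for (k in seq_len(nrow(o$tags))) {
      tg <- derivatization_tag(o$tags$tag[k])
      idx <- o$tags$index[k]
      M[idx, names(tg$delta)] <- M[idx, names(tg$delta)] +
        tg$delta * o$tags$n_sites[k]
    }
  }
  oh_counts <- vapply(o$monomers$oh, length, integer(1))
  mz_v <- numeric(0)
  species_v <- character(0)
  start_v <- integer(0)
  end_v <- integer(0)
  w_v <- integer(0)
  formula_v <- character(0)
  cleav_v <- character(0)
  for (i in seq_len(len)) {
    for (j in i:len) {
      if (i == 1L && j == len) next
      # single monomers are always emitted; longer internal (two-cleavage)
      # fragments only for length >= 4 when enabled
      internal <- i > 1L && j < len && j > i
      if (internal && (len < 4L || !include_internal)) next
      k <- j - i
      cnt <- if (k == 0L) M[i, ] else colSums(M[i:j, , drop = FALSE])
      cnt[["H"]] <- cnt[["H"]] - 2L * k
      cnt[["O"]] <- cnt[["O"]] - k
      free_oh <- sum(oh_counts[i:j]) - k
      species <- paste(o$monomers$id[i:j], collapse = "/")
      cleav <- paste0(
        if (i > 1L) paste0("ester ", i - 1L, "-", i) else NULL,
        if (i > 1L && j < len) " + " else NULL,
        if (j < len) paste0("ester ", j, "-", j + 1L) else NULL
      )
      for (wk in 0:min(max_water_loss, free_oh)) {
        cw <- cnt
        cw[["H"]] <- cw[["H"]] - 2L * wk
        cw[["O"]] <- cw[["O"]] - wk
        mz_v <- c(mz_v, (sum(cw * am) + delta_mass) / z)
        species_v <- c(species_v, species)
        start_v <- c(start_v, i)
        end_v <- c(end_v, j)
        w_v <- c(w_v, wk)
        formula_v <- c(formula_v, .formula_string_counts(cw))
        cleav_v <- c(cleav_v, cleav)
      }
    }
  }
  out <- tibble::new_tibble(
    list(
      mz = mz_v, species = species_v, start = start_v, end = end_v,
      length = end_v - start_v + 1L, n_water_loss = w_v,
      formula = formula_v, cleavage = cleav_v
    ),
    nrow = length(mz_v)
  )
  out <- out[!duplicated(data.frame(round_mz(out$mz, 4), out$species, out$n_water_loss)), ]
  out[order(out$mz, out$species), ]
}

# ---------------------------------------------------------------------------
# Chain-cleavage (C-C) diagnostic ions for hydroxyl/epoxy localization.
#
# Model: homolytic cleavage of each C-C bond flanking an oxygen-bearing
# mid-chain carbon. Per-carbon hydrogens are counted on a saturated backbone
# (carboxyl carbon 1 H; CH2 and CHOH 2 H; epoxide CH 1 H; terminal CH3 or
# CH2OH 3 H); double-bond hydrogens are removed from the omega-side fragment
# because double-bond positions are not encoded in the descriptors. Each side
# is then offered with hydrogen-transfer offsets {-1, 0, +1} and 0-1 water
# loss. When the cleaved bond lies inside an epoxide span the bridging oxygen
# can depart with either side, so both assignments are generated. These are
# candidate species for matching observed diagnostics, not asserted formulas.

.carbon_h_saturated <- function(m) {
  n <- m$n
  oh <- m$oh[[1]]
  epoxy_carbons <- unique(c(m$epoxy[[1]], m$epoxy[[1]] + 1L))
  carbox <- m$carboxyls[[1]]
  h <- rep(2L, n)
  h[carbox] <- 1L
  if (n %in% carbox == FALSE && !(n %in% epoxy_carbons)) h[n] <- 3L
  h[intersect(epoxy_carbons, seq_len(n))] <- 1L
  # CHOH keeps 2 H total (1 on C + 1 on O); CH2OH terminal keeps 3
  h
}

.carbon_o <- function(m) {
  n <- m$n
  o <- rep(0L, n)
  o[m$carboxyls[[1]]] <- 2L
  o[m$oh[[1]]] <- o[m$oh[[1]]] + 1L
  o
}

#' Predict chain-cleavage (C-C) diagnostic ions for a monomer
#'
#' Generates candidate fragment ions from cleavage of the C-C bonds flanking
#' each oxygen-bearing mid-chain carbon (hydroxyl positions and epoxide
#' carbons; the carboxyl carbon does not count). A monomer with no such
#' function yields an empty result. Candidates should be matched against
#' observed peaks with a looser tolerance (0.03 Da) than ester fragments.
#'
#' @param m A one-row monomer tibble or a catalog id (with `catalog`).
#' @param adduct Adduct for candidate ions (default `"[M-H]-"`).
#' @param catalog Catalog for id resolution.
#' @return A tibble with columns `mz`, `formula`, `bond` (cleaved bond as its
#'   lower carbon), `side` (`"carboxyl"`/`"omega"`), `h_offset`,
#'   `n_water_loss`, deduplicated by resulting formula and sorted by `mz`.
#' @examples
#' nrow(predict_chain_cleavage_ions(parse_shorthand("16:0"))) # 0
#' @export
predict_chain_cleavage_ions <- function(m, adduct = "[M-H]-",
                                        catalog = default_catalog()) {
  if (is.character(m)) {
    stopifnot(m %in% catalog$id)
    m <- catalog[catalog$id == m, ]
  }
  stopifnot(is.data.frame(m), nrow(m) == 1L)
  n <- m$n
  d <- m$d
  epoxy <- m$epoxy[[1]]
  oxy_carbons <- sort(unique(c(
    setdiff(m$oh[[1]], m$carboxyls[[1]]),
    epoxy, epoxy + 1L
  )))
  if (!length(oxy_carbons)) {
    return(tibble(
      mz = numeric(0), formula = character(0), bond = integer(0),
      side = character(0), h_offset = integer(0), n_water_loss = integer(0)
    ))
  }
  bonds <- sort(unique(c(oxy_carbons - 1L, oxy_carbons)))
  bonds <- bonds[bonds >= 1L & bonds <= n - 1L]
  h_sat <- .carbon_h_saturated(m)
  o_cnt <- .carbon_o(m)
  rows <- list()
  ad <- adduct_spec(adduct)
  emit <- function(counts, bond, side, h_off, w) {
    if (any(counts < 0)) {
      return()
    }
    f <- .formula_canonical(counts)
    # the candidate must survive ionization (e.g. have a proton to lose)
    ionizable <- tryCatch(
      {
        combine_formulas(f, ad$delta)
        TRUE
      },
      error = function(e) FALSE
    )
    if (!ionizable) {
      return()
    }
    rows[[length(rows) + 1L]] <<- tibble(
      mz = ion_mz(f, adduct), formula = formula_string(f),
      bond = bond, side = side, h_offset = h_off, n_water_loss = w
    )
  }
  for (b in bonds) {
    # epoxide oxygen assignment(s) for each span relative to this bond
    assignments <- list(vapply(epoxy, function(p) {
      if (b < p) "omega" else if (b > p) "carboxyl" else "carboxyl"
    }, character(1)))
    if (any(epoxy == b)) {
      alt <- assignments[[1]]
      alt[epoxy == b] <- "omega"
      assignments <- c(assignments, list(alt))
    }
    for (asg in assignments) {
      o_cbx <- sum(o_cnt[seq_len(b)]) + sum(asg == "carboxyl")
      o_omg <- sum(o_cnt[(b + 1L):n]) + sum(asg == "omega")
      h_cbx <- sum(h_sat[seq_len(b)])
      h_omg <- max(sum(h_sat[(b + 1L):n]) - 2L * d, 0L)
      for (h_off in -1:1) {
        for (w in 0:1) {
          base_c <- c(C = b, H = h_cbx + h_off - 2L * w, O = o_cbx - w)
          base_o <- c(C = n - b, H = h_omg + h_off - 2L * w, O = o_omg - w)
          if (w == 0L || o_cbx >= 1L) emit(base_c, b, "carboxyl", h_off, w)
          if (w == 0L || o_omg >= 1L) emit(base_o, b, "omega", h_off, w)
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::distinct(out, .data$formula, .keep_all = TRUE)
  dplyr::arrange(out, .data$mz)
}
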