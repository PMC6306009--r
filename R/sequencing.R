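# De novo sequencing of cutin oligomers: decompose a precursor mass into
# monomer multisets, enumerate the distinct orderings of each multiset, score
# every ordering by how many of its predicted ester-cleavage fragments are
# observed, and rank. The score formalizes the qualitative presence/absence
# reasoning used to read daughter-ion spectra; intensities are recorded but
# unused by default.

.pkg_cache <- new.env(parent = emptyenv())

# all multisets of size k from n items, as a k x N index matrix
.multiset_indices <- function(n, k) {
  stopifnot(k >= 1L)
  M <- matrix(seq_len(n), nrow = 1L)
  if (k == 1L) {
    return(M)
  }
  for (step in 2:k) {
    last <- M[nrow(M), ]
    counts <- n - last + 1L
    keep <- rep(seq_len(ncol(M)), counts)
    newlast <- sequence(counts) + rep(last, counts) - 1L
    M <- rbind(M[, keep, drop = FALSE], newlast)
  }
  M
}

.cached_multisets <- function(catalog_ids, k) {
  key <- paste0(.fnv1a(paste(catalog_ids, collapse = "\x1f")), "_", k)
  if (is.null(.pkg_cache[[key]])) {
    .pkg_cache[[key]] <- .multiset_indices(length(catalog_ids), k)
  }
  .pkg_cache[[key]]
}

#' Construct a centroided MS/MS spectrum
#'
#' @param precursor_mz Precursor m/z.
#' @param peaks A data frame with columns `mz` and (optionally) `intensity`,
#'   or a numeric vector of m/z values. Peaks are sorted ascending by m/z.
#' @param adduct Ionization assumed for the precursor (default `"[M-H]-"`).
#' @param source_id Free-text provenance label.
#' @return An `ms2_spectrum` object.
#' @export
spectrum <- function(precursor_mz, peaks, adduct = "[M-H]-", source_id = "") {
  if (is.numeric(peaks)) peaks <- tibble(mz = peaks, intensity = 1)
  peaks <- as_tibble(peaks)
  if (!"intensity" %in% names(peaks)) peaks$intensity <- 1
  stopifnot(is.numeric(peaks$mz))
  if (nrow(peaks) > 0 && any(peaks$mz <= 0)) abort("peak m/z must be > 0")
  if (nrow(peaks) > 0 && any(peaks$intensity < 0)) abort("intensities must be >= 0")
  if (precursor_mz <= 0) abort("precursor m/z must be > 0")
  adduct_spec(adduct)
  peaks <- dplyr::arrange(peaks[, c("mz", "intensity")], .data$mz)
  structure(
    list(
      precursor_mz = precursor_mz,
      adduct = if (is.character(adduct)) adduct else adduct$name,
      peaks = peaks, source_id = source_id
    ),
    class = "ms2_spectrum"
  )
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ms2_spectrum> precursor %.4f %s, %d peaks%s\n",
    x$precursor_mz, x$adduct, nrow(x$peaks),
    if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""
  ))
  invisible(x)
}

# oligomer length windows implied by the monomer m/z window 164-331:
# an n-mer precursor falls in [164 n, 331 n] (dimers 328-662, trimers
# 492-993, tetramers 656-1324)
.lengths_for_mz <- function(mz, max_len = 6L) {
  k <- seq_len(max_len)
  k[mz >= 164 * k & mz <= 331 * k]
}

#' Decompose a precursor m/z into monomer multisets
#'
#' Exhaustively enumerates all multisets of catalog acids of the requested
#' lengths and returns exactly those whose oligomer ion (sum of monomer
#' formulas minus one water per ester bond, ionized with `adduct`) falls
#' within `tol_da` of the precursor. Fatty alcohols are excluded unless
#' `include_alcohols = TRUE`. Compositions sharing an elemental formula are
#' flagged isobaric, never merged.
#'
#' @param mz Precursor m/z.
#' @param catalog Monomer catalog (default [default_catalog()]).
#' @param adduct Adduct name or spec (default `"[M-H]-"`).
#' @param min_len,max_len Oligomer length bounds (`max_len` capped at 6).
#' @param tol_da Absolute tolerance in Da (default 0.02).
#' @param include_alcohols Allow fatty-alcohol catalog entries?
#' @return A tibble sorted by absolute mass error with columns `composition`
#'   (list of sorted id vectors), `n_monomers`, `formula`, `theoretical_mz`,
#'   `error_da`, `error_ppm`, `isobar`.
#' @examples
#' decompose_precursor(585.47, min_len = 2, max_len = 2)
#' @export
decompose_precursor <- function(mz, catalog = default_catalog(),
                                adduct = "[M-H]-", min_len = 1L, max_len = 4L,
                                tol_da = 0.02, include_alcohols = FALSE) {
  if (max_len > 6L) abort("max_len is capped at 6 (combinatorial bound)")
  if (min_len < 1L || min_len > max_len) abort("need 1 <= min_len <= max_len")
  if (tol_da < 0) abort("tol_da must be >= 0")
  elig <- if (include_alcohols) catalog else catalog[!catalog$alcohol, ]
  if (nrow(elig) == 0L) abort("catalog has no eligible monomers")
  ad <- adduct_spec(adduct)
  delta_mass <- monoisotopic_mass(.formula_canonical(ad$delta))
  z <- abs(ad$charge)
  hits <- list()
  for (k in min_len:max_len) {
    idx <- .cached_multisets(elig$id, k)
    sums <- if (k == 1L) elig$mass[idx[1, ]] else colSums(matrix(elig$mass[idx], nrow = k))
    theo <- (sums - (k - 1L) * .MASS_H2O + delta_mass) / z
    sel <- which(abs(theo - mz) <= tol_da)
    if (length(sel)) {
      hits[[length(hits) + 1L]] <- tibble(
        composition = purrr::map(sel, function(s) sort(elig$id[idx[, s]])),
        n_monomers = k,
        theoretical_mz = theo[sel]
      )
    }
  }
  if (!length(hits)) {
    return(tibble(
      composition = list(), n_monomers = integer(0), formula = character(0),
      theoretical_mz = numeric(0), error_da = numeric(0),
      error_ppm = numeric(0), isobar = logical(0)
    ))
  }
  out <- dplyr::bind_rows(hits)
  out$formula <- vapply(seq_len(nrow(out)), function(i) {
    ids <- out$composition[[i]]
    f <- Reduce(combine_formulas, elig$formula[match(ids, elig$id)],
      stats::setNames(integer(0), character(0))
    )
    k <- length(ids)
    if (k > 1L) f <- combine_formulas(f, c(H = 2L * (k - 1L), O = k - 1L), sign = -1L)
    formula_string(f)
  }, character(1))
  out <- dplyr::mutate(out,
    error_da = mz - .data$theoretical_mz,
    error_ppm = .data$error_da / .data$theoretical_mz * 1e6
  )
  out <- dplyr::mutate(out,
    isobar = duplicated(.data$formula) | duplicated(.data$formula, fromLast = TRUE)
  )
  out <- dplyr::arrange(out, abs(.data$error_da), .data$n_monomers)
  out[, c(
    "composition", "n_monomers", "formula", "theoretical_mz",
    "error_da", "error_ppm", "isobar"
  )]
}

# distinct permutations of a multiset of ids (multinomial enumeration)
.multiset_perms <- function(ids) {
  tab <- table(ids)
  uniq <- names(tab)
  counts <- as.integer(tab)
  total <- sum(counts)
  rec <- function(counts, acc) {
    if (sum(counts) == 0L) {
      return(list(acc))
    }
    out <- list()
    for (u in seq_along(uniq)) {
      if (counts[u] > 0L) {
        counts[u] <- counts[u] - 1L
        out <- c(out, rec(counts, c(acc, uniq[u])))
        counts[u] <- counts[u] + 1L
      }
    }
    out
  }
  rec(counts, character(0))
}

#' Score one candidate ordering against an observed spectrum
#'
#' The score is the number of distinct observed peaks explained by at least
#' one predicted ester-cleavage peak (from [predict_ester_fragments()])
#' within tolerance. Counting explained *observed* ions rather than matched
#' *predictions* prevents several isobaric predictions (e.g. water-loss
#' forms of different sub-oligomers that collapse onto one mass) from
#' inflating a candidate through a single ion. Matching is
#' presence/absence; set `intensity_weighted = TRUE` to sum the matched
#' observed intensities instead.
#'
#' @param o A `cutin_oligomer` (length >= 2).
#' @param spec An `ms2_spectrum`.
#' @param tol_da Match tolerance in Da (default 0.02).
#' @param max_water_loss Water-loss cap passed to the fragment predictor.
#' @param include_internal Score two-cleavage internal fragments? Off by
#'   default: internal fragments require two backbone cleavages, are weak in
#'   practice, and scoring them lets implausible orderings explain terminal
#'   ions via internal coincidences.
#' @param intensity_weighted Weight matches by observed intensity?
#' @return A list with `score`, `n_predicted`, `water_losses_invoked` and the
#'   `matches` evidence tibble (one row per predicted peak).
#' @export
score_ordering <- function(o, spec, tol_da = 0.02, max_water_loss = 2L,
                           include_internal = FALSE,
                           intensity_weighted = FALSE) {
  stopifnot(inherits(spec, "ms2_spectrum"))
  pred <- predict_ester_fragments(o,
    adduct = spec$adduct, max_water_loss = max_water_loss,
    include_internal = include_internal
  )
  obs <- spec$peaks
  if (nrow(obs) == 0L || nrow(pred) == 0L) {
    pred$observed_mz <- rep(NA_real_, nrow(pred))
    pred$observed_intensity <- rep(NA_real_, nrow(pred))
    pred$error_da <- rep(NA_real_, nrow(pred))
    pred$matched <- rep(FALSE, nrow(pred))
    return(list(
      score = 0, n_predicted = nrow(pred), n_matched_predicted = 0L,
      water_losses_invoked = 0L, matches = pred
    ))
  }
  nearest <- vapply(pred$mz, function(p) which.min(abs(obs$mz - p)), integer(1))
  err <- obs$mz[nearest] - pred$mz
  matched <- abs(err) <= tol_da
  pred$observed_mz <- ifelse(matched, obs$mz[nearest], NA_real_)
  pred$observed_intensity <- ifelse(matched, obs$intensity[nearest], NA_real_)
  pred$error_da <- ifelse(matched, err, NA_real_)
  pred$matched <- matched
  explained <- unique(nearest[matched])
  score <- if (intensity_weighted) {
    sum(obs$intensity[explained])
  } else {
    length(explained)
  }
  # parsimony: each explained observed peak is attributed to the predicted
  # fragment that needs the fewest water losses to account for it
  invoked <- sum(vapply(explained, function(oi) {
    min(pred$n_water_loss[matched & nearest == oi])
  }, numeric(1)))
  list(
    score = score,
    n_predicted = nrow(pred),
    n_matched_predicted = sum(matched),
    water_losses_invoked = invoked,
    matches = pred
  )
}

#' Sequence an MS/MS spectrum of a cutin oligomer
#'
#' For each composition candidate of the precursor (see
#' [decompose_precursor()]), enumerates the distinct orderings of the
#' multiset, discards orderings whose non-terminal monomers lack a hydroxyl to
#' host the next ester bond, scores every remaining ordering against the
#' observed peaks and ranks them. Equal scores share a dense rank and are
#' reported as ambiguous, never silently broken; within a rank, orderings are
#' sorted by fewer invoked water losses among matched peaks, then smaller
#' composition mass error, then lexicographic symbolic serialization. Note
#' that a full reversal of a sequence predicts the same fragment masses, so a
#' reversal that is itself a valid oligomer always ties its mirror image:
#' direction beyond the free-carboxyl convention requires labeling evidence.
#'
#' For trimer candidates the central-monomer evidence of the top rank is
#' populated: a monomer shared by two matched dimer daughters must occupy the
#' central position.
#'
#' @param spec An `ms2_spectrum`.
#' @param catalog Monomer catalog.
#' @param min_len,max_len Length bounds; derived from the precursor m/z via
#'   the monomer window (164-331 per unit) when `NULL`.
#' @param tol_da Fragment match tolerance in Da.
#' @param precursor_tol_da Composition search tolerance around the precursor
#'   (default `max(0.1, tol_da)`): precursor isolation is physically much
#'   wider than fragment mass accuracy, and reported precursor values drift
#'   accordingly. Wrong compositions admitted by the wider window are scored
#'   down by their fragments rather than excluded a priori.
#' @param max_water_loss Water-loss cap per fragment.
#' @param intensity_weighted Passed to [score_ordering()].
#' @return A `cutin_sequencing` object; see [tidy.cutin_sequencing()].
#' @export
sequence_spectrum <- function(spec, catalog = default_catalog(),
                              min_len = NULL, max_len = NULL, tol_da = 0.02,
                              precursor_tol_da = max(0.1, tol_da),
                              max_water_loss = 2L, intensity_weighted = FALSE) {
  stopifnot(inherits(spec, "ms2_spectrum"))
  if (is.null(min_len) || is.null(max_len)) {
    ks <- .lengths_for_mz(spec$precursor_mz)
    ks <- ks[ks >= 2L]
    if (!length(ks)) ks <- 2:4
    min_len <- min_len %||% min(ks)
    max_len <- max_len %||% max(ks)
  }
  params <- list(
    min_len = min_len, max_len = max_len, tol_da = tol_da,
    precursor_tol_da = precursor_tol_da,
    max_water_loss = max_water_loss, intensity_weighted = intensity_weighted,
    adduct = spec$adduct, catalog_checksum = catalog_checksum(catalog)
  )
  comps <- decompose_precursor(
    spec$precursor_mz,
    catalog = catalog, adduct = spec$adduct,
    min_len = min_len, max_len = max_len, tol_da = precursor_tol_da
  )
  empty_result <- function(diagnostic) {
    structure(
      list(
        ranking = tibble(
          rank = integer(0), sequence = character(0), symbolic = character(0),
          length = integer(0), score = numeric(0), n_predicted = integer(0),
          n_matched_predicted = integer(0),
          water_losses_invoked = integer(0), mass_error_da = numeric(0),
          isobar = logical(0)
        ),
        matches = list(), central_evidence = NULL, ambiguity = FALSE,
        spectrum = spec, params = params, diagnostic = diagnostic
      ),
      class = "cutin_sequencing"
    )
  }
  if (nrow(comps) == 0L) {
    return(empty_result(sprintf(
      "no monomer composition within %.3g Da of precursor %.4f for lengths %d-%d",
      precursor_tol_da, spec$precursor_mz, min_len, max_len
    )))
  }
  acc <- list(
    sequence = character(0), symbolic = character(0), length = integer(0),
    score = numeric(0), n_predicted = integer(0),
    n_matched_predicted = integer(0),
    water_losses_invoked = numeric(0), mass_error_da = numeric(0),
    isobar = logical(0)
  )
  evidences <- list()
  oh_len <- vapply(catalog$oh, length, integer(1))
  for (ci in seq_len(nrow(comps))) {
    ids <- comps$composition[[ci]]
    perms <- .multiset_perms(ids)
    for (p in perms) {
      hosts <- p[-length(p)]
      if (length(hosts) && any(oh_len[match(hosts, catalog$id)] == 0L)) next
      o <- oligomer(p, catalog = catalog)
      sc <- score_ordering(o, spec,
        tol_da = tol_da, max_water_loss = max_water_loss,
        intensity_weighted = intensity_weighted
      )
      acc$sequence <- c(acc$sequence, paste(p, collapse = "/"))
      acc$symbolic <- c(acc$symbolic, render_symbolic(o))
      acc$length <- c(acc$length, length(p))
      acc$score <- c(acc$score, sc$score)
      acc$n_predicted <- c(acc$n_predicted, sc$n_predicted)
      acc$n_matched_predicted <- c(acc$n_matched_predicted, sc$n_matched_predicted)
      acc$water_losses_invoked <- c(acc$water_losses_invoked, sc$water_losses_invoked)
      acc$mass_error_da <- c(acc$mass_error_da, comps$error_da[ci])
      acc$isobar <- c(acc$isobar, comps$isobar[ci])
      evidences[[length(evidences) + 1L]] <- sc$matches
    }
  }
  if (!length(acc$sequence)) {
    return(empty_result(
      "composition(s) found but no ordering satisfies the linkage constraints"
    ))
  }
  ranking <- tibble::new_tibble(acc, nrow = length(acc$sequence))
  # deterministic order within a score: fewest invoked water losses, then
  # the most corroborated candidate (more predicted fragments supported by
  # the spectrum), then composition error, then symbolic text
  ord <- order(
    -ranking$score, ranking$water_losses_invoked,
    -ranking$n_matched_predicted,
    abs(ranking$mass_error_da), ranking$symbolic
  )
  ranking <- ranking[ord, ]
  evidences <- evidences[ord]
  ranking$rank <- as.integer(dplyr::dense_rank(-ranking$score))
  ranking <- ranking[, c(
    "rank", "sequence", "symbolic", "length", "score", "n_predicted",
    "n_matched_predicted", "water_losses_invoked", "mass_error_da", "isobar"
  )]
  ambiguity <- sum(ranking$rank == 1L) > 1L
  central <- .central_evidence(ranking, evidences)
  structure(
    list(
      ranking = ranking, matches = evidences, central_evidence = central,
      ambiguity = ambiguity, spectrum = spec, params = params,
      diagnostic = NA_character_
    ),
    class = "cutin_sequencing"
  )
}

# central-monomer logic for trimer candidates: the monomer present in both
# matched dimer daughters must occupy the central position
.central_evidence <- function(ranking, evidences) {
  top <- which(ranking$rank == 1L & ranking$length == 3L)
  if (!length(top)) {
    return(NULL)
  }
  i <- top[1]
  ev <- evidences[[i]]
  dim12 <- ev[ev$length == 2L & ev$start == 1L & ev$matched, , drop = FALSE]
  dim23 <- ev[ev$length == 2L & ev$start == 2L & ev$matched, , drop = FALSE]
  if (nrow(dim12) == 0L || nrow(dim23) == 0L) {
    return(NULL)
  }
  seq_ids <- stringr::str_split_1(ranking$sequence[i], stringr::fixed("/"))
  tibble(
    central_monomer = seq_ids[2],
    dimer_daughter_1 = dim12$species[1],
    dimer_daughter_1_mz = dim12$observed_mz[1],
    dimer_daughter_2 = dim23$species[1],
    dimer_daughter_2_mz = dim23$observed_mz[1],
    statement = paste0(
      seq_ids[2], " is common to both matched dimer daughters (",
      sprintf("%.2f", dim12$observed_mz[1]), ", ",
      sprintf("%.2f", dim23$observed_mz[1]),
      ") and therefore occupies the central position"
    )
  )
}

#' @export
print.cutin_sequencing <- function(x, ...) {
  cat("<cutin_sequencing>\n")
  cat(sprintf(
    "  precursor %.4f %s, %d observed peaks\n",
    x$spectrum$precursor_mz, x$spectrum$adduct, nrow(x$spectrum$peaks)
  ))
  if (!is.na(x$diagnostic)) cat("  diagnostic:", x$diagnostic, "\n")
  if (nrow(x$ranking)) {
    cat(sprintf(
      "  %d candidate ordering(s); top score %g%s\n",
      nrow(x$ranking), x$ranking$score[1],
      if (x$ambiguity) " (tied; ambiguous)" else ""
    ))
    print(utils::head(x$ranking, 5))
  }
  if (!is.null(x$central_evidence)) {
    cat("  central evidence:", x$central_evidence$statement, "\n")
  }
  invisible(x)
}

#' Tidy a sequencing result
#'
#' @param x A `cutin_sequencing` object.
#' @param ... Unused.
#' @return The ranking tibble (one row per candidate ordering).
#' @export
tidy.cutin_sequencing <- function(x, ...) x$ranking

#' @rdname tidy.cutin_sequencing
#' @return For `glance()`: a one-row summary tibble.
#' @export
glance.cutin_sequencing <- function(x, ...) {
  tibble(
    precursor_mz = x$spectrum$precursor_mz,
    n_peaks = nrow(x$spectrum$peaks),
    n_orderings = nrow(x$ranking),
    top_score = if (nrow(x$ranking)) x$ranking$score[1] else NA_real_,
    top_sequence = if (nrow(x$ranking)) x$ranking$sequence[1] else NA_character_,
    ambiguity = x$ambiguity
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Mirror plot of observed peaks against the top ordering's predictions
#'
#' @param object A `cutin_sequencing` object with at least one candidate.
#' @param ... Unused.
#' @return A ggplot: observed peaks point up, predicted peaks of the
#'   top-ranked ordering point down, matched predictions highlighted.
#' @export
autoplot.cutin_sequencing <- function(object, ...) {
  stopifnot(nrow(object$ranking) > 0L)
  obs <- object$spectrum$peaks
  pred <- object$matches[[1]]
  pred$rel <- -1
  obs$rel <- obs$intensity / max(obs$intensity)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = obs,
      ggplot2::aes(x = .data$mz, xend = .data$mz, y = 0, yend = .data$rel),
      color = "grey30"
    ) +
    ggplot2::geom_segment(
      data = pred,
      ggplot2::aes(
        x = .data$mz, xend = .data$mz, y = 0, yend = .data$rel,
        color = .data$matched
      )
    ) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#1b9e77", `FALSE` = "#d95f02")) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(
      x = "m/z", y = "observed (up) / predicted (down)",
      color = "matched",
      title = object$ranking$sequence[1]
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Assemble overlapping subfragment sequences
#'
#' For each ordered pair of fragment sequences where a suffix of the first
#' equals a prefix of the second (monomer ids, in order) with overlap length
#' `k >= min_overlap`, emits the merged sequence; longer overlaps give
#' greater confidence and sort first.
#'
#' @param fragments A list of character id vectors, `cutin_oligomer`s, or
#'   `cutin_sequencing` results (top-ranked sequence taken).
#' @param min_overlap Minimum overlap length (>= 1).
#' @return A tibble with columns `i`, `j` (fragment indices), `overlap`,
#'   `merged` (list-column of id vectors) and `sequence`.
#' @examples
#' assemble_overlaps(list(c("X", "Y", "Z"), c("Y", "Z", "W")))
#' @export
assemble_overlaps <- function(fragments, min_overlap = 1L) {
  if (min_overlap < 1L) abort("min_overlap must be >= 1")
  seqs <- purrr::map(fragments, function(f) {
    if (inherits(f, "cutin_oligomer")) {
      return(f$monomers$id)
    }
    if (inherits(f, "cutin_sequencing")) {
      if (nrow(f$ranking) == 0L) {
        return(character(0))
      }
      return(stringr::str_split_1(f$ranking$sequence[1], stringr::fixed("/")))
    }
    as.character(f)
  })
  rows <- list()
  for (i in seq_along(seqs)) {
    for (j in seq_along(seqs)) {
      if (i == j) next
      u <- seqs[[i]]
      v <- seqs[[j]]
      if (!length(u) || !length(v)) next
      for (k in seq(min_overlap, min(length(u), length(v)))) {
        if (identical(
          u[(length(u) - k + 1L):length(u)], v[seq_len(k)]
        )) {
          merged <- c(u, if (k < length(v)) v[(k + 1L):length(v)] else character(0))
          rows[[length(rows) + 1L]] <- tibble(
            i = i, j = j, overlap = k,
            merged = list(merged),
            sequence = paste(merged, collapse = "/")
          )
        }
      }
    }
  }
  if (!length(rows)) {
    return(tibble(
      i = integer(0), j = integer(0), overlap = integer(0),
      merged = list(), sequence = character(0)
    ))
  }
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$overlap), .data$i, .data$j)
}
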