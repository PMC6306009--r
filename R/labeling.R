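# Interpretation of derivatized-cutin experiments. A monomer recovered WITH a
# tag had that group free (non-esterified) in the intact polymer; recovered
# WITHOUT the tag, the group was engaged in an ester bond. Ratios of the two
# populations, aggregated over replicates, are summarized as log2 ratios with
# a delta-method standard error.

#' m/z of a derivatized monomer ion
#'
#' Adds `n_sites` copies of a derivatization tag delta to the monomer's
#' neutral formula and ionizes. Dansyl and DmPA derivatives are detected in
#' positive mode, hence the `"[M+H]+"` default.
#'
#' @param m A one-row monomer tibble or a catalog id.
#' @param tag Tag name or spec (see [derivatization_tags()]).
#' @param n_sites Number of labeled sites (must not exceed the monomer's free
#'   sites of the tag's class; 0 returns the unmodified ion).
#' @param adduct Adduct (default `"[M+H]+"`).
#' @param catalog Catalog for id resolution.
#' @return m/z at full precision.
#' @examples
#' round_mz(derivatized_mz("16-OH-16:0", "dansyl"), 3) # 506.294
#' @export
derivatized_mz <- function(m, tag, n_sites = 1L, adduct = "[M+H]+",
                           catalog = default_catalog()) {
  if (is.character(m)) {
    stopifnot(m %in% catalog$id)
    m <- catalog[catalog$id == m, ]
  }
  stopifnot(is.data.frame(m), nrow(m) == 1L)
  tg <- derivatization_tag(tag)
  avail <- if (tg$site_class == "hydroxyl") {
    length(m$oh[[1]])
  } else {
    length(m$carboxyls[[1]])
  }
  if (n_sites > avail) {
    abort(sprintf(
      "%d %s site(s) requested but %s has only %d",
      n_sites, tg$site_class, m$id, avail
    ))
  }
  f <- parse_formula(m$formula)
  for (k in seq_len(n_sites)) f <- combine_formulas(f, tg$delta)
  ion_mz(f, adduct)
}

#' Log2 free/esterified ratio with delta-method standard error
#'
#' Computes `log2(fr / es)` and its first-order (delta-method) standard
#' error, `se = 1/ln(2) * sqrt((se_fr/fr)^2 + (se_es/es)^2)`, where `fr` and
#' `es` are mean abundances of the tagged (free) and untagged (esterified)
#' populations and `se_fr`, `se_es` their standard errors.
#'
#' @param fr,es Mean abundances (must be > 0); vectorized.
#' @param se_fr,se_es Standard errors (>= 0).
#' @param monomer_id Optional id column carried through.
#' @return A tibble with columns `monomer_id` (if given), `mean_free`,
#'   `se_free`, `mean_esterified`, `se_esterified`, `log2_ratio`, `se_log2`.
#' @examples
#' log_ratio_stats(4, 0.4, 1, 0.1)
#' @export
log_ratio_stats <- function(fr, se_fr, es, se_es, monomer_id = NULL) {
  if (any(fr <= 0) || any(es <= 0)) {
    abort("fr and es must be > 0 (log ratio undefined otherwise)")
  }
  if (any(se_fr < 0) || any(se_es < 0)) abort("standard errors must be >= 0")
  out <- tibble(
    mean_free = fr, se_free = se_fr,
    mean_esterified = es, se_esterified = se_es,
    log2_ratio = log2(fr / es),
    se_log2 = 1 / log(2) * sqrt((se_fr / fr)^2 + (se_es / es)^2)
  )
  if (!is.null(monomer_id)) {
    out <- dplyr::bind_cols(tibble(monomer_id = monomer_id), out)
  }
  out
}

#' Aggregate label observations into per-monomer free/esterified ratios
#'
#' Takes a tidy table of observations from a derivatization experiment and
#' returns, per monomer, the mean and standard error of the tagged (free) and
#' untagged (esterified) abundances across replicates, plus the log2 ratio
#' and its delta-method standard error.
#'
#' @param observations A data frame with columns `monomer_id`, `labeled`
#'   (logical: tag observed on the molecule), `abundance` (>= 0) and
#'   `replicate`.
#' @return A `cutin_label_ratios` tibble (one row per monomer).
#' @export
label_ratios <- function(observations) {
  obs <- as_tibble(observations)
  need <- c("monomer_id", "labeled", "abundance", "replicate")
  missing <- setdiff(need, names(obs))
  if (length(missing)) {
    abort(paste0("observations lack column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(obs$abundance < 0)) abort("abundances must be >= 0")
  per_rep <- obs |>
    dplyr::group_by(.data$monomer_id, .data$replicate, .data$labeled) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop")
  agg <- per_rep |>
    dplyr::group_by(.data$monomer_id, .data$labeled) |>
    dplyr::summarise(
      mean = mean(.data$abundance),
      se = stats::sd(.data$abundance) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(se = dplyr::coalesce(.data$se, 0)) |>
    tidyr::pivot_wider(
      names_from = "labeled", values_from = c("mean", "se", "n"),
      names_glue = "{.value}_{ifelse(labeled, 'free', 'esterified')}"
    )
  for (col in c(
    "mean_free", "se_free", "n_free",
    "mean_esterified", "se_esterified", "n_esterified"
  )) {
    if (!col %in% names(agg)) agg[[col]] <- NA_real_
  }
  ok <- !is.na(agg$mean_free) & !is.na(agg$mean_esterified) &
    agg$mean_free > 0 & agg$mean_esterified > 0
  stats_tbl <- log_ratio_stats(
    fr = agg$mean_free[ok], se_fr = agg$se_free[ok],
    es = agg$mean_esterified[ok], se_es = agg$se_esterified[ok],
    monomer_id = agg$monomer_id[ok]
  )
  out <- dplyr::left_join(
    agg[, c("monomer_id", "mean_free", "se_free", "mean_esterified", "se_esterified")],
    stats_tbl[, c("monomer_id", "log2_ratio", "se_log2")],
    by = "monomer_id"
  )
  class(out) <- c("cutin_label_ratios", class(out))
  out
}

#' Bar plot of per-monomer log2 free/esterified ratios
#'
#' @param object A `cutin_label_ratios` tibble from [label_ratios()].
#' @param ... Unused.
#' @return A ggplot with one bar per monomer and +/- 1 SE error bars.
#' @export
autoplot.cutin_label_ratios <- function(object, ...) {
  dat <- object[!is.na(object$log2_ratio), ]
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$monomer_id, .data$log2_ratio),
    y = .data$log2_ratio
  )) +
    ggplot2::geom_col(fill = "#7570b3") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$log2_ratio - .data$se_log2,
        ymax = .data$log2_ratio + .data$se_log2
      ),
      width = 0.3
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "log2(free / esterified)",
      title = "Free vs esterified groups by monomer"
    ) +
    ggplot2::theme_minimal()
}

#' Quantify an analyte against an internal standard
#'
#' Single-point internal-standard quantification as used for GC-MS monomer
#' profiling against a heptadecanoic-acid spike:
#' `amount = amount_is * area_analyte / area_is`.
#'
#' @param area_analyte Peak area(s) of the analyte.
#' @param area_is Peak area of the internal standard (> 0).
#' @param amount_is Spiked amount of the internal standard (default 10, in
#'   micrograms).
#' @return Amount(s) in the units of `amount_is`.
#' @examples
#' quantify_internal_standard(5e5, 1e6) # 5 ug
#' @export
quantify_internal_standard <- function(area_analyte, area_is, amount_is = 10) {
  if (any(area_is <= 0)) abort("internal-standard area must be > 0")
  if (any(area_analyte < 0)) abort("analyte areas must be >= 0")
  amount_is * area_analyte / area_is
}
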