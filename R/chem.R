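#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Monoisotopic atomic masses (most abundant isotope), frozen at >= 8
# significant digits. Isotope patterns are deliberately out of scope: the
# Q-TOF workflow this package models reads only monoisotopic peaks.
.ATOMIC_MASS <- c(
  H  = 1.00782503,
  C  = 12.0,
  N  = 14.00307401,
  O  = 15.99491462,
  S  = 31.97207100,
  Li = 7.01600455,
  Na = 22.98976928
)

#' Mass of a proton (hydrogen atom) and of water, in Da
#'
#' Convenience constants used throughout fragment arithmetic.
#' @keywords internal
.MASS_H <- .ATOMIC_MASS[["H"]]
.MASS_H2O <- 2 * .ATOMIC_MASS[["H"]] + .ATOMIC_MASS[["O"]]

#' Parse an elemental formula string
#'
#' Formulas use Hill-like element/count notation, e.g. `"C18H32O4"` or
#' `"H2O"`. An empty string is the empty formula. Supported elements are
#' C, H, N, O, S, Li and Na.
#'
#' @param x A single formula string.
#' @return A named integer vector of element counts (possibly empty).
#' @examples
#' parse_formula("C18H32O4")
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- stringr::str_trim(x)
  if (x == "" || x == "0") {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- stringr::str_match_all(x, "([A-Z][a-z]?)(\\d*)")[[1]]
  m <- m[m[, 1] != "", , drop = FALSE]
  if (paste0(m[, 1], collapse = "") != x) {
    abort(paste0("cannot parse formula: '", x, "'"))
  }
  els <- m[, 2]
  bad <- setdiff(els, names(.ATOMIC_MASS))
  if (length(bad) > 0) {
    abort(paste0("unknown element symbol(s): ", paste(bad, collapse = ", ")))
  }
  counts <- ifelse(m[, 3] == "", 1L, suppressWarnings(as.integer(m[, 3])))
  out <- tapply(counts, els, sum)
  counts <- as.integer(out)
  names(counts) <- names(out)
  .formula_canonical(counts)
}

# internal: order elements C, H, then alphabetical (Hill order); drop zeros
.formula_canonical <- function(f) {
  f <- f[f != 0]
  if (length(f) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  rest <- sort(setdiff(names(f), c("C", "H")))
  ord <- c(intersect(c("C", "H"), names(f)), rest)
  stats::setNames(as.integer(f[ord]), ord)
}

.as_formula <- function(f) {
  if (is.character(f)) parse_formula(f) else .formula_canonical(f)
}

# memoised string -> counts parsing (hot path in fragment prediction)
.formula_cache <- new.env(parent = emptyenv())
.parse_formula_cached <- function(x) {
  hit <- .formula_cache[[x]]
  if (is.null(hit)) {
    hit <- parse_formula(x)
    .formula_cache[[x]] <- hit
  }
  hit
}

# fast Hill-order serialization of a full-length named count vector
.formula_string_counts <- function(counts) {
  nz <- counts != 0
  if (!any(nz)) {
    return("")
  }
  els <- names(counts)[nz]
  v <- counts[nz]
  paste0(els, ifelse(v == 1, "", v), collapse = "")
}

#' Serialize an elemental formula to Hill-order text
#'
#' @param f A named integer vector (as from [parse_formula()]) or a string.
#' @return A single string, e.g. `"C18H32O4"`; `""` for the empty formula.
#' @export
formula_string <- function(f) {
  f <- .as_formula(f)
  if (length(f) == 0) {
    return("")
  }
  paste0(names(f), ifelse(f == 1, "", f), collapse = "")
}

#' Add or subtract elemental formulas
#'
#' Element-wise combination of two formulas. Subtraction that would drive any
#' element count negative is an error naming the offending element, so that
#' impossible neutral species are caught at construction time rather than as
#' silently wrong masses.
#'
#' @param a,b Formulas (named integer vectors or strings).
#' @param sign `+1` to add, `-1` to subtract `b` from `a`.
#' @return A named integer vector in Hill order.
#' @examples
#' formula_string(combine_formulas("C16H32O3", "C18H36O5"))
#' formula_string(combine_formulas("C34H68O8", "H2O", sign = -1))
#' @export
combine_formulas <- function(a, b, sign = 1L) {
  stopifnot(sign %in% c(1L, -1L))
  a <- .as_formula(a)
  b <- .as_formula(b)
  els <- union(names(a), names(b))
  av <- stats::setNames(integer(length(els)), els)
  av[names(a)] <- a
  bv <- stats::setNames(integer(length(els)), els)
  bv[names(b)] <- b
  out <- av + sign * bv
  if (any(out < 0)) {
    neg <- names(out)[out < 0]
    abort(paste0(
      "formula subtraction yields negative count for element(s): ",
      paste(neg, collapse = ", ")
    ))
  }
  .formula_canonical(out)
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum of count times the standard monoisotopic atomic mass for each element.
#' The empty formula has mass 0.
#'
#' @param f A formula (named integer vector, string, or character vector of
#'   strings, in which case the result is vectorized).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")      # 18.010565
#' monoisotopic_mass("C18H30O3") # 294.219495
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f) && length(f) > 1) {
    return(vapply(f, monoisotopic_mass, numeric(1), USE.NAMES = FALSE))
  }
  f <- .as_formula(f)
  if (length(f) == 0) {
    return(0)
  }
  sum(.ATOMIC_MASS[names(f)] * f)
}

# Built-in adduct table. Negative-mode work in this package assumes singly
# charged [M-H]- species; the lithium adducts cover MALDI with Li-doped DHB.
.ADDUCTS <- list(
  "[M-H]-"     = list(name = "[M-H]-", delta = c(H = -1L), charge = -1L),
  "[M+H]+"     = list(name = "[M+H]+", delta = c(H = 1L), charge = 1L),
  "[M+Li]+"    = list(name = "[M+Li]+", delta = c(Li = 1L), charge = 1L),
  "[M+2Li-H]+" = list(name = "[M+2Li-H]+", delta = c(Li = 2L, H = -1L), charge = 1L)
)

#' Ionization adduct specifications
#'
#' `adducts()` lists the built-in adducts; `adduct_spec()` retrieves one by its
#' exact name (`"[M-H]-"`, `"[M+H]+"`, `"[M+Li]+"`, `"[M+2Li-H]+"`) or passes a
#' user-supplied spec through after validation.
#'
#' @param x An adduct name, or a list with fields `name`, `delta` (signed
#'   element count changes relative to the neutral molecule) and `charge`
#'   (non-zero integer).
#' @return `adducts()`: a tibble with columns `name`, `delta`, `charge`.
#'   `adduct_spec()`: a list with fields `name`, `delta`, `charge`.
#' @export
adducts <- function() {
  tibble(
    name = unname(vapply(.ADDUCTS, `[[`, character(1), "name")),
    delta = unname(vapply(.ADDUCTS, function(a) {
      paste0(
        ifelse(a$delta > 0, "+", "-"),
        ifelse(abs(a$delta) == 1, "", abs(a$delta)), names(a$delta),
        collapse = ""
      )
    }, character(1))),
    charge = unname(vapply(.ADDUCTS, `[[`, integer(1), "charge"))
  )
}

#' @rdname adducts
#' @export
adduct_spec <- function(x) {
  if (is.list(x) && all(c("name", "delta", "charge") %in% names(x))) {
    if (x$charge == 0) abort("adduct charge must be non-zero")
    return(x)
  }
  stopifnot(is.character(x), length(x) == 1L)
  if (!x %in% names(.ADDUCTS)) {
    abort(paste0(
      "unknown adduct '", x, "'; built-ins are: ",
      paste(names(.ADDUCTS), collapse = ", ")
    ))
  }
  .ADDUCTS[[x]]
}

#' m/z of an ionized neutral species
#'
#' Applies an adduct's formula change to a neutral elemental formula and
#' divides by the absolute charge. All arithmetic in this package is performed
#' on neutral formulas; charged species only ever arise through this function.
#' That convention reproduces the printed oligomer ions exactly, whereas
#' summing deprotonated monomer m/z values double-counts lost protons.
#'
#' @param neutral Neutral formula (named vector or string).
#' @param adduct Adduct name or spec (default `"[M-H]-"`).
#' @return m/z at full double precision; round with [round_mz()] for
#'   comparison with printed values.
#' @examples
#' round_mz(ion_mz("C18H30O3", "[M-H]-")) # 293.21
#' @export
ion_mz <- function(neutral, adduct = "[M-H]-") {
  if (is.character(neutral) && length(neutral) > 1) {
    return(vapply(neutral, ion_mz, numeric(1), adduct = adduct, USE.NAMES = FALSE))
  }
  ad <- adduct_spec(adduct)
  f <- combine_formulas(.as_formula(neutral), ad$delta, sign = 1L)
  monoisotopic_mass(f) / abs(ad$charge)
}

#' Round m/z half-away-from-zero
#'
#' Printed m/z values in instrument reports use arithmetic rounding, not
#' banker's rounding, so `round_mz(287.225) == 287.23`.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2, the printed precision).
#' @export
round_mz <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Match an observed m/z against a theoretical value
#'
#' A match passes when EITHER the ppm or the Da tolerance is satisfied (when
#' both are provided); supplying only one applies only that one. Defaults are
#' 10 ppm or 0.02 Da, reflecting the deviation of printed Q-TOF values from
#' theory.
#'
#' @param observed,theoretical m/z values (vectorized, recycled).
#' @param tol_ppm Tolerance in parts-per-million, or `NULL` to skip.
#' @param tol_da Tolerance in Da, or `NULL` to skip.
#' @return A tibble with columns `observed`, `theoretical`, `error_da`,
#'   `error_ppm`, `within_tolerance`.
#' @examples
#' mass_match(585.47, 585.4730)
#' @export
mass_match <- function(observed, theoretical, tol_ppm = 10, tol_da = 0.02) {
  if (any(theoretical <= 0)) abort("theoretical m/z must be > 0")
  if (is.null(tol_ppm) && is.null(tol_da)) {
    abort("at least one of tol_ppm, tol_da must be given")
  }
  if (!is.null(tol_ppm) && any(tol_ppm < 0)) abort("tol_ppm must be >= 0")
  if (!is.null(tol_da) && any(tol_da < 0)) abort("tol_da must be >= 0")
  error_da <- observed - theoretical
  error_ppm <- error_da / theoretical * 1e6
  ok <- rep(FALSE, length(error_da))
  if (!is.null(tol_ppm)) ok <- ok | abs(error_ppm) <= tol_ppm
  if (!is.null(tol_da)) ok <- ok | abs(error_da) <= tol_da
  tibble(
    observed = observed, theoretical = theoretical,
    error_da = error_da, error_ppm = error_ppm,
    within_tolerance = ok
  )
}

# Built-in derivatization chemistries. Deltas are reagent-minus-leaving-group:
# dansyl chloride on a hydroxyl adds the dansyl group (+C12H11NO2S), the
# benzyloxypyridinium reagent benzylates a hydroxyl (+C7H6), and DmPA bromide
# esterifies a free carboxyl (+C10H11NO).
.TAGS <- list(
  dansyl = list(name = "dansyl", site_class = "hydroxyl", delta = c(C = 12L, H = 11L, N = 1L, O = 2L, S = 1L)),
  benzyl = list(name = "benzyl", site_class = "hydroxyl", delta = c(C = 7L, H = 6L)),
  DmPA   = list(name = "DmPA", site_class = "carboxyl", delta = c(C = 10L, H = 11L, N = 1L, O = 1L))
)

#' Derivatization tag specifications
#'
#' Built-in chemistries for labeling non-esterified groups in the intact
#' polymer: `dansyl` (hydroxyl, +C12H11NO2S), `benzyl` (hydroxyl, +C7H6) and
#' `DmPA` (carboxyl, +C10H11NO). A monomer recovered *with* the tag had the
#' labeled group free in the intact polymer; recovered *without* it, the group
#' was esterified.
#'
#' @param x A tag name, or a list with fields `name`, `site_class`
#'   (`"hydroxyl"` or `"carboxyl"`) and `delta`.
#' @return `derivatization_tags()`: a tibble; `derivatization_tag()`: a list
#'   spec.
#' @export
derivatization_tags <- function() {
  tibble(
    name = unname(vapply(.TAGS, `[[`, character(1), "name")),
    site_class = unname(vapply(.TAGS, `[[`, character(1), "site_class")),
    delta = unname(vapply(.TAGS, function(t) formula_string(t$delta), character(1))),
    delta_mass = unname(vapply(.TAGS, function(t) monoisotopic_mass(t$delta), numeric(1)))
  )
}

#' @rdname derivatization_tags
#' @export
derivatization_tag <- function(x) {
  if (is.list(x) && all(c("name", "site_class", "delta") %in% names(x))) {
    stopifnot(x$site_class %in% c("hydroxyl", "carboxyl"))
    return(x)
  }
  stopifnot(is.character(x), length(x) == 1L)
  if (!x %in% names(.TAGS)) {
    abort(paste0(
      "unknown derivatization tag '", x, "'; built-ins are: ",
      paste(names(.TAGS), collapse = ", ")
    ))
  }
  .TAGS[[x]]
}
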