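# Cutin monomers are described positionally: chain length n, number of double
# bonds d, hydroxyl positions (1-based from the carboxyl carbon; omega == n),
# epoxy spans (stored as the lower carbon of each adjacent pair), and carboxyl
# positions (always containing 1 for acids; also n for diacids). Fatty
# alcohols (no carboxyl) are carried for completeness but take no part in
# oligomers unless explicitly enabled.

.monomer_formula_counts <- function(n, d, oh, epoxy, carboxyls, alcohol) {
  noh <- length(oh)
  ne <- length(epoxy)
  nc <- length(carboxyls)
  if (alcohol) {
    c(C = n, H = 2L * n + 2L - 2L * d - 2L * ne, O = noh + ne)
  } else {
    c(
      C = n,
      H = 2L * n - 2L * d - 2L * ne - 2L * (nc - 1L),
      O = 2L * nc + noh + ne
    )
  }
}

#' Construct a cutin monomer record
#'
#' @param n Chain length in carbons.
#' @param d Number of C=C double bonds.
#' @param oh Integer vector of hydroxyl positions (1-based from the carboxyl
#'   carbon; the omega carbon is position `n`).
#' @param epoxy Integer vector of epoxide spans, giving the lower carbon of
#'   each adjacent pair (`9` means the 9,10-epoxide).
#' @param carboxyls Carboxyl positions; `1` for ordinary fatty acids,
#'   `c(1, n)` for diacids, `integer(0)` together with `alcohol = TRUE` for
#'   fatty alcohols.
#' @param alcohol Is this a fatty alcohol (no carboxyl)?
#' @param id Canonical shorthand id; derived with [render_shorthand()] when
#'   `NULL`.
#' @param sim_weight Relative sampling weight used by the polymer simulator.
#' @return A one-row tibble with list-columns `oh`, `epoxy`, `carboxyls` plus
#'   derived `formula`, `mass` (neutral monoisotopic) and `mz` (`[M-H]-`).
#' @examples
#' monomer(16, 0, oh = c(10, 16))
#' @export
monomer <- function(n, d = 0L, oh = integer(0), epoxy = integer(0),
                    carboxyls = 1L, alcohol = FALSE, id = NULL,
                    sim_weight = 1) {
  n <- as.integer(n)
  d <- as.integer(d)
  oh <- sort(as.integer(oh))
  epoxy <- sort(as.integer(epoxy))
  carboxyls <- sort(as.integer(carboxyls))
  if (alcohol) carboxyls <- integer(0)
  if (n < 2) abort("chain length n must be >= 2")
  if (d < 0) abort("double-bond count must be >= 0")
  low <- if (alcohol) 1L else 2L
  if (length(oh) && (any(oh < low) | any(oh > n))) {
    abort(sprintf("hydroxyl positions must lie in [%d, %d]", low, n))
  }
  if (length(epoxy) && (any(epoxy < 2L) | any(epoxy > n - 1L))) {
    abort("epoxy span lower carbons must lie in [2, n-1]")
  }
  if (!alcohol) {
    if (!1L %in% carboxyls) abort("acids must carry a carboxyl at position 1")
    if (!all(carboxyls %in% c(1L, n))) {
      abort("carboxyl positions are restricted to carbons 1 and n")
    }
  }
  epoxy_carbons <- unique(c(epoxy, epoxy + 1L))
  overlap <- c(
    intersect(oh, epoxy_carbons),
    intersect(oh, carboxyls),
    intersect(epoxy_carbons, carboxyls)
  )
  if (length(overlap)) {
    abort(paste0(
      "hydroxyl, epoxy and carboxyl positions must be disjoint; clash at carbon(s) ",
      paste(unique(overlap), collapse = ", ")
    ))
  }
  counts <- .monomer_formula_counts(n, d, oh, epoxy, carboxyls, alcohol)
  if (counts[["H"]] <= 0) abort("descriptors imply a non-positive hydrogen count")
  f <- formula_string(counts)
  out <- tibble(
    id = NA_character_, n = n, d = d,
    oh = list(oh), epoxy = list(epoxy), carboxyls = list(carboxyls),
    alcohol = alcohol,
    formula = f,
    mass = monoisotopic_mass(f),
    mz = if (alcohol) NA_real_ else ion_mz(f, "[M-H]-"),
    sim_weight = sim_weight
  )
  out$id <- id %||% render_shorthand(out)
  out
}

#' Elemental formula implied by monomer descriptors
#'
#' For acids: `C_n H_(2n - 2d - 2*n_epoxy - 2*(n_carboxyl - 1))
#' O_(2*n_carboxyl + n_OH + n_epoxy)`; for fatty alcohols:
#' `C_n H_(2n + 2 - 2d - 2*n_epoxy) O_(n_OH + n_epoxy)`.
#'
#' @param m A one-row monomer tibble (from [monomer()], [parse_shorthand()] or
#'   a catalog row).
#' @return A named integer vector of element counts.
#' @export
monomer_formula <- function(m) {
  stopifnot(nrow(m) == 1L)
  .formula_canonical(.monomer_formula_counts(
    m$n, m$d, m$oh[[1]], m$epoxy[[1]], m$carboxyls[[1]], m$alcohol
  ))
}

#' Render the canonical shorthand name of a monomer
#'
#' The canonical grammar is compact: `"16:0"`, `"16-OH-16:0"`,
#' `"10,16-diOH-16:0"`, `"18-OH-9,10-epoxy-18:1"`, diacids take a `-DCA`
#' suffix (`"9,10-diOH-18:0-DCA"`) and 1-alcohols an `-ol` suffix
#' (`"26:0-ol"`).
#'
#' @param m A one-row monomer tibble.
#' @return A single string; `render_shorthand(parse_shorthand(s)) == s` for
#'   canonical `s`.
#' @export
render_shorthand <- function(m) {
  stopifnot(nrow(m) == 1L)
  oh <- m$oh[[1]]
  epoxy <- m$epoxy[[1]]
  base <- paste0(m$n, ":", m$d)
  if (m$alcohol) {
    # canonical alcohols are 1-ols; other hydroxyls render positionally
    extra <- setdiff(oh, 1L)
    pre <- if (length(extra)) .oh_segment(extra) else ""
    return(paste0(pre, base, "-ol"))
  }
  seg <- character(0)
  if (length(oh)) seg <- c(seg, .oh_segment(oh))
  if (length(epoxy)) {
    seg <- c(seg, vapply(
      epoxy, function(p) paste0(p, ",", p + 1L, "-epoxy-"), character(1)
    ))
  }
  suffix <- if (length(m$carboxyls[[1]]) == 2L) "-DCA" else ""
  paste0(paste0(seg, collapse = ""), base, suffix)
}

.oh_segment <- function(oh) {
  prefix <- switch(min(length(oh), 4L), "OH", "diOH", "triOH", "tetraOH")
  paste0(paste(oh, collapse = ","), "-", prefix, "-")
}

#' Parse monomer shorthand text
#'
#' Accepts the canonical compact grammar (see [render_shorthand()]) as well as
#' the spelled-out chemical prefixes, e.g. `"9,10,18-trihydroxy-18:0"` or
#' `"18-hydroxy-9,10-epoxy-18:1"`.
#'
#' @param text A single shorthand string.
#' @return A one-row monomer tibble.
#' @examples
#' parse_shorthand("9,10,18-trihydroxy-18:0")$formula
#' @export
parse_shorthand <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- stringr::str_trim(text)
  alcohol <- FALSE
  diacid <- FALSE
  if (stringr::str_ends(s, "-ol")) {
    alcohol <- TRUE
    s <- stringr::str_sub(s, 1L, -4L)
  } else if (stringr::str_ends(s, "-DCA")) {
    diacid <- TRUE
    s <- stringr::str_sub(s, 1L, -5L)
  }
  m <- stringr::str_match(s, "^(.*?)(\\d+):(\\d+)$")
  if (is.na(m[1, 1])) abort(paste0("cannot parse monomer shorthand: '", text, "'"))
  n <- as.integer(m[1, 3])
  d <- as.integer(m[1, 4])
  rest <- m[1, 2]
  oh <- integer(0)
  epoxy <- integer(0)
  if (rest != "") {
    seg_re <- "^(\\d+(?:,\\d+)*)-(OH|diOH|triOH|tetraOH|hydroxy|dihydroxy|trihydroxy|tetrahydroxy|epoxy)-"
    while (rest != "") {
      sm <- stringr::str_match(rest, seg_re)
      if (is.na(sm[1, 1])) {
        abort(paste0("cannot parse monomer shorthand: '", text, "'"))
      }
      pos <- as.integer(stringr::str_split_1(sm[1, 2], ","))
      kind <- sm[1, 3]
      if (kind == "epoxy") {
        if (length(pos) %% 2 != 0 || any(pos[seq(2, length(pos), 2)] != pos[seq(1, length(pos), 2)] + 1L)) {
          abort("epoxy positions must be adjacent pairs, e.g. 9,10-epoxy")
        }
        epoxy <- c(epoxy, pos[seq(1, length(pos), 2)])
      } else {
        want <- c(
          OH = 1L, diOH = 2L, triOH = 3L, tetraOH = 4L,
          hydroxy = 1L, dihydroxy = 2L, trihydroxy = 3L, tetrahydroxy = 4L
        )[[kind]]
        if (length(pos) != want) {
          abort(paste0("'", kind, "' requires ", want, " position(s) in '", text, "'"))
        }
        oh <- c(oh, pos)
      }
      rest <- stringr::str_remove(rest, seg_re)
    }
  }
  if (any(oh > n) || any(epoxy + 1L > n)) {
    abort(paste0("substituent position exceeds chain length in '", text, "'"))
  }
  if (alcohol && !1L %in% oh) oh <- c(1L, oh)
  monomer(
    n = n, d = d, oh = oh, epoxy = epoxy,
    carboxyls = if (alcohol) integer(0) else if (diacid) c(1L, n) else 1L,
    alcohol = alcohol
  )
}

# ---------------------------------------------------------------------------
# Built-in apple cutin catalog: the C16/C18 hydroxy-, epoxy- and
# polyhydroxy-acids identified in apple fruit cutin, plus the extended list of
# diacids, 2-hydroxy acids, very-long-chain acids and fatty alcohols.
# sim_weight encodes the qualitative abundance ranking: the six dominant
# monomers (together roughly 80% of the monomer pool) carry most weight;
# alcohols default to 0 so they never enter simulated polymers unless enabled.
.CATALOG_DEF <- list(
  # six most abundant monomers
  list("9,10,18-triOH-18:0", 18, 0, c(9, 10, 18), NULL, 1, FALSE, 8),
  list("10,16-diOH-16:0", 16, 0, c(10, 16), NULL, 1, FALSE, 8),
  list("9,10,18-triOH-18:3", 18, 3, c(9, 10, 18), NULL, 1, FALSE, 8),
  list("9,10,18-triOH-18:2", 18, 2, c(9, 10, 18), NULL, 1, FALSE, 8),
  list("18-OH-18:2", 18, 2, 18, NULL, 1, FALSE, 8),
  list("9,10,18-triOH-18:1", 18, 1, c(9, 10, 18), NULL, 1, FALSE, 8),
  # remaining C16/C18 oxygenated acids
  list("16-OH-16:0", 16, 0, 16, NULL, 1, FALSE, 2),
  list("10,16-diOH-16:1", 16, 1, c(10, 16), NULL, 1, FALSE, 1),
  list("18-OH-18:1", 18, 1, 18, NULL, 1, FALSE, 1),
  list("18-OH-18:3", 18, 3, 18, NULL, 1, FALSE, 2),
  list("18-OH-9,10-epoxy-18:0", 18, 0, 18, 9, 1, FALSE, 2),
  list("18-OH-9,10-epoxy-18:1", 18, 1, 18, 9, 1, FALSE, 2),
  list("18-OH-9,10-epoxy-18:2", 18, 2, 18, 9, 1, FALSE, 1),
  list("2-OH-16:0", 16, 0, 2, NULL, 1, FALSE, 0.5),
  # unsubstituted acids
  list("16:0", 16, 0, NULL, NULL, 1, FALSE, 1),
  list("18:0", 18, 0, NULL, NULL, 1, FALSE, 0.5),
  list("18:1", 18, 1, NULL, NULL, 1, FALSE, 0.5),
  list("18:2", 18, 2, NULL, NULL, 1, FALSE, 0.5),
  # diacids
  list("16:0-DCA", 16, 0, NULL, NULL, c(1, 16), FALSE, 0.25),
  list("9,10-diOH-18:0-DCA", 18, 0, c(9, 10), NULL, c(1, 18), FALSE, 0.25),
  # very-long-chain acids
  list("20:0", 20, 0, NULL, NULL, 1, FALSE, 0.25),
  list("20:3", 20, 3, NULL, NULL, 1, FALSE, 0.25),
  list("2-OH-22:0", 22, 0, 2, NULL, 1, FALSE, 0.25),
  list("2-OH-24:0", 24, 0, 2, NULL, 1, FALSE, 0.25),
  list("30:0", 30, 0, NULL, NULL, 1, FALSE, 0.25),
  # fatty alcohols (never sampled into polymers by default)
  list("26:0-ol", 26, 0, 1, NULL, NULL, TRUE, 0),
  list("28:0-ol", 28, 0, 1, NULL, NULL, TRUE, 0),
  list("30:0-ol", 30, 0, 1, NULL, NULL, TRUE, 0)
)

#' The built-in apple cutin monomer catalog
#'
#' Hydroxy-, epoxy- and polyhydroxy C16/C18 fatty acids identified in apple
#' fruit cutin, together with an extended list of diacids, 2-hydroxy acids,
#' very-long-chain acids and fatty alcohols. Every entry's formula is derived
#' from its positional descriptors, never stored.
#'
#' @return A catalog tibble (one monomer per row) with columns `id`, `n`, `d`,
#'   list-columns `oh`, `epoxy`, `carboxyls`, plus `alcohol`, `formula`,
#'   `mass`, `mz` (`[M-H]-`) and `sim_weight`.
#' @examples
#' default_catalog()
#' @export
default_catalog <- function() {
  rows <- purrr::map(.CATALOG_DEF, function(e) {
    monomer(
      n = e[[2]], d = e[[3]], oh = e[[4]] %||% integer(0),
      epoxy = e[[5]] %||% integer(0),
      carboxyls = e[[6]] %||% integer(0), alcohol = e[[7]],
      id = e[[1]], sim_weight = e[[8]]
    )
  })
  out <- dplyr::bind_rows(rows)
  stopifnot(!anyDuplicated(out$id))
  class(out) <- c("cutin_catalog", class(out))
  out
}

#' Look up catalog monomers by observed m/z or neutral mass
#'
#' Isobaric species (identical elemental formula, e.g. an omega-hydroxy epoxy
#' acid and a dihydroxy unsaturated acid of the same chain length) are never
#' merged: all matches are returned, with `isobar = TRUE` whenever more than
#' one catalog entry matches.
#'
#' @param catalog A catalog tibble.
#' @param mz Observed m/z (mutually exclusive with `mass`).
#' @param mass Neutral monoisotopic mass.
#' @param adduct Adduct assumed when matching `mz` (default `"[M-H]-"`).
#' @param tol_da Absolute tolerance in Da (default 0.01).
#' @return The matching catalog rows with `error_da` and `isobar` columns,
#'   sorted by absolute error.
#' @export
catalog_lookup <- function(catalog, mz = NULL, mass = NULL,
                           adduct = "[M-H]-", tol_da = 0.01) {
  if (is.null(mz) == is.null(mass)) {
    abort("give exactly one of mz or mass")
  }
  if (!is.null(mz)) {
    ad <- adduct_spec(adduct)
    target <- mz * abs(ad$charge) - monoisotopic_mass(.formula_canonical(ad$delta))
  } else {
    target <- mass
  }
  hits <- dplyr::filter(catalog, abs(.data$mass - target) <= tol_da)
  hits <- dplyr::mutate(hits,
    error_da = .data$mass - target,
    isobar = dplyr::n() > 1L
  )
  dplyr::arrange(hits, abs(.data$error_da))
}

#' Read and write monomer catalogs as TSV
#'
#' The TSV schema has columns `id`, `n`, `d`, `oh_positions` (comma-separated,
#' may be empty), `epoxy_spans` (comma-separated lower carbons of each
#' adjacent pair), `carboxyls` (comma-separated), `alcohol` (TRUE/FALSE) and
#' optional `sim_weight`. Formulas and masses are always rederived on read.
#'
#' @param path File path.
#' @param catalog A catalog tibble (for writing).
#' @return `read_catalog()`: a catalog tibble; `write_catalog()`: `path`,
#'   invisibly.
#' @export
read_catalog <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), n = readr::col_integer(),
    d = readr::col_integer(), oh_positions = readr::col_character(),
    epoxy_spans = readr::col_character(), carboxyls = readr::col_character(),
    alcohol = readr::col_logical(), .default = readr::col_double()
  ))
  parse_pos <- function(x) {
    if (is.na(x) || x == "") integer(0) else as.integer(stringr::str_split_1(x, ","))
  }
  rows <- purrr::pmap(raw, function(id, n, d, oh_positions, epoxy_spans,
                                    carboxyls, alcohol, ...) {
    extra <- list(...)
    monomer(
      n = n, d = d, oh = parse_pos(oh_positions),
      epoxy = parse_pos(epoxy_spans), carboxyls = parse_pos(carboxyls),
      alcohol = alcohol, id = id,
      sim_weight = extra$sim_weight %||% 1
    )
  })
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$id)) abort("catalog ids must be unique")
  class(out) <- c("cutin_catalog", class(out))
  out
}

#' @rdname read_catalog
#' @export
write_catalog <- function(catalog, path) {
  fmt <- function(col) vapply(col, paste, character(1), collapse = ",")
  flat <- tibble(
    id = catalog$id, n = catalog$n, d = catalog$d,
    oh_positions = fmt(catalog$oh),
    epoxy_spans = fmt(catalog$epoxy),
    carboxyls = fmt(catalog$carboxyls),
    alcohol = catalog$alcohol,
    sim_weight = catalog$sim_weight
  )
  readr::write_tsv(flat, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Symbolic nomenclature: a one-line ASCII rendering of the pac-man style
# schematic used for cutin moieties. Monomer:
#   [<n>:<d>|COOH@1{,n}|OH@p1,p2,...|EP@p-q]
# with empty fields omitted. Oligomers join monomers left-to-right from the
# free-carboxyl terminus with "<=(pos)=", pos being the esterified hydroxyl
# position on the left-hand monomer.

.render_symbolic_monomer <- function(m) {
  fields <- paste0(m$n, ":", m$d)
  cb <- m$carboxyls[[1]]
  if (length(cb)) fields <- c(fields, paste0("COOH@", paste(cb, collapse = ",")))
  oh <- m$oh[[1]]
  if (length(oh)) fields <- c(fields, paste0("OH@", paste(oh, collapse = ",")))
  ep <- m$epoxy[[1]]
  if (length(ep)) {
    fields <- c(fields, paste0(
      "EP@",
      paste(vapply(ep, function(p) paste0(p, "-", p + 1L), character(1)),
        collapse = ","
      )
    ))
  }
  paste0("[", paste(fields, collapse = "|"), "]")
}

#' Render the symbolic one-line nomenclature
#'
#' @param x A one-row monomer tibble, a catalog subset (rendered row-wise), or
#'   a `cutin_oligomer`.
#' @return Character vector of symbolic renderings, e.g.
#'   `"[16:0|COOH@1|OH@10,16]"` or
#'   `"[16:0|COOH@1|OH@16] <=(16)= [18:0|COOH@1|OH@9,10,18]"`.
#' @export
render_symbolic <- function(x) {
  if (inherits(x, "cutin_oligomer")) {
    mono <- vapply(
      seq_len(nrow(x$monomers)),
      function(i) .render_symbolic_monomer(x$monomers[i, ]), character(1)
    )
    if (length(mono) == 1L) {
      return(mono)
    }
    joins <- paste0(" <=(", x$linkage_sites, ")= ")
    return(paste0(mono[1], paste0(joins, mono[-1], collapse = "")))
  }
  stopifnot(is.data.frame(x))
  vapply(seq_len(nrow(x)), function(i) .render_symbolic_monomer(x[i, ]), character(1))
}

#' Parse the symbolic nomenclature back into monomers or an oligomer
#'
#' Inverse of [render_symbolic()]: a single bracketed term yields a one-row
#' monomer tibble; joined terms yield a `cutin_oligomer`.
#'
#' @param text A single symbolic string.
#' @return A monomer tibble or a `cutin_oligomer`.
#' @export
parse_symbolic <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- stringr::str_match_all(
    text, "\\[([^\\]]+)\\]|<=\\((\\d+)\\)="
  )[[1]]
  terms <- parts[!is.na(parts[, 2]), 2]
  sites <- as.integer(parts[!is.na(parts[, 3]), 3])
  if (length(terms) == 0L || length(sites) != length(terms) - 1L) {
    abort(paste0("cannot parse symbolic nomenclature: '", text, "'"))
  }
  mono <- dplyr::bind_rows(purrr::map(terms, .parse_symbolic_monomer))
  if (nrow(mono) == 1L) {
    return(mono)
  }
  oligomer(mono, linkage_sites = sites)
}

.parse_symbolic_monomer <- function(term) {
  fields <- stringr::str_split_1(term, stringr::fixed("|"))
  nd <- stringr::str_match(fields[1], "^(\\d+):(\\d+)$")
  if (is.na(nd[1, 1])) abort(paste0("bad symbolic monomer term: '", term, "'"))
  n <- as.integer(nd[1, 2])
  d <- as.integer(nd[1, 3])
  oh <- integer(0)
  epoxy <- integer(0)
  carboxyls <- integer(0)
  for (f in fields[-1]) {
    kv <- stringr::str_match(f, "^(COOH|OH|EP)@(.+)$")
    if (is.na(kv[1, 1])) abort(paste0("bad symbolic field: '", f, "'"))
    vals <- stringr::str_split_1(kv[1, 3], ",")
    if (kv[1, 2] == "COOH") {
      carboxyls <- as.integer(vals)
    } else if (kv[1, 2] == "OH") {
      oh <- as.integer(vals)
    } else {
      lo <- as.integer(stringr::str_extract(vals, "^\\d+"))
      hi <- as.integer(stringr::str_extract(vals, "\\d+$"))
      if (any(hi != lo + 1L)) abort("EP spans must be adjacent pairs p-(p+1)")
      epoxy <- lo
    }
  }
  monomer(
    n = n, d = d, oh = oh, epoxy = epoxy, carboxyls = carboxyls,
    alcohol = length(carboxyls) == 0L
  )
}
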