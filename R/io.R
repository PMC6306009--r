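# File formats and report generation. MGF (Mascot Generic Format) is the
# spectrum interchange: universally writable, plain text, one BEGIN
# IONS/END IONS block per spectrum with PEPMASS and optional CHARGE/TITLE
# headers followed by "mz intensity" peak rows.

# 32-bit FNV-1a over UTF-8 bytes, in double arithmetic (kept exact by
# splitting the multiply into 16-bit halves); used to fingerprint catalogs in
# reports so a result can be traced to the library that produced it.
.fnv1a <- function(text) {
  bytes <- as.integer(charToRaw(paste(text, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- ((h1 * p) %% 65536) * 65536 + h0 * p
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Checksum of a monomer catalog
#'
#' A 32-bit FNV-1a fingerprint of the catalog's ids, descriptors and masses,
#' embedded in every report for provenance.
#'
#' @param catalog A catalog tibble.
#' @return An 8-character hex string.
#' @export
catalog_checksum <- function(catalog) {
  flat <- vapply(seq_len(nrow(catalog)), function(i) {
    paste(
      catalog$id[i], catalog$n[i], catalog$d[i],
      paste(catalog$oh[[i]], collapse = ","),
      paste(catalog$epoxy[[i]], collapse = ","),
      paste(catalog$carboxyls[[i]], collapse = ","),
      catalog$alcohol[i], sprintf("%.6f", catalog$mass[i]),
      sep = "|"
    )
  }, character(1))
  .fnv1a(flat)
}

#' Read centroided spectra from an MGF file
#'
#' Parses BEGIN IONS/END IONS blocks; `PEPMASS` is required per block (the
#' first number is taken), `CHARGE` selects the assumed adduct (`1-` gives
#' `[M-H]-`, otherwise `[M+H]+`; absent defaults to `default_adduct`), and
#' `TITLE` becomes the spectrum's `source_id`. Malformed blocks are skipped
#' with a warning naming the offending line.
#'
#' @param path MGF file path.
#' @param default_adduct Adduct assumed when a block carries no CHARGE.
#' @return A list of `ms2_spectrum` objects (possibly empty).
#' @export
read_mgf <- function(path, default_adduct = "[M-H]-") {
  if (!file.exists(path)) abort(paste0("MGF file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) {
    warn(paste0("empty MGF file: ", path))
    return(list())
  }
  spectra <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (stringr::str_trim(lines[i]) != "BEGIN IONS") {
      i <- i + 1L
      next
    }
    start <- i
    i <- i + 1L
    pepmass <- NA_real_
    charge <- NA_character_
    title <- ""
    mzs <- numeric(0)
    ints <- numeric(0)
    bad <- NA_integer_
    while (i <= length(lines) && stringr::str_trim(lines[i]) != "END IONS") {
      ln <- stringr::str_trim(lines[i])
      if (ln == "") {
        i <- i + 1L
        next
      }
      if (stringr::str_detect(ln, "^[A-Z]+=")) {
        key <- stringr::str_extract(ln, "^[A-Z]+")
        val <- stringr::str_remove(ln, "^[A-Z]+=")
        if (key == "PEPMASS") {
          pepmass <- suppressWarnings(as.numeric(stringr::str_split_1(val, "\\s+")[1]))
        } else if (key == "CHARGE") {
          charge <- val
        } else if (key == "TITLE") {
          title <- val
        }
      } else {
        fields <- suppressWarnings(as.numeric(stringr::str_split_1(ln, "[\\s,]+")))
        if (length(fields) < 1L || anyNA(fields)) {
          if (is.na(bad)) bad <- i
        } else {
          mzs <- c(mzs, fields[1])
          ints <- c(ints, if (length(fields) >= 2L) fields[2] else 0)
        }
      }
      i <- i + 1L
    }
    i <- i + 1L # consume END IONS
    if (!is.na(bad)) {
      warn(sprintf("skipping MGF block at line %d: non-numeric peak row at line %d", start, bad))
      next
    }
    if (is.na(pepmass)) {
      warn(sprintf("skipping MGF block at line %d: missing or non-numeric PEPMASS", start))
      next
    }
    adduct <- if (!is.na(charge) && stringr::str_detect(charge, "-")) {
      "[M-H]-"
    } else if (!is.na(charge)) {
      "[M+H]+"
    } else {
      default_adduct
    }
    spectra[[length(spectra) + 1L]] <- spectrum(
      precursor_mz = pepmass,
      peaks = tibble(mz = mzs, intensity = ints),
      adduct = adduct,
      source_id = title
    )
  }
  spectra
}

#' Write spectra to an MGF file
#'
#' @param spectra A single `ms2_spectrum` or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "ms2_spectrum")) spectra <- list(spectra)
  blocks <- purrr::map_chr(spectra, function(s) {
    charge <- if (s$adduct == "[M-H]-") "1-" else "1+"
    paste(
      c(
        "BEGIN IONS",
        if (nzchar(s$source_id)) paste0("TITLE=", s$source_id) else NULL,
        sprintf("PEPMASS=%.6f", s$precursor_mz),
        paste0("CHARGE=", charge),
        sprintf("%.6f %.6g", s$peaks$mz, s$peaks$intensity),
        "END IONS"
      ),
      collapse = "\n"
    )
  })
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' Write an analysis report
#'
#' Serializes a sequencing result or a label-ratio table with deterministic
#' field order. JSON reports embed the full run configuration and catalog
#' checksum; CSV reports echo them as columns so that a re-parsed CSV
#' reproduces the ranking.
#'
#' @param result A `cutin_sequencing` object or a `cutin_label_ratios`
#'   tibble.
#' @param path Output path.
#' @param format `"json"` or `"csv"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = NULL) {
  format <- format %||% (if (stringr::str_ends(path, "\\.json")) "json" else "csv")
  if (!format %in% c("json", "csv")) abort("format must be 'json' or 'csv'")
  if (inherits(result, "cutin_sequencing")) {
    if (format == "json") {
      payload <- list(
        config = result$params,
        spectrum = list(
          precursor_mz = result$spectrum$precursor_mz,
          adduct = result$spectrum$adduct,
          n_peaks = nrow(result$spectrum$peaks),
          source_id = result$spectrum$source_id
        ),
        ambiguity = result$ambiguity,
        diagnostic = result$diagnostic,
        ranking = result$ranking,
        central_evidence = result$central_evidence
      )
      jsonlite::write_json(payload, path,
        auto_unbox = TRUE, digits = NA, null = "null", na = "null", pretty = TRUE
      )
    } else {
      flat <- result$ranking
      flat$precursor_mz <- result$spectrum$precursor_mz
      flat$adduct <- result$spectrum$adduct
      flat$catalog_checksum <- result$params$catalog_checksum
      flat$tol_da <- result$params$tol_da
      readr::write_csv(flat, path)
    }
  } else if (is.data.frame(result)) {
    if (format == "json") {
      jsonlite::write_json(as.data.frame(result), path,
        auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
      )
    } else {
      readr::write_csv(result, path)
    }
  } else {
    abort("unsupported result type for write_report")
  }
  invisible(path)
}

# run configuration: validated defaults, optionally overlaid from a YAML file
.default_config <- function() {
  list(
    adduct = "[M-H]-", tol_da = 0.02, tol_ppm = 10,
    min_len = NULL, max_len = NULL, max_water_loss = 2L,
    catalog = NULL, seed = NULL
  )
}

#' Load a run configuration
#'
#' Reads a YAML file of option overrides on top of the package defaults
#' (adduct `[M-H]-`, 0.02 Da / 10 ppm tolerances, water-loss cap 2). Unknown
#' keys are an error, so typos cannot silently fall back to defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
    }
    cfg[names(user)] <- user
  }
  cfg
}
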