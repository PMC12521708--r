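#' Opioid formulary: drugs, OME conversion factors, available strengths
#'
#' A formulary holds, per opioid, its oral-morphine-equivalent (OME)
#' conversion factor (mg OME per mg drug, oral route) and the commercially
#' available formulation strengths. All dose arithmetic in the package runs
#' through a formulary; there are no hard-coded conversion factors. Oral
#' route only: parenteral and transdermal conversion are out of scope, as is
#' methadone, whose conversion is dose-dependent (nonlinear).
#'
#' @section File formats:
#' JSON: `{"version": str, "opioids": [{"name", "ome_factor",
#' "formulations": [{"strength_mg", "release", "units_per_pack"}],
#' "is_backup_suitable"}]}`.
#' CSV: one row per formulation with columns `name`, `ome_factor`,
#' `strength_mg`, `release`, `units_per_pack`, plus optional
#' `is_backup_suitable`.
#'
#' @name formulary
NULL

#' Create an opioid specification
#'
#' @param name Lowercase drug identifier, unique within a formulary.
#' @param ome_factor Positive conversion factor, mg OME per mg drug (oral).
#'   Oral morphine must have factor exactly 1.
#' @param formulations Data frame with columns `strength_mg` (positive),
#'   `release` (`"immediate"` or `"extended"`), `units_per_pack` (integer
#'   >= 1). May have zero rows for conversion-only entries.
#' @param is_backup_suitable Logical; `TRUE` when an immediate-release form
#'   exists so the drug can serve as back-up (rescue) medication.
#' @return An object of class `opioid_spec`.
#' @export
opioid_spec <- function(name, ome_factor, formulations = NULL,
                        is_backup_suitable = NA) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_validation("'name' must be a non-empty string")
  }
  name <- tolower(name)
  check_number(ome_factor, "ome_factor", min = 0, strict_min = TRUE)
  if (name == "morphine" && ome_factor != 1) {
    stop_validation("oral morphine must have ome_factor exactly 1")
  }
  if (is.null(formulations)) {
    formulations <- data.frame(
      strength_mg = numeric(), release = character(),
      units_per_pack = integer(), stringsAsFactors = FALSE
    )
  }
  formulations <- validate_formulations(formulations, name)
  if (is.na(is_backup_suitable)) {
    is_backup_suitable <- any(formulations$release == "immediate")
  }
  check_flag(is_backup_suitable, "is_backup_suitable")
  structure(
    list(
      name = name, ome_factor = as.numeric(ome_factor),
      formulations = formulations, is_backup_suitable = is_backup_suitable
    ),
    class = "opioid_spec"
  )
}

validate_formulations <- function(df, drug) {
  if (!is.data.frame(df)) {
    stop_validation(sprintf("formulations for '%s' must be a data frame", drug))
  }
  needed <- c("strength_mg", "release", "units_per_pack")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop_validation(sprintf(
      "formulations for '%s' lack column(s): %s",
      drug, paste(missing_cols, collapse = ", ")
    ))
  }
  df <- df[needed]
  if (nrow(df)) {
    if (any(!is.finite(df$strength_mg)) || any(df$strength_mg <= 0)) {
      stop_validation(sprintf("'%s': strength_mg must be positive", drug))
    }
    if (!all(df$release %in% c("immediate", "extended"))) {
      stop_validation(sprintf(
        "'%s': release must be 'immediate' or 'extended'", drug
      ))
    }
    upp <- df$units_per_pack
    if (any(!is.finite(upp)) || any(upp < 1) || any(upp != round(upp))) {
      stop_validation(sprintf("'%s': units_per_pack must be integers >= 1", drug))
    }
    df$units_per_pack <- as.integer(upp)
    df <- df[order(df$strength_mg, df$release), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Build a formulary from opioid specifications
#'
#' @param ... `opioid_spec` objects (or a single list of them).
#' @param version Free-text version string identifying the conversion table
#'   edition.
#' @return An object of class `formulary`.
#' @examples
#' f <- formulary(
#'   opioid_spec("morphine", 1,
#'     data.frame(strength_mg = c(10, 30), release = "immediate",
#'                units_per_pack = 20L)),
#'   version = "example"
#' )
#' to_ome("morphine", 50, f)
#' @export
formulary <- function(..., version = "unversioned") {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1L]], "opioid_spec") &&
      is.list(specs[[1L]])) {
    specs <- specs[[1L]]
  }
  if (!length(specs)) stop_validation("a formulary must contain >= 1 opioid")
  ok <- vapply(specs, inherits, logical(1L), what = "opioid_spec")
  if (!all(ok)) stop_validation("all entries must be opioid_spec objects")
  nms <- vapply(specs, `[[`, character(1L), "name")
  dup <- unique(nms[duplicated(nms)])
  if (length(dup)) {
    stop_validation(sprintf(
      "duplicate opioid name(s) in formulary: %s", paste(dup, collapse = ", ")
    ))
  }
  names(specs) <- nms
  structure(list(version = as.character(version), opioids = specs),
            class = "formulary")
}

#' @export
print.formulary <- function(x, ...) {
  cat(sprintf("<formulary> version '%s', %d opioids\n",
              x$version, length(x$opioids)))
  for (sp in x$opioids) {
    cat(sprintf(
      "  %-14s factor %-6g %d formulation(s)%s\n", sp$name, sp$ome_factor,
      nrow(sp$formulations), if (sp$is_backup_suitable) ", backup-suitable" else ""
    ))
  }
  invisible(x)
}

lookup_opioid <- function(drug, formulary) {
  if (!inherits(formulary, "formulary")) {
    stop_validation("'formulary' must be a formulary object")
  }
  if (!is.character(drug) || length(drug) != 1L) {
    stop_validation("'drug' must be a single drug name")
  }
  drug <- tolower(drug)
  if (drug == "methadone" && is.null(formulary$opioids[[drug]])) {
    stop_lookup(paste(
      "methadone is not supported: its equianalgesic conversion is",
      "dose-dependent (nonlinear) and outside this calculator's scope"
    ))
  }
  sp <- formulary$opioids[[drug]]
  if (is.null(sp)) {
    stop_lookup(sprintf("unknown drug '%s' (not in formulary '%s')",
                        drug, formulary$version))
  }
  sp
}

#' Convert a drug dose to oral morphine equivalents
#'
#' `to_ome()` multiplies a dose by the drug's OME conversion factor;
#' `from_ome()` divides, recovering the drug dose that corresponds to a given
#' OME amount. Both are exact (no rounding) and exact inverses of each other.
#'
#' @param drug Drug name present in `formulary`.
#' @param dose_mg Non-negative dose in mg of the drug per 24 h.
#' @param ome_mg Non-negative dose in mg OME per 24 h.
#' @param formulary A [formulary] object.
#' @return Numeric scalar: mg OME (`to_ome`) or mg drug (`from_ome`).
#' @examples
#' f <- default_formulary()
#' to_ome("oxycodone", 40, f)
#' from_ome("oxycodone", 60, f)
#' @export
to_ome <- function(drug, dose_mg, formulary) {
  sp <- lookup_opioid(drug, formulary)
  check_number(dose_mg, "dose_mg", min = 0)
  dose_mg * sp$ome_factor
}

#' @rdname to_ome
#' @export
from_ome <- function(drug, ome_mg, formulary) {
  sp <- lookup_opioid(drug, formulary)
  check_number(ome_mg, "ome_mg", min = 0)
  ome_mg / sp$ome_factor
}

#' Read a formulary from JSON or CSV
#'
#' The format is chosen by file extension (`.json` or `.csv`). Validation is
#' strict: unknown drugs later fail loudly, negative factors and duplicate
#' drug names are rejected at load time.
#'
#' @param path Path to a formulary file.
#' @return A [formulary] object.
#' @export
load_formulary <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_validation(sprintf("formulary file not found: '%s'", path))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    load_formulary_json(path)
  } else if (ext == "csv") {
    load_formulary_csv(path)
  } else {
    stop_validation(sprintf("unsupported formulary format '.%s' (json or csv)", ext))
  }
}

load_formulary_json <- function(path) {
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    error = function(e) stop_validation(sprintf(
      "cannot parse formulary JSON '%s': %s", path, conditionMessage(e)
    ))
  )
  if (is.null(raw$opioids) || !length(raw$opioids)) {
    stop_validation(sprintf("formulary '%s' has no 'opioids' array", path))
  }
  specs <- lapply(raw$opioids, function(o) {
    for (field in c("name", "ome_factor")) {
      if (is.null(o[[field]])) {
        stop_validation(sprintf(
          "formulary '%s': opioid entry lacks field '%s'", path, field
        ))
      }
    }
    fmts <- if (length(o$formulations)) {
      do.call(rbind, lapply(o$formulations, function(fm) {
        for (field in c("strength_mg", "release", "units_per_pack")) {
          if (is.null(fm[[field]])) {
            stop_validation(sprintf(
              "formulary '%s', drug '%s': formulation lacks field '%s'",
              path, o$name, field
            ))
          }
        }
        data.frame(
          strength_mg = as.numeric(fm$strength_mg),
          release = as.character(fm$release),
          units_per_pack = as.integer(fm$units_per_pack),
          stringsAsFactors = FALSE
        )
      }))
    } else NULL
    opioid_spec(o$name, o$ome_factor, fmts,
                is_backup_suitable = o$is_backup_suitable %||% NA)
  })
  formulary(specs, version = raw$version %||% "unversioned")
}

load_formulary_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop_validation(sprintf(
      "cannot parse formulary CSV '%s': %s", path, conditionMessage(e)
    ))
  )
  needed <- c("name", "ome_factor", "strength_mg", "release", "units_per_pack")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop_validation(sprintf(
      "formulary CSV '%s' lacks column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  specs <- lapply(split(df, tolower(df$name)), function(rows) {
    fac <- unique(rows$ome_factor)
    if (length(fac) != 1L) {
      stop_validation(sprintf(
        "formulary CSV '%s': conflicting ome_factor values for '%s'",
        path, rows$name[1L]
      ))
    }
    backup <- if ("is_backup_suitable" %in% names(rows)) {
      isTRUE(as.logical(rows$is_backup_suitable[1L]))
    } else NA
    opioid_spec(
      rows$name[1L], fac,
      rows[c("strength_mg", "release", "units_per_pack")],
      is_backup_suitable = backup
    )
  })
  formulary(unname(specs), version = paste0("csv:", basename(path)))
}

#' Write a formulary to JSON
#'
#' Inverse of [load_formulary()] for the JSON format; loading then writing
#' then loading again yields an identical formulary.
#'
#' @param formulary A [formulary] object.
#' @param path Output file path (`.json`).
#' @return `path`, invisibly.
#' @export
write_formulary <- function(formulary, path) {
  if (!inherits(formulary, "formulary")) {
    stop_validation("'formulary' must be a formulary object")
  }
  out <- list(
    version = formulary$version,
    opioids = lapply(unname(formulary$opioids), function(sp) {
      list(
        name = sp$name,
        ome_factor = sp$ome_factor,
        formulations = lapply(seq_len(nrow(sp$formulations)), function(i) {
          as.list(sp$formulations[i, ])
        }),
        is_backup_suitable = sp$is_backup_suitable
      )
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' The packaged default formulary
#'
#' Loads the conversion table shipped with the package
#' (`inst/extdata/formulary.json`): oral-route OME factors following the
#' 2016 edition of the CDC morphine-milligram-equivalent table, with typical
#' European tablet/capsule strengths. Treat it as configuration — analyses
#' that must be reproducible should pin their own formulary file.
#'
#' @return A [formulary] object.
#' @export
default_formulary <- function() {
  load_formulary(system.file("extdata", "formulary.json", package = "opitaper",
                             mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
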