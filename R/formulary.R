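#' @keywords internal
"_PACKAGE"

# Routes the formulary recognises, and the dose unit each route implies.
# Oral and subcutaneous doses are totals over 24 h in milligrams; transdermal
# patches are labelled by delivery rate in micrograms per hour.
.routes <- c("oral", "subcutaneous", "transdermal")

#' Dose unit implied by a route
#'
#' Oral and subcutaneous opioid doses are expressed as milligrams per 24
#' hours; transdermal patches are labelled by delivery rate in micrograms per
#' hour. Units are fixed by route so that a dose number can never be read in
#' the wrong unit.
#'
#' @param route One of `"oral"`, `"subcutaneous"`, `"transdermal"`.
#' @return `"mg/24h"` or `"microgram/h"`.
#' @export
#' @examples
#' route_unit("oral")
#' route_unit("transdermal")
route_unit <- function(route) {
  if (!route %in% .routes) {
    stop("unknown route: ", route, call. = FALSE)
  }
  if (route == "transdermal") "microgram/h" else "mg/24h"
}

new_formulary <- function(version, drug_routes, factors, patch_tables,
                          breakthrough_divisor, egfr_warning_threshold,
                          practical_increments) {
  structure(
    list(
      version = version,
      drug_routes = drug_routes,
      factors = factors,
      patch_tables = patch_tables,
      breakthrough_divisor = breakthrough_divisor,
      egfr_warning_threshold = egfr_warning_threshold,
      practical_increments = practical_increments
    ),
    class = "formulary"
  )
}

#' Validate a formulary
#'
#' Checks every structural invariant a formulary must satisfy before it may
#' drive conversions, and returns *all* violations, not just the first:
#'
#' * `(drug, route)` pairs unique; routes drawn from the known route set;
#'   dose units consistent with the route.
#' * Methadone, if present, is marked unsupported (its pharmacodynamics make
#'   table-based conversion unsafe).
#' * A hub factor exists: `(morphine, oral)` with `ome_per_unit` exactly 1.
#' * Every conversion factor is strictly positive and refers to a declared
#'   drug/route.
#' * Every supported non-transdermal drug/route has exactly one factor; every
#'   supported transdermal drug has a non-empty patch table.
#' * Patch bands are sorted by strength, strength strictly increasing with
#'   `ome_low`, bands non-overlapping except that one band's `ome_high` may
#'   equal the next band's `ome_low` (the shared border).
#'
#' @param formulary A `formulary` object.
#' @return Character vector of violation messages; `character(0)` when valid.
#' @seealso [load_formulary()], which calls this and turns violations into an
#'   error.
#' @export
validate_formulary <- function(formulary) {
  f <- formulary
  bad <- character(0)
  dr <- f$drug_routes

  key <- paste(dr$drug, dr$route)
  if (anyDuplicated(key)) {
    bad <- c(bad, paste0("duplicate drug/route entries: ",
                         paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  if (!all(dr$route %in% .routes)) {
    bad <- c(bad, paste0("unknown route(s): ",
                         paste(setdiff(dr$route, .routes), collapse = ", ")))
  }
  ok_route <- dr$route %in% .routes
  if (any(ok_route)) {
    want <- vapply(dr$route[ok_route], route_unit, character(1))
    wrong <- dr$unit[ok_route] != want
    if (any(wrong)) {
      bad <- c(bad, paste0("unit inconsistent with route for: ",
                           paste(key[ok_route][wrong], collapse = ", ")))
    }
  }
  if (any(dr$drug == "methadone" & dr$supported)) {
    bad <- c(bad, "methadone must have supported=false")
  }

  fa <- f$factors
  fkey <- paste(fa$drug, fa$route)
  hub <- fa$drug == "morphine" & fa$route == "oral"
  if (!any(hub)) {
    bad <- c(bad, "missing hub factor: (morphine, oral) must be present")
  } else if (any(fa$ome_per_unit[hub] != 1)) {
    bad <- c(bad, "hub factor (morphine, oral) must have ome_per_unit exactly 1")
  }
  if (any(!is.finite(fa$ome_per_unit) | fa$ome_per_unit <= 0)) {
    bad <- c(bad, paste0("non-positive ome_per_unit for: ",
                         paste(fkey[!is.finite(fa$ome_per_unit) |
                                      fa$ome_per_unit <= 0], collapse = ", ")))
  }
  orphan <- !fkey %in% key
  if (any(orphan)) {
    bad <- c(bad, paste0("factor for undeclared drug/route: ",
                         paste(fkey[orphan], collapse = ", ")))
  }
  if (anyDuplicated(fkey)) {
    bad <- c(bad, paste0("duplicate factors for: ",
                         paste(unique(fkey[duplicated(fkey)]), collapse = ", ")))
  }
  need_factor <- dr$supported & dr$route != "transdermal"
  missing_f <- need_factor & !key %in% fkey
  if (any(missing_f)) {
    bad <- c(bad, paste0("supported drug/route without conversion factor: ",
                         paste(key[missing_f], collapse = ", ")))
  }

  need_table <- dr$supported & dr$route == "transdermal"
  for (d in dr$drug[need_table]) {
    tab <- f$patch_tables[[d]]
    if (is.null(tab) || nrow(tab) == 0) {
      bad <- c(bad, paste0("supported transdermal drug without patch table: ", d))
      next
    }
    if (is.unsorted(tab$strength, strictly = TRUE)) {
      bad <- c(bad, paste0("patch strengths not strictly increasing for: ", d))
    }
    if (is.unsorted(tab$ome_low, strictly = TRUE)) {
      bad <- c(bad, paste0("patch ome_low not strictly increasing with strength for: ", d))
    }
    if (any(tab$ome_high <= tab$ome_low)) {
      bad <- c(bad, paste0("patch band with ome_high <= ome_low for: ", d))
    }
    if (nrow(tab) > 1) {
      gap <- tab$ome_low[-1] - tab$ome_high[-nrow(tab)]
      if (any(gap < 0)) {
        bad <- c(bad, paste0("overlapping patch bands for: ", d))
      }
    }
  }
  extra_tab <- setdiff(names(f$patch_tables), dr$drug[dr$route == "transdermal"])
  if (length(extra_tab)) {
    bad <- c(bad, paste0("patch table for undeclared transdermal drug: ",
                         paste(extra_tab, collapse = ", ")))
  }

  if (!is.numeric(f$breakthrough_divisor) || f$breakthrough_divisor <= 0) {
    bad <- c(bad, "breakthrough_divisor must be a positive number")
  }
  if (!is.numeric(f$egfr_warning_threshold) || f$egfr_warning_threshold <= 0) {
    bad <- c(bad, "egfr_warning_threshold must be a positive number")
  }
  inc <- unlist(f$practical_increments)
  if (length(inc) && any(!is.finite(inc) | inc <= 0)) {
    bad <- c(bad, "practical increments must be positive numbers")
  }
  bad
}

.formulary_schema_error <- function(field, detail) {
  stop("formulary schema error in field `", field, "`: ", detail, call. = FALSE)
}

.as_formulary <- function(x, where = "formulary") {
  for (k in c("version", "drugs", "factors")) {
    if (is.null(x[[k]])) .formulary_schema_error(k, "required key missing")
  }
  version <- as.character(x$version)

  parse_entries <- function(entries, field, required) {
    if (length(entries) == 0) .formulary_schema_error(field, "must be non-empty")
    lapply(seq_along(entries), function(i) {
      e <- entries[[i]]
      for (k in required) {
        if (is.null(e[[k]])) {
          .formulary_schema_error(paste0(field, "[", i, "].", k),
                                  "required key missing")
        }
      }
      e
    })
  }

  drugs <- parse_entries(x$drugs, "drugs", c("drug", "route"))
  drug_routes <- do.call(rbind, lapply(drugs, function(e) {
    route <- as.character(e$route)
    if (!route %in% .routes) {
      .formulary_schema_error("drugs.route",
                              paste0("unknown route `", route, "`"))
    }
    data.frame(
      drug = tolower(as.character(e$drug)),
      route = route,
      unit = route_unit(route),
      supported = if (is.null(e$supported)) TRUE else isTRUE(e$supported),
      renal_risk = isTRUE(e$renal_risk),
      stringsAsFactors = FALSE
    )
  }))

  factors <- do.call(rbind, lapply(
    parse_entries(x$factors, "factors", c("drug", "route", "ome_per_unit")),
    function(e) {
      if (!is.numeric(e$ome_per_unit)) {
        .formulary_schema_error("factors.ome_per_unit", "must be a number")
      }
      data.frame(
        drug = tolower(as.character(e$drug)),
        route = as.character(e$route),
        ome_per_unit = as.numeric(e$ome_per_unit),
        stringsAsFactors = FALSE
      )
    }
  ))

  patch_tables <- list()
  if (!is.null(x$patch_tables)) {
    patch_tables <- lapply(x$patch_tables, function(bands) {
      do.call(rbind, lapply(
        parse_entries(bands, "patch_tables", c("strength", "ome_low", "ome_high")),
        function(b) {
          data.frame(strength = as.numeric(b$strength),
                     ome_low = as.numeric(b$ome_low),
                     ome_high = as.numeric(b$ome_high))
        }
      ))
    })
    names(patch_tables) <- tolower(names(x$patch_tables))
  }

  defaults <- if (is.null(x$defaults)) list() else x$defaults
  divisor <- if (is.null(defaults$breakthrough_divisor)) 6 else
    as.numeric(defaults$breakthrough_divisor)
  egfr_thr <- if (is.null(defaults$egfr_warning_threshold)) 30 else
    as.numeric(defaults$egfr_warning_threshold)
  increments <- if (is.null(defaults$practical_increments)) list() else
    lapply(defaults$practical_increments, as.numeric)

  f <- new_formulary(version, drug_routes, factors, patch_tables,
                     divisor, egfr_thr, increments)
  bad <- validate_formulary(f)
  if (length(bad)) {
    stop("invalid formulary (", where, "):\n  - ",
         paste(bad, collapse = "\n  - "), call. = FALSE)
  }
  f
}

#' Load a formulary from a YAML or JSON file
#'
#' A formulary file is the data-driven stand-in for a guideline's
#' equianalgesic tables: drugs and routes, oral-morphine-equivalent
#' conversion factors, transdermal patch band tables, renal-risk flags and
#' the practical defaults (breakthrough divisor, eGFR warning threshold,
#' rounding increments). Conversion ratios are deliberately data, never code,
#' so a guideline revision never requires a software change. The machine
#' readable schema ships at
#' `system.file("extdata", "formulary-schema.json", package = "omeconvert")`.
#'
#' Files ending in `.json` are parsed as JSON, everything else as YAML (of
#' which JSON is a subset). Parsing is followed by full invariant validation;
#' a validation failure reports every violation, not just the first.
#'
#' @param path Path to the formulary file.
#' @return A `formulary` object.
#' @export
#' @examples
#' f <- load_formulary(system.file("extdata", "formulary-f1.yaml",
#'                                 package = "omeconvert"))
#' f$version
load_formulary <- function(path) {
  if (!file.exists(path)) stop("formulary file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  .as_formulary(raw, where = path)
}

#' Serialise a formulary back to a file
#'
#' Writes the structured-text representation accepted by [load_formulary()];
#' loading the written file reproduces a structurally identical formulary
#' (the round-trip property the test suite asserts). Format follows the file
#' extension: `.json` writes JSON, anything else YAML.
#'
#' @param formulary A `formulary` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_formulary <- function(formulary, path) {
  f <- formulary
  dr <- f$drug_routes
  x <- list(
    version = f$version,
    drugs = lapply(seq_len(nrow(dr)), function(i) {
      list(drug = dr$drug[i], route = dr$route[i],
           supported = dr$supported[i], renal_risk = dr$renal_risk[i])
    }),
    factors = lapply(seq_len(nrow(f$factors)), function(i) {
      list(drug = f$factors$drug[i], route = f$factors$route[i],
           ome_per_unit = f$factors$ome_per_unit[i])
    }),
    patch_tables = lapply(f$patch_tables, function(tab) {
      lapply(seq_len(nrow(tab)), function(i) {
        list(strength = tab$strength[i], ome_low = tab$ome_low[i],
             ome_high = tab$ome_high[i])
      })
    }),
    defaults = list(
      breakthrough_divisor = f$breakthrough_divisor,
      egfr_warning_threshold = f$egfr_warning_threshold,
      practical_increments = f$practical_increments
    )
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Look up the OME conversion factor for a drug/route
#'
#' Absence is a value, not an error: a drug/route pair without a published
#' equianalgesic factor returns `NULL`, and callers must treat that as "no
#' guideline equivalence" — a number is never fabricated.
#'
#' @param formulary A `formulary` object.
#' @param drug Drug name (case-insensitive).
#' @param route Route name.
#' @return A list with `drug`, `route`, `ome_per_unit`, or `NULL` when the
#'   formulary carries no factor for the pair.
#' @export
#' @examples
#' f1 <- fixture_formulary_f1()
#' lookup_factor(f1, "oxycodone", "oral")$ome_per_unit
#' lookup_factor(f1, "buprenorphine", "oral")  # NULL: no equivalence
lookup_factor <- function(formulary, drug, route) {
  fa <- formulary$factors
  i <- which(fa$drug == tolower(drug) & fa$route == route)
  if (length(i) == 0) return(NULL)
  list(drug = fa$drug[i], route = fa$route[i], ome_per_unit = fa$ome_per_unit[i])
}

.drug_route_entry <- function(formulary, drug, route) {
  dr <- formulary$drug_routes
  i <- which(dr$drug == tolower(drug) & dr$route == route)
  if (length(i) == 0) return(NULL)
  as.list(dr[i, , drop = FALSE])
}

# Practical rounding increment for a drug/route: an exact "drug:route" key
# wins over a route-level key; NULL when no increment is configured.
.lookup_increment <- function(formulary, drug, route) {
  inc <- formulary$practical_increments
  exact <- inc[[paste0(tolower(drug), ":", route)]]
  if (!is.null(exact)) return(exact)
  inc[[route]]
}

#' @export
print.formulary <- function(x, ...) {
  cat("<formulary> version", x$version, "\n")
  cat("  drug/routes:", nrow(x$drug_routes),
      "(", sum(x$drug_routes$supported), "supported )\n")
  cat("  factors:", nrow(x$factors),
      "| patch tables:", length(x$patch_tables), "\n")
  cat("  breakthrough divisor:", x$breakthrough_divisor,
      "| eGFR warning threshold:", x$egfr_warning_threshold, "mL/min\n")
  invisible(x)
}
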