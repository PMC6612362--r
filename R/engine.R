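# Dose comparisons are canonicalised to integer micro-milligrams so that
# clinically meaningful equalities -- above all a calculated OME landing
# exactly on a shared patch-band border -- never depend on binary float
# representation. Arithmetic itself stays in doubles (exact inverses hold to
# ~1e-16), only *comparisons* go through the key.
.dose_key <- function(x) round(x * 1e6)

.warning_codes <- c("renal_caution", "below_smallest_patch",
                    "above_largest_patch", "large_dose")

new_warning <- function(code, message) {
  stopifnot(code %in% .warning_codes)
  structure(list(code = code, message = message), class = "dose_warning")
}

#' Build a conversion request
#'
#' One opioid switch to be converted: an index (starting) drug/route/dose and
#' a target drug/route, with optional patient context. Doses are in the
#' route's fixed unit: mg per 24 h for oral and subcutaneous, micrograms per
#' hour for transdermal.
#'
#' @param index_drug,index_route Starting opioid and route.
#' @param index_dose Starting dose, strictly positive, in the index route's
#'   unit.
#' @param target_drug,target_route Opioid and route being switched to.
#' @param egfr Optional estimated glomerular filtration rate (mL/min),
#'   non-negative; used for the renal caution. Omitted eGFR produces no
#'   warning — kidney function is never silently assumed normal or abnormal.
#' @param indication Optional indication category (closed list; see
#'   [audit_indications()]).
#' @param rounding `"off"` (exact target dose) or `"practical"` (round down
#'   to the formulary's practical increment).
#' @return A `conversion_request` object.
#' @export
#' @examples
#' conversion_request("morphine", "oral", 60, "oxycodone", "oral")
conversion_request <- function(index_drug, index_route, index_dose,
                               target_drug, target_route,
                               egfr = NULL, indication = NULL,
                               rounding = c("off", "practical")) {
  rounding <- match.arg(rounding)
  if (!is.numeric(index_dose) || length(index_dose) != 1 ||
      !is.finite(index_dose) || index_dose <= 0) {
    stop("index_dose must be a single positive number", call. = FALSE)
  }
  if (!is.null(egfr)) {
    if (!is.numeric(egfr) || length(egfr) != 1 || !is.finite(egfr) || egfr < 0) {
      stop("egfr must be a single non-negative number", call. = FALSE)
    }
  }
  for (r in c(index_route, target_route)) {
    if (!r %in% .routes) stop("unknown route: ", r, call. = FALSE)
  }
  structure(
    list(index_drug = tolower(index_drug), index_route = index_route,
         index_dose = index_dose, target_drug = tolower(target_drug),
         target_route = target_route, egfr = egfr, indication = indication,
         rounding = rounding),
    class = "conversion_request"
  )
}

#' Convert a dose to its 24-hour oral morphine equivalent
#'
#' The hub map: `dose * ome_per_unit` for the drug/route. Everything in the
#' engine converts through oral morphine equivalents rather than a dense
#' pairwise ratio matrix, which guarantees transitive consistency of chained
#' conversions.
#'
#' @inheritParams lookup_factor
#' @param dose Strictly positive dose in the route's unit.
#' @return OME in mg/24h, or `NULL` when the formulary has no factor for the
#'   pair (no guideline equivalence).
#' @export
#' @examples
#' f1 <- fixture_formulary_f1()
#' to_ome(f1, "oxycodone", "oral", 30)  # 60
to_ome <- function(formulary, drug, route, dose) {
  if (!is.numeric(dose) || length(dose) != 1 || !is.finite(dose) || dose <= 0) {
    stop("dose must be a single positive number", call. = FALSE)
  }
  fac <- lookup_factor(formulary, drug, route)
  if (is.null(fac)) return(NULL)
  dose * fac$ome_per_unit
}

#' Convert a 24-hour oral morphine equivalent to a target dose
#'
#' Exact inverse of [to_ome()]: `ome / ome_per_unit`. Only continuous
#' (non-transdermal) targets have a continuous dose scale; transdermal
#' targets must go through [select_patch()] because patches exist only in
#' discrete strengths.
#'
#' @inheritParams lookup_factor
#' @param ome Strictly positive OME in mg/24h.
#' @return Dose in the target route's unit, or `NULL` when no factor exists.
#' @export
#' @examples
#' f1 <- fixture_formulary_f1()
#' from_ome(f1, "morphine", "subcutaneous", 60)  # 30
from_ome <- function(formulary, drug, route, ome) {
  if (!is.numeric(ome) || length(ome) != 1 || !is.finite(ome) || ome <= 0) {
    stop("ome must be a single positive number", call. = FALSE)
  }
  if (route == "transdermal") {
    stop("transdermal targets have discrete strengths; use select_patch()",
         call. = FALSE)
  }
  fac <- lookup_factor(formulary, drug, route)
  if (is.null(fac)) return(NULL)
  ome / fac$ome_per_unit
}

#' Select a transdermal patch strength for an OME
#'
#' Finds the band whose inclusive `[ome_low, ome_high]` range contains the
#' OME. When the OME lands exactly on the border shared by two adjacent bands
#' the *lower*-strength patch is returned: rounding down is the safety
#' direction for opioids, and rounding up at exactly this border is the
#' historical defect this rule corrects. OMEs below the smallest band return
#' no band plus a `below_smallest_patch` warning; OMEs above the largest band
#' return the largest band plus an `above_largest_patch` warning (combination
#' patches are real practice, so a warning, not an error).
#'
#' @param table A patch band `data.frame` with columns `strength`, `ome_low`,
#'   `ome_high`, passing the formulary invariants.
#' @param ome Strictly positive OME in mg/24h.
#' @param tie `"down"` (default, corrected behaviour) or `"up"` (re-enables
#'   the historical round-up defect; exists solely so the defect's signature
#'   can be reproduced and regression-tested).
#' @return A list with `band` (one-row data.frame or `NULL`) and `warning`
#'   (a warning object or `NULL`).
#' @export
#' @examples
#' f1 <- fixture_formulary_f1()
#' select_patch(f1$patch_tables$fentanyl, 70)$band$strength   # 25
#' select_patch(f1$patch_tables$fentanyl, 60)$band$strength   # 12: border -> down
select_patch <- function(table, ome, tie = c("down", "up")) {
  tie <- match.arg(tie)
  if (is.null(table) || nrow(table) == 0) {
    stop("empty patch table", call. = FALSE)
  }
  if (!is.numeric(ome) || length(ome) != 1 || !is.finite(ome) || ome <= 0) {
    stop("ome must be a single positive number", call. = FALSE)
  }
  k <- .dose_key(ome)
  lo <- .dose_key(table$ome_low)
  hi <- .dose_key(table$ome_high)
  inside <- which(lo <= k & k <= hi)
  if (length(inside) >= 1) {
    pick <- if (tie == "down") inside[1] else inside[length(inside)]
    return(list(band = table[pick, , drop = FALSE], warning = NULL))
  }
  if (k < lo[1]) {
    return(list(
      band = NULL,
      warning = new_warning(
        "below_smallest_patch",
        sprintf("OME %g mg/24h is below the smallest patch band (starts at %g mg/24h)",
                ome, table$ome_low[1]))
    ))
  }
  if (k > hi[length(hi)]) {
    n <- nrow(table)
    return(list(
      band = table[n, , drop = FALSE],
      warning = new_warning(
        "above_largest_patch",
        sprintf("OME %g mg/24h exceeds the largest patch band (ends at %g mg/24h); largest strength returned",
                ome, table$ome_high[n]))
    ))
  }
  # OME falls in a gap between bands: round down to the band below.
  below <- which(hi < k)
  list(band = table[below[length(below)], , drop = FALSE], warning = NULL)
}

#' Round a dose down to a practical increment
#'
#' Practical (deliverable) doses are multiples of a formulation increment.
#' Rounding is always *down* — the single safety direction used throughout
#' the engine — except that a positive dose is never rounded to zero: a dose
#' below one increment returns the increment itself with `inflated = TRUE`,
#' which callers surface as a `large_dose` warning because the practical dose
#' then exceeds the exact dose.
#'
#' @param dose Strictly positive dose.
#' @param increment Strictly positive increment.
#' @return A list with `dose` (the rounded value) and `inflated` (logical).
#' @export
#' @examples
#' round_practical(31.2, 2.5)  # 30, not inflated
#' round_practical(1.1, 2.5)   # 2.5, inflated
round_practical <- function(dose, increment) {
  if (!is.numeric(increment) || increment <= 0) {
    stop("increment must be positive", call. = FALSE)
  }
  if (!is.numeric(dose) || dose <= 0) {
    stop("dose must be positive", call. = FALSE)
  }
  n <- floor(round(dose / increment, 9))
  if (n < 1) list(dose = increment, inflated = TRUE)
  else list(dose = n * increment, inflated = FALSE)
}

#' Breakthrough (rescue) dose from a regular daily dose
#'
#' The as-needed rescue dose for pain flares, computed as the total regular
#' 24-hour dose divided by the formulary's breakthrough divisor (default 6,
#' i.e. one sixth of the daily dose — standard palliative-care practice).
#' Transdermal routes are refused: breakthrough is computed on a 24-hour
#' dose, so patch users convert to an OME first.
#'
#' @inheritParams lookup_factor
#' @param daily_dose Total regular 24-hour dose, strictly positive, mg/24h.
#' @param rounding `"off"` (default) returns the exact quotient;
#'   `"practical"` additionally rounds down to the configured increment.
#' @return Breakthrough dose in mg. When practical rounding inflates the
#'   dose (exact dose below one increment) the result carries attribute
#'   `inflated = TRUE`.
#' @export
#' @examples
#' f1 <- fixture_formulary_f1()
#' breakthrough_dose(f1, "morphine", "oral", 60)  # 10
breakthrough_dose <- function(formulary, drug, route, daily_dose,
                              rounding = c("off", "practical")) {
  rounding <- match.arg(rounding)
  if (route == "transdermal") {
    stop("breakthrough is computed on a 24-hour dose; convert the patch to OME first",
         call. = FALSE)
  }
  if (!is.numeric(daily_dose) || length(daily_dose) != 1 ||
      !is.finite(daily_dose) || daily_dose <= 0) {
    stop("daily_dose must be a single positive number", call. = FALSE)
  }
  dose <- daily_dose / formulary$breakthrough_divisor
  if (rounding == "practical") {
    inc <- .lookup_increment(formulary, drug, route)
    if (!is.null(inc)) {
      rp <- round_practical(dose, inc)
      dose <- rp$dose
      if (rp$inflated) attr(dose, "inflated") <- TRUE
    }
  }
  dose
}

#' Renal-impairment caution for a drug
#'
#' Fires a `renal_caution` warning if and only if an eGFR was provided, it is
#' below the formulary's warning threshold (default 30 mL/min), and the drug
#' is flagged as needing caution in renal impairment. An absent eGFR produces
#' no warning: kidney function is never silently assumed.
#'
#' @inheritParams lookup_factor
#' @param egfr Estimated glomerular filtration rate in mL/min, or `NULL`.
#' @return A warning object, or `NULL`.
#' @export
#' @examples
#' f1 <- fixture_formulary_f1()
#' renal_warning(f1, "morphine", egfr = 20)$code  # "renal_caution"
renal_warning <- function(formulary, drug, egfr = NULL) {
  if (is.null(egfr)) return(NULL)
  if (!is.numeric(egfr) || length(egfr) != 1 || !is.finite(egfr) || egfr < 0) {
    stop("egfr must be a single non-negative number", call. = FALSE)
  }
  dr <- formulary$drug_routes
  risky <- any(dr$renal_risk[dr$drug == tolower(drug)])
  if (risky && egfr < formulary$egfr_warning_threshold) {
    new_warning(
      "renal_caution",
      sprintf("eGFR %g mL/min is below %g mL/min: consider dose adjustment of %s in renal impairment",
              egfr, formulary$egfr_warning_threshold, tolower(drug)))
  } else {
    NULL
  }
}

new_conversion_result <- function(status, formulary_version, request,
                                  ome = NULL, exact_target_dose = NULL,
                                  practical_target_dose = NULL,
                                  warnings = list(), target_unit = NULL) {
  structure(
    list(status = status, ome = ome, exact_target_dose = exact_target_dose,
         practical_target_dose = practical_target_dose, warnings = warnings,
         formulary_version = formulary_version, request = request,
         target_unit = target_unit),
    class = "conversion_result"
  )
}

#' Convert an opioid dose between drugs and routes
#'
#' The full decision-support pipeline: check both endpoints are supported,
#' map the index dose to its oral morphine equivalent, then either select a
#' patch strength (transdermal target) or invert the hub map (continuous
#' target), apply practical rounding if requested, and attach safety
#' warnings. A request either yields a dose or an explicit non-`ok` status —
#' a dose is never silently substituted or fabricated:
#'
#' * `unsupported_drug`: an endpoint drug is known but deliberately excluded
#'   from table-based conversion (methadone).
#' * `no_guideline_equivalence`: an endpoint has no conversion factor or
#'   patch table in the formulary. Such requests are what audit analysis
#'   excludes, and they are countable from the result status alone.
#'
#' @inheritParams lookup_factor
#' @param request A [conversion_request()].
#' @param patch_tie Border tie rule passed to [select_patch()]; leave at
#'   `"down"` outside of defect-regression studies.
#' @return A `conversion_result`; always carries the formulary version for
#'   audit. When `status != "ok"` no dose fields are populated.
#' @export
#' @examples
#' f1 <- fixture_formulary_f1()
#' convert(f1, conversion_request("morphine", "oral", 60, "oxycodone", "oral"))
convert <- function(formulary, request, patch_tie = c("down", "up")) {
  patch_tie <- match.arg(patch_tie)
  if (!inherits(request, "conversion_request")) {
    stop("request must be a conversion_request", call. = FALSE)
  }
  ver <- formulary$version
  dr <- formulary$drug_routes

  # Known-but-unsupported drugs (methadone) are a distinct refusal from a
  # simple gap in the guideline tables.
  for (d in c(request$index_drug, request$target_drug)) {
    if (any(dr$drug == d & !dr$supported)) {
      return(new_conversion_result("unsupported_drug", ver, request))
    }
  }

  ome <- to_ome(formulary, request$index_drug, request$index_route,
                request$index_dose)
  if (is.null(ome)) {
    return(new_conversion_result("no_guideline_equivalence", ver, request))
  }

  warnings <- list()
  rw <- renal_warning(formulary, request$target_drug, request$egfr)
  if (!is.null(rw)) warnings <- c(warnings, list(rw))

  if (request$target_route == "transdermal") {
    tab <- formulary$patch_tables[[request$target_drug]]
    entry <- .drug_route_entry(formulary, request$target_drug, "transdermal")
    if (is.null(tab) || is.null(entry)) {
      return(new_conversion_result("no_guideline_equivalence", ver, request))
    }
    sel <- select_patch(tab, ome, tie = patch_tie)
    if (!is.null(sel$warning)) warnings <- c(warnings, list(sel$warning))
    practical <- if (is.null(sel$band)) NULL else sel$band$strength
    return(new_conversion_result("ok", ver, request, ome = ome,
                                 exact_target_dose = NULL,
                                 practical_target_dose = practical,
                                 warnings = warnings,
                                 target_unit = "microgram/h"))
  }

  exact <- from_ome(formulary, request$target_drug, request$target_route, ome)
  if (is.null(exact)) {
    return(new_conversion_result("no_guideline_equivalence", ver, request))
  }
  practical <- exact
  if (request$rounding == "practical") {
    inc <- .lookup_increment(formulary, request$target_drug,
                             request$target_route)
    if (!is.null(inc)) {
      rp <- round_practical(exact, inc)
      practical <- rp$dose
      if (rp$inflated) {
        warnings <- c(warnings, list(new_warning(
          "large_dose",
          sprintf("practical dose %g mg exceeds the exact dose %g mg (exact dose below one %g mg increment)",
                  rp$dose, exact, inc))))
      }
    }
  }
  new_conversion_result("ok", ver, request, ome = ome,
                        exact_target_dose = exact,
                        practical_target_dose = practical,
                        warnings = warnings, target_unit = "mg/24h")
}

#' @export
print.conversion_result <- function(x, ...) {
  req <- x$request
  cat(sprintf("%s %s %g %s -> %s %s\n",
              req$index_drug, req$index_route, req$index_dose,
              route_unit(req$index_route), req$target_drug, req$target_route))
  if (x$status != "ok") {
    cat("  status:", x$status, "\n")
  } else {
    cat(sprintf("  OME: %g mg/24h\n", x$ome))
    if (!is.null(x$exact_target_dose)) {
      cat(sprintf("  exact dose: %g %s\n", x$exact_target_dose, x$target_unit))
    }
    if (!is.null(x$practical_target_dose)) {
      cat(sprintf("  practical dose: %g %s\n",
                  x$practical_target_dose, x$target_unit))
    } else {
      cat("  practical dose: none (no suitable patch band)\n")
    }
  }
  for (w in x$warnings) cat(sprintf("  warning [%s]: %s\n", w$code, w$message))
  cat("  formulary:", x$formulary_version, "\n")
  invisible(x)
}
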