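# Deterministic test fixtures and the two independent oracles used across
# the test suite. Fixture conversion values are chosen round and distinct so
# every hand example is mental arithmetic; they intentionally differ from any
# real guideline's values so the fixtures can never be mistaken for clinical
# guidance.

#' The F1 fixture formulary
#'
#' A 10-entry synthetic formulary used throughout the tests and examples.
#' Its values are NOT clinical data. Contents:
#'
#' | drug | route | factor | renal risk |
#' |---|---|---|---|
#' | morphine | oral | 1 (the hub) | yes |
#' | morphine | subcutaneous | 2 | yes |
#' | oxycodone | oral | 2 | no |
#' | oxycodone | subcutaneous | 4 | no |
#' | codeine | oral | 0.1 | yes |
#' | alfentanil | subcutaneous | 30 | no |
#' | diamorphine | subcutaneous | 3 | yes |
#' | hydromorphone | oral | 5 | no |
#' | methadone | oral | unsupported | — |
#' | fentanyl | transdermal | patch bands | no |
#'
#' Fentanyl patch bands (strength in microgram/h vs OME mg/24h):
#' 12: 30–60, 25: 60–90, 50: 90–150, 75: 150–210, 100: 210–270 — four shared
#' borders at OME 60, 90, 150 and 210. Defaults: breakthrough divisor 6,
#' eGFR warning threshold 30 mL/min, practical increment 2.5 mg for oral
#' routes. Buprenorphine is deliberately absent (a guideline gap for
#' exercising the no-equivalence path); methadone is present but
#' unsupported.
#'
#' The identical formulary ships as a file at
#' `system.file("extdata", "formulary-f1.yaml", package = "omeconvert")` to
#' exercise the loader.
#'
#' @return A `formulary` with `version == "F1"`.
#' @export
fixture_formulary_f1 <- function() {
  dr <- function(drug, route, supported = TRUE, renal_risk = FALSE) {
    data.frame(drug = drug, route = route, unit = route_unit(route),
               supported = supported, renal_risk = renal_risk,
               stringsAsFactors = FALSE)
  }
  drug_routes <- rbind(
    dr("morphine", "oral", renal_risk = TRUE),
    dr("morphine", "subcutaneous", renal_risk = TRUE),
    dr("oxycodone", "oral"),
    dr("oxycodone", "subcutaneous"),
    dr("codeine", "oral", renal_risk = TRUE),
    dr("alfentanil", "subcutaneous"),
    dr("diamorphine", "subcutaneous", renal_risk = TRUE),
    dr("hydromorphone", "oral"),
    dr("methadone", "oral", supported = FALSE),
    dr("fentanyl", "transdermal")
  )
  factors <- data.frame(
    drug = c("morphine", "morphine", "oxycodone", "oxycodone", "codeine",
             "alfentanil", "diamorphine", "hydromorphone"),
    route = c("oral", "subcutaneous", "oral", "subcutaneous", "oral",
              "subcutaneous", "subcutaneous", "oral"),
    ome_per_unit = c(1, 2, 2, 4, 0.1, 30, 3, 5),
    stringsAsFactors = FALSE
  )
  patch_tables <- list(
    fentanyl = data.frame(
      strength = c(12, 25, 50, 75, 100),
      ome_low = c(30, 60, 90, 150, 210),
      ome_high = c(60, 90, 150, 210, 270)
    )
  )
  f <- new_formulary("F1", drug_routes, factors, patch_tables,
                     breakthrough_divisor = 6, egfr_warning_threshold = 30,
                     practical_increments = list(oral = 2.5))
  stopifnot(length(validate_formulary(f)) == 0)
  f
}

#' Specification for the seeded request generator
#'
#' @param seed Integer seed; the same seed always yields the identical
#'   request sequence.
#' @param n_requests Total number of generated calculations.
#' @param frac_no_equivalence Fraction (exact count `round(frac * n)`) of
#'   conversion requests involving a drug with no guideline equivalence.
#' @param frac_border Fraction of requests whose OME lands exactly on a
#'   shared fentanyl patch-band border.
#' @param frac_unsupported Fraction of requests targeting the unsupported
#'   drug (methadone).
#' @param frac_breakthrough Fraction of breakthrough (rescue-dose)
#'   calculations.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(seed, n_requests, frac_no_equivalence = 0.05,
                         frac_border = 0.05, frac_unsupported = 0.02,
                         frac_breakthrough = 0.2) {
  stopifnot(n_requests > 0,
            frac_no_equivalence + frac_border + frac_unsupported +
              frac_breakthrough <= 1)
  structure(list(seed = as.integer(seed), n_requests = as.integer(n_requests),
                 frac_no_equivalence = frac_no_equivalence,
                 frac_border = frac_border,
                 frac_unsupported = frac_unsupported,
                 frac_breakthrough = frac_breakthrough),
            class = "fixture_spec")
}

# Supported continuous drug/route pairs of a formulary, as a data.frame.
.continuous_pairs <- function(formulary) {
  dr <- formulary$drug_routes
  dr[dr$supported & dr$route != "transdermal", c("drug", "route")]
}

.f1_borders <- c(60, 90, 150, 210)

#' Generate a deterministic sequence of calculation requests
#'
#' Draws requests over the F1 drug pool with the exact composition the spec
#' demands: `round(frac * n)` no-equivalence requests (buprenorphine, absent
#' from F1), border-exact fentanyl patch requests (OME landing exactly on a
#' shared band border), methadone requests, and breakthrough calculations;
#' the rest are ordinary conversions with non-border doses. Doses are drawn
#' on a 2.5 mg OME grid avoiding band borders. Order is shuffled, but the
#' whole sequence is a pure function of the seed (Mersenne-Twister).
#'
#' @param spec A [fixture_spec()].
#' @param formulary Formulary to draw the drug pool from; defaults to F1.
#' @return A list of elements, each either
#'   `list(kind = "conversion", request = <conversion_request>, border = <lgl>)`
#'   or `list(kind = "breakthrough", drug =, route =, daily_dose =)`.
#' @export
generate_requests <- function(spec, formulary = fixture_formulary_f1()) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_requests
  n_noeq <- round(spec$frac_no_equivalence * n)
  n_border <- round(spec$frac_border * n)
  n_unsup <- round(spec$frac_unsupported * n)
  n_bt <- round(spec$frac_breakthrough * n)
  n_plain <- n - n_noeq - n_border - n_unsup - n_bt
  pairs <- .continuous_pairs(formulary)

  local_seed(spec$seed, {
    pick_pair <- function() pairs[sample.int(nrow(pairs), 1), ]
    # OME grid: 2.5 mg steps from 10 to 300, borders excluded so that only
    # deliberately border-tagged requests ever land on a border.
    omes <- setdiff(seq(10, 300, by = 2.5), .f1_borders)
    conv <- function(idx, ome, tgt_drug, tgt_route, border = FALSE) {
      dose <- ome / lookup_factor(formulary, idx$drug, idx$route)$ome_per_unit
      list(kind = "conversion",
           request = conversion_request(idx$drug, idx$route, dose,
                                        tgt_drug, tgt_route),
           border = border)
    }
    out <- list()
    for (i in seq_len(n_plain)) {
      idx <- pick_pair()
      # Half continuous targets, half fentanyl patch targets.
      if (stats::runif(1) < 0.5) {
        repeat {
          tgt <- pick_pair()
          if (!(tgt$drug == idx$drug && tgt$route == idx$route)) break
        }
        out[[length(out) + 1L]] <- conv(idx, sample(omes, 1), tgt$drug, tgt$route)
      } else {
        out[[length(out) + 1L]] <- conv(idx, sample(omes, 1),
                                        "fentanyl", "transdermal")
      }
    }
    for (i in seq_len(n_border)) {
      idx <- pick_pair()
      out[[length(out) + 1L]] <- conv(idx, sample(.f1_borders, 1),
                                      "fentanyl", "transdermal", border = TRUE)
    }
    for (i in seq_len(n_noeq)) {
      idx <- pick_pair()
      out[[length(out) + 1L]] <- conv(idx, sample(omes, 1),
                                      "buprenorphine", "oral")
    }
    for (i in seq_len(n_unsup)) {
      idx <- pick_pair()
      out[[length(out) + 1L]] <- conv(idx, sample(omes, 1),
                                      "methadone", "oral")
    }
    for (i in seq_len(n_bt)) {
      idx <- pick_pair()
      out[[length(out) + 1L]] <- list(
        kind = "breakthrough", drug = idx$drug, route = idx$route,
        daily_dose = sample(seq(15, 300, by = 15), 1))
    }
    out[sample.int(length(out))]
  })
}

#' Independent pairwise conversion oracle
#'
#' Brute-force re-derivation of what [convert()] should return, sharing no
#' code with the engine: the target dose is computed by the direct pairwise
#' ratio `factor_index / factor_target` looked up straight from the factor
#' table (no hub intermediate), and patch selection is re-implemented as a
#' linear scan with an explicit border-down comparison. Used as the ground
#' truth in engine equivalence tests and as the gold standard in audit
#' match-rate analyses.
#'
#' @inheritParams convert
#' @return A list with `status`, `practical_dose`, `exact_dose` (shaped like
#'   the fields of a `conversion_result` the audit layer compares on).
#' @export
pairwise_oracle <- function(formulary, request) {
  stopifnot(inherits(request, "conversion_request"))
  fa <- formulary$factors
  dr <- formulary$drug_routes
  unsupported <- function(d) any(dr$drug == d & !dr$supported)
  if (unsupported(request$index_drug) || unsupported(request$target_drug)) {
    return(list(status = "unsupported_drug",
                practical_dose = NULL, exact_dose = NULL))
  }
  fi <- fa$ome_per_unit[fa$drug == request$index_drug &
                          fa$route == request$index_route]
  if (length(fi) != 1) {
    return(list(status = "no_guideline_equivalence",
                practical_dose = NULL, exact_dose = NULL))
  }

  if (request$target_route == "transdermal") {
    tab <- formulary$patch_tables[[request$target_drug]]
    if (is.null(tab)) {
      return(list(status = "no_guideline_equivalence",
                  practical_dose = NULL, exact_dose = NULL))
    }
    ome_u <- round(request$index_dose * fi * 1e6)  # micro-mg, exact decimals
    strength <- NULL
    for (i in seq_len(nrow(tab))) {
      lo_u <- round(tab$ome_low[i] * 1e6)
      hi_u <- round(tab$ome_high[i] * 1e6)
      if (ome_u >= lo_u && ome_u <= hi_u) {
        strength <- tab$strength[i]   # first hit = lowest band: border-down
        break
      }
      if (ome_u < lo_u) {             # gap between bands: take the band below
        if (i > 1) strength <- tab$strength[i - 1]
        break
      }
    }
    if (is.null(strength) && ome_u > round(tab$ome_high[nrow(tab)] * 1e6)) {
      strength <- tab$strength[nrow(tab)]
    }
    return(list(status = "ok", practical_dose = strength, exact_dose = NULL))
  }

  ft <- fa$ome_per_unit[fa$drug == request$target_drug &
                          fa$route == request$target_route]
  if (length(ft) != 1) {
    return(list(status = "no_guideline_equivalence",
                practical_dose = NULL, exact_dose = NULL))
  }
  exact <- request$index_dose * fi / ft
  practical <- exact
  if (request$rounding == "practical") {
    inc <- formulary$practical_increments[[
      paste0(request$target_drug, ":", request$target_route)]]
    if (is.null(inc)) inc <- formulary$practical_increments[[request$target_route]]
    if (!is.null(inc)) {
      k <- floor(round(exact / inc, 9))
      practical <- if (k < 1) inc else k * inc
    }
  }
  list(status = "ok", practical_dose = practical, exact_dose = exact)
}

#' Build a gold standard for audit match-rate analysis
#'
#' Wraps [pairwise_oracle()] (conversions) and the breakthrough quotient
#' (breakthrough records) into the reference a [match_rate()] analysis
#' compares a log against, tagged with the formulary version it covers.
#'
#' @inheritParams lookup_factor
#' @return A `gold_standard` object.
#' @export
make_gold_standard <- function(formulary) {
  structure(
    list(
      formulary_version = formulary$version,
      predict = function(record) {
        if (identical(record$kind, "breakthrough")) {
          return(list(status = "ok",
                      practical_dose =
                        record$index_dose / formulary$breakthrough_divisor))
        }
        req <- conversion_request(record$index_drug, record$index_route,
                                  record$index_dose, record$target_drug,
                                  record$target_route)
        pairwise_oracle(formulary, req)
      }
    ),
    class = "gold_standard"
  )
}

#' Replay generated requests through the engine into an audit log
#'
#' Drives [convert()] / [breakthrough_dose()] over a generated request
#' sequence and appends one audit record per calculation, with deterministic
#' minute-spaced timestamps. `patch_tie = "up"` replays the sequence through
#' the historical round-up patch defect, which is how defect-era logs are
#' reconstructed for analysis.
#'
#' @inheritParams convert
#' @param requests Output of [generate_requests()].
#' @param start Timestamp of the first record (ISO-8601 UTC).
#' @return An `audit_log` with one record per request, in order.
#' @export
replay_requests <- function(formulary, requests, patch_tie = c("down", "up"),
                            start = "2017-05-01T08:00:00Z") {
  patch_tie <- match.arg(patch_tie)
  t0 <- as.POSIXct(start, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  log <- audit_log()
  for (i in seq_along(requests)) {
    el <- requests[[i]]
    ts <- .iso8601(t0 + 60 * (i - 1))
    rec <- if (el$kind == "breakthrough") {
      dose <- breakthrough_dose(formulary, el$drug, el$route, el$daily_dose)
      as_breakthrough_record(formulary, el$drug, el$route, el$daily_dose,
                             dose, timestamp = ts)
    } else {
      res <- convert(formulary, el$request, patch_tie = patch_tie)
      as_audit_record(el$request, res, timestamp = ts)
    }
    log <- append_record(log, rec)
  }
  log
}

#' Reconstruct a study-shaped audit log
#'
#' Builds a log with the composition of a defect-era prescribing audit:
#' `n_conversions` drug-to-drug conversions of which `n_no_equivalence`
#' involve a drug pair without guideline equivalence and `n_defect_border`
#' land exactly on a patch-band border, plus `n_breakthrough` breakthrough
#' calculations — all replayed through the engine with the round-up patch
#' defect enabled, so that exactly the border-exact conversions mismatch the
#' gold standard. About 62% of conversions carry the "cancer pain"
#' indication.
#'
#' @inheritParams lookup_factor
#' @param seed Integer seed.
#' @param n_conversions Total drug-to-drug conversions recorded.
#' @param n_no_equivalence How many of them lack guideline equivalence.
#' @param n_defect_border How many land exactly on a patch-band border.
#' @param n_breakthrough Breakthrough calculations recorded.
#' @param patch_tie Tie rule to replay with; `"up"` reproduces the
#'   defect-era log, `"down"` the corrected tool.
#' @return An `audit_log`.
#' @export
build_study_log <- function(formulary = fixture_formulary_f1(), seed = 1,
                            n_conversions = 210, n_no_equivalence = 18,
                            n_defect_border = 10, n_breakthrough = 76,
                            patch_tie = c("up", "down")) {
  patch_tie <- match.arg(patch_tie)
  n_total <- n_conversions + n_breakthrough
  spec <- fixture_spec(
    seed, n_total,
    frac_no_equivalence = n_no_equivalence / n_total,
    frac_border = n_defect_border / n_total,
    frac_unsupported = 0,
    frac_breakthrough = n_breakthrough / n_total
  )
  requests <- generate_requests(spec, formulary)
  # Tag ~62% of conversions as cancer pain, deterministically.
  requests <- local_seed(seed + 1L, {
    lapply(requests, function(el) {
      if (el$kind == "conversion") {
        el$request$indication <- if (stats::runif(1) < 0.62) "cancer pain"
          else "non-cancer pain"
      }
      el
    })
  })
  replay_requests(formulary, requests, patch_tie = patch_tie)
}
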