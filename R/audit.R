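# Audit layer: every calculation the engine performs can be captured as one
# append-only record containing conversion data and non-identifiable context
# only. The log replaces a remote capture database with a local JSON-lines
# file carrying the same data contract.

.audit_fields <- c(
  "record_id", "timestamp", "kind", "index_drug", "index_route", "index_dose",
  "target_drug", "target_route", "status", "ome", "exact_dose",
  "practical_dose", "warnings", "indication", "formulary_version"
)
.audit_kinds <- c("conversion", "breakthrough")
.audit_statuses <- c("ok", "no_guideline_equivalence", "unsupported_drug")

#' Closed list of indication categories
#'
#' The only free-form-looking field an audit record may carry is the
#' indication, and it is restricted to this closed category list so that no
#' patient-identifiable text can enter the log.
#'
#' @return Character vector of allowed indication categories.
#' @export
audit_indications <- function() {
  c("cancer pain", "non-cancer pain", "end of life care", "unspecified")
}

#' Create an empty audit log
#'
#' An in-memory append-only log. Records receive gapless, monotonically
#' increasing `record_id`s on append; there is no update or delete
#' operation. Persist with [write_audit_log()] and reload with
#' [read_audit_log()].
#'
#' @return An `audit_log` object of length 0.
#' @export
audit_log <- function() {
  structure(list(records = list()), class = "audit_log")
}

#' @export
length.audit_log <- function(x) length(x$records)

.iso8601 <- function(time = Sys.time()) {
  format(as.POSIXct(time, tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

.validate_record <- function(record) {
  bad <- character(0)
  extra <- setdiff(names(record), .audit_fields)
  if (length(extra)) {
    bad <- c(bad, paste0("forbidden field(s) — potential identifiable data: ",
                         paste(extra, collapse = ", ")))
  }
  required <- c("timestamp", "kind", "index_drug", "index_route", "index_dose",
                "status", "formulary_version")
  miss <- setdiff(required, names(record))
  if (length(miss)) {
    bad <- c(bad, paste0("missing required field(s): ",
                         paste(miss, collapse = ", ")))
  } else {
    if (!grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}Z$", record$timestamp)) {
      bad <- c(bad, "timestamp must be ISO-8601 UTC (YYYY-MM-DDThh:mm:ssZ)")
    }
    if (!record$kind %in% .audit_kinds) {
      bad <- c(bad, paste0("kind must be one of: ",
                           paste(.audit_kinds, collapse = ", ")))
    }
    if (!record$status %in% .audit_statuses) {
      bad <- c(bad, paste0("status must be one of: ",
                           paste(.audit_statuses, collapse = ", ")))
    }
    if (!is.numeric(record$index_dose) || record$index_dose <= 0) {
      bad <- c(bad, "index_dose must be a positive number")
    }
  }
  ind <- record$indication
  if (!is.null(ind) && !is.na(ind) && !ind %in% audit_indications()) {
    bad <- c(bad, paste0("indication must come from the closed category list (",
                         paste(audit_indications(), collapse = "; "), ")"))
  }
  if (!is.null(record$warnings) &&
      !all(is.na(record$warnings) | record$warnings %in% .warning_codes)) {
    bad <- c(bad, "warnings must be machine-stable codes")
  }
  bad
}

#' Build an audit record from a request and its result
#'
#' Captures the conversion data and nothing else: drug/route/dose endpoints,
#' result status, exact and practical doses, warning codes, the indication
#' category, and the formulary version the engine used. No patient
#' identifiable field exists in the schema.
#'
#' @param request The [conversion_request()] that was converted.
#' @param result The `conversion_result` returned by [convert()].
#' @param timestamp ISO-8601 UTC string; defaults to now.
#' @return A list ready for [append_record()] (its `record_id` is assigned on
#'   append).
#' @export
as_audit_record <- function(request, result, timestamp = .iso8601()) {
  list(
    timestamp = timestamp,
    kind = "conversion",
    index_drug = request$index_drug,
    index_route = request$index_route,
    index_dose = request$index_dose,
    target_drug = request$target_drug,
    target_route = request$target_route,
    status = result$status,
    ome = if (is.null(result$ome)) NA_real_ else result$ome,
    exact_dose = if (is.null(result$exact_target_dose)) NA_real_ else
      result$exact_target_dose,
    practical_dose = if (is.null(result$practical_target_dose)) NA_real_ else
      result$practical_target_dose,
    warnings = vapply(result$warnings, function(w) w$code, character(1)),
    indication = if (is.null(request$indication)) "unspecified" else
      request$indication,
    formulary_version = result$formulary_version
  )
}

#' Build an audit record for a breakthrough calculation
#'
#' @inheritParams lookup_factor
#' @param daily_dose Daily dose the breakthrough dose was computed from.
#' @param dose The computed breakthrough dose.
#' @param indication Indication category.
#' @param timestamp ISO-8601 UTC string; defaults to now.
#' @return A list ready for [append_record()].
#' @export
as_breakthrough_record <- function(formulary, drug, route, daily_dose, dose,
                                   indication = "unspecified",
                                   timestamp = .iso8601()) {
  list(
    timestamp = timestamp,
    kind = "breakthrough",
    index_drug = tolower(drug),
    index_route = route,
    index_dose = daily_dose,
    target_drug = NA_character_,
    target_route = NA_character_,
    status = "ok",
    ome = NA_real_,
    exact_dose = as.numeric(dose),
    practical_dose = as.numeric(dose),
    warnings = character(0),
    indication = indication,
    formulary_version = formulary$version
  )
}

#' Append one record to an audit log
#'
#' The log is append-only: the only mutation is adding exactly one record,
#' which receives the next gapless `record_id`. Records violating the schema
#' — above all any field outside the closed schema, where identifiable data
#' could hide — are rejected with an error naming the field.
#'
#' @param log An `audit_log`.
#' @param record A record from [as_audit_record()] or
#'   [as_breakthrough_record()].
#' @return The updated `audit_log`.
#' @export
append_record <- function(log, record) {
  stopifnot(inherits(log, "audit_log"))
  record$record_id <- NULL
  bad <- .validate_record(record)
  if (length(bad)) {
    stop("audit record rejected:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  }
  record <- c(list(record_id = length(log$records) + 1L), record)
  log$records[[length(log$records) + 1L]] <- record[.audit_fields]
  log
}

#' Write an audit log as JSON-lines
#'
#' One record per line, fields in fixed schema order. The schema ships at
#' `system.file("extdata", "audit-record-schema.json", package = "omeconvert")`.
#'
#' @param log An `audit_log`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audit_log <- function(log, path) {
  stopifnot(inherits(log, "audit_log"))
  lines <- vapply(log$records, function(r) {
    r$warnings <- I(r$warnings)  # keep a JSON array even for one code
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA,
                                  na = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines audit log
#'
#' Record ids are preserved as written; [summarize_usage()] reports (rather
#' than fails on) corrupt lines, so a damaged log still yields an audit.
#'
#' @param path Path to a JSON-lines log written by [write_audit_log()].
#' @return An `audit_log`.
#' @export
read_audit_log <- function(path) {
  if (!file.exists(path)) stop("audit log not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  log <- audit_log()
  log$records <- lapply(lines, function(l) {
    r <- tryCatch(jsonlite::fromJSON(l, simplifyVector = TRUE),
                  error = function(e) NULL)
    if (is.null(r)) return(structure(list(raw = l), class = "corrupt_record"))
    r$warnings <- as.character(unlist(r$warnings))
    for (k in c("ome", "exact_dose", "practical_dose")) {
      if (is.null(r[[k]])) r[[k]] <- NA_real_
    }
    for (k in c("target_drug", "target_route", "indication")) {
      if (is.null(r[[k]])) r[[k]] <- NA_character_
    }
    r[.audit_fields]
  })
  log
}

#' Export an audit log as CSV
#'
#' Fixed header order matching the record schema; warning codes joined with
#' `;`.
#'
#' @inheritParams write_audit_log
#' @return `path`, invisibly.
#' @export
export_audit_csv <- function(log, path) {
  stopifnot(inherits(log, "audit_log"))
  rows <- lapply(log$records, function(r) {
    if (inherits(r, "corrupt_record")) return(NULL)
    r$warnings <- paste(r$warnings, collapse = ";")
    as.data.frame(r, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(.audit_fields)), .audit_fields))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Summarise usage of a log: per-opioid index/target tallies
#'
#' Tallies drug-to-drug conversion records by index opioid (the drug switched
#' *from*) and target opioid (the drug switched *to*), counts breakthrough
#' calculations separately, and quarantines corrupt records by id instead of
#' failing. Both tally columns sum to the drug-to-drug record count by
#' construction (conservation), mirroring a usage table whose two columns
#' each sum to the number of switches.
#'
#' @param log An `audit_log`.
#' @return A `usage_summary`: `index_counts`, `target_counts` (named integer
#'   vectors), `total_conversions`, `total_breakthrough`,
#'   `quarantined_records` (record ids / line numbers), `formulary_versions`.
#' @export
summarize_usage <- function(log) {
  stopifnot(inherits(log, "audit_log"))
  index_counts <- integer(0)
  target_counts <- integer(0)
  n_conv <- 0L
  n_bt <- 0L
  quarantined <- integer(0)
  versions <- character(0)
  for (i in seq_along(log$records)) {
    r <- log$records[[i]]
    if (inherits(r, "corrupt_record") || length(.validate_record_lite(r))) {
      quarantined <- c(quarantined, i)
      next
    }
    versions <- union(versions, r$formulary_version)
    if (r$kind == "breakthrough") {
      n_bt <- n_bt + 1L
      next
    }
    n_conv <- n_conv + 1L
    index_counts[r$index_drug] <-
      (if (is.na(match(r$index_drug, names(index_counts)))) 0L
       else index_counts[[r$index_drug]]) + 1L
    tgt <- r$target_drug
    if (is.na(tgt)) tgt <- "(none)"
    target_counts[tgt] <-
      (if (is.na(match(tgt, names(target_counts)))) 0L
       else target_counts[[tgt]]) + 1L
  }
  structure(
    list(index_counts = if (length(index_counts))
           index_counts[order(names(index_counts))] else index_counts,
         target_counts = if (length(target_counts))
           target_counts[order(names(target_counts))] else target_counts,
         total_conversions = n_conv, total_breakthrough = n_bt,
         quarantined_records = quarantined,
         formulary_versions = versions),
    class = "usage_summary"
  )
}

# Cheap structural check used when tallying: a record missing its skeleton is
# quarantined, not fatal.
.validate_record_lite <- function(r) {
  required <- c("record_id", "kind", "index_drug", "status")
  miss <- setdiff(required, names(r))
  if (length(miss)) return(miss)
  if (!r$kind %in% .audit_kinds || !r$status %in% .audit_statuses) return("kind/status")
  character(0)
}

#' @export
print.usage_summary <- function(x, ...) {
  drugs <- sort(union(names(x$index_counts), names(x$target_counts)))
  cat("Opioid                As Index (n)  As Target (n)\n")
  for (d in drugs) {
    cat(sprintf("%-22s %12d %14d\n", d,
                if (d %in% names(x$index_counts)) x$index_counts[[d]] else 0L,
                if (d %in% names(x$target_counts)) x$target_counts[[d]] else 0L))
  }
  cat(sprintf("%-22s %12d %14d\n", "TOTAL",
              x$total_conversions, x$total_conversions))
  cat("breakthrough calculations:", x$total_breakthrough, "\n")
  if (length(x$quarantined_records)) {
    cat("quarantined records:",
        paste(x$quarantined_records, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export a usage summary as CSV
#'
#' Three columns (`Opioid`, `As Index Opioid (n)`, `As Target Opioid (n)`)
#' preceded by a `#`-prefixed metadata block (totals, breakthrough count,
#' formulary versions, quarantine count).
#'
#' @param summary A `usage_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_usage_csv <- function(summary, path) {
  drugs <- sort(union(names(summary$index_counts), names(summary$target_counts)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# total_conversions,", summary$total_conversions),
    paste0("# total_breakthrough,", summary$total_breakthrough),
    paste0("# quarantined,", length(summary$quarantined_records)),
    paste0("# formulary_versions,",
           paste(summary$formulary_versions, collapse = ";"))
  ), con)
  df <- data.frame(
    Opioid = drugs,
    `As Index Opioid (n)` = vapply(drugs, function(d)
      if (d %in% names(summary$index_counts)) summary$index_counts[[d]] else 0L,
      integer(1)),
    `As Target Opioid (n)` = vapply(drugs, function(d)
      if (d %in% names(summary$target_counts)) summary$target_counts[[d]] else 0L,
      integer(1)),
    check.names = FALSE
  )
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Compare a log against a gold standard and compute the match rate
#'
#' Reproduces the accuracy-audit procedure: records whose status is
#' `no_guideline_equivalence` are excluded from analysis (no gold-standard
#' value exists for them), each remaining record's final *practical* dose is
#' compared with the gold standard's, and the match rate is reported as a
#' percentage rounded half-up to one decimal. The comparison is on practical
#' doses because rounding, not ratio arithmetic, is where conversion tools
#' historically diverge from guideline tables.
#'
#' @param log An `audit_log`.
#' @param gold A gold standard from [make_gold_standard()], covering the same
#'   formulary version as the log (a mismatch is a hard error).
#' @return A `match_summary`: `total_records`, `excluded_no_equivalence`,
#'   `excluded_unsupported`, `analyzed`, `matched`, `mismatched_record_ids`,
#'   `match_rate` (percent, one decimal; `NA` when nothing was analyzable).
#' @export
match_rate <- function(log, gold) {
  stopifnot(inherits(log, "audit_log"), inherits(gold, "gold_standard"))
  total <- 0L
  excl_noeq <- 0L
  excl_unsup <- 0L
  analyzed <- 0L
  matched <- 0L
  mism <- integer(0)
  for (r in log$records) {
    if (inherits(r, "corrupt_record")) next
    total <- total + 1L
    if (r$formulary_version != gold$formulary_version) {
      stop("formulary version mismatch: log has `", r$formulary_version,
           "`, gold standard covers `", gold$formulary_version, "`",
           call. = FALSE)
    }
    if (r$status == "no_guideline_equivalence") {
      excl_noeq <- excl_noeq + 1L
      next
    }
    if (r$status == "unsupported_drug") {
      excl_unsup <- excl_unsup + 1L
      next
    }
    analyzed <- analyzed + 1L
    ref <- gold$predict(r)
    rec_absent <- is.na(r$practical_dose)
    ref_absent <- is.null(ref$practical_dose)
    # "no deliverable dose" (e.g. OME below the smallest patch) matches when
    # the gold standard reaches the same refusal
    same <- identical(ref$status, "ok") &&
      ((rec_absent && ref_absent) ||
         (!rec_absent && !ref_absent &&
            .dose_key(r$practical_dose) == .dose_key(ref$practical_dose)))
    if (same) matched <- matched + 1L else mism <- c(mism, r$record_id)
  }
  structure(
    list(total_records = total,
         excluded_no_equivalence = excl_noeq,
         excluded_unsupported = excl_unsup,
         analyzed = analyzed, matched = matched,
         mismatched_record_ids = mism,
         match_rate = if (analyzed == 0) NA_real_ else
           round_half_up(100 * matched / analyzed, 1)),
    class = "match_summary"
  )
}

#' Round half-up to a number of decimals
#'
#' Audit percentages are reported half-up (2.45 -> 2.5), not by the
#' round-half-even rule of [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(96.25, 1)  # 96.3
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' @export
print.match_summary <- function(x, ...) {
  cat("records:", x$total_records,
      "| excluded (no equivalence):", x$excluded_no_equivalence,
      "| excluded (unsupported):", x$excluded_unsupported, "\n")
  cat("analyzed:", x$analyzed, "| matched:", x$matched, "\n")
  cat("match rate:",
      if (is.na(x$match_rate)) "undefined (nothing analyzable)"
      else paste0(x$match_rate, "%"), "\n")
  invisible(x)
}
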