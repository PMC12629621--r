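# Controlled vocabularies shared across the package.

#' Charlson comorbidity vocabulary
#'
#' The 19 Charlson items (the 1987 index, with leukaemia and lymphoma listed
#' separately from other malignancies) plus the explicit code \code{"none"}.
#' Case records may only use these codes; anything else is a vocabulary
#' error, never silently dropped, because a dropped condition would corrupt
#' the comorbidity score downstream.
#'
#' @return Character vector of accepted comorbidity codes.
#' @export
charlson_vocabulary <- function() {
  c("myocardial_infarction", "congestive_heart_failure",
    "peripheral_vascular_disease", "cerebrovascular_disease", "dementia",
    "chronic_pulmonary_disease", "rheumatic_disease", "peptic_ulcer_disease",
    "mild_liver_disease", "diabetes_uncomplicated",
    "diabetes_with_complications", "hemiplegia", "renal_disease",
    "any_malignancy", "leukemia", "lymphoma",
    "moderate_severe_liver_disease", "metastatic_solid_tumor", "aids",
    "none")
}

dre_levels <- function() c("not_done", "normal", "abnormal")
risk_factor_levels <- function() {
  c("family_history_prostate_ca", "brca_carrier", "african_ancestry")
}
preference_levels <- function() c("requests_screening", "declines", "unstated")
psa_context_levels <- function() c("screening", "follow_up", "symptomatic")
category_levels <- function() {
  c("cat1_screen_recommended", "cat2_screen_not_recommended",
    "cat3_normal_followup", "cat4_elevated_psa", "cat5_other")
}

schema_error <- function(msg, field = NULL) {
  stop(errorCondition(msg, field = field,
                      class = c("psarag_schema_error", "psarag_error")))
}

vocab_error <- function(msg, accepted) {
  stop(errorCondition(
    paste0(msg, "\nAccepted codes: ", paste(accepted, collapse = ", ")),
    accepted = accepted,
    class = c("psarag_vocab_error", "psarag_error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}

#' Parse and validate a structured case record
#'
#' Converts a raw case record (a named list, typically read from JSON or
#' YAML) into a validated \code{case_scenario}. Optional fields default to
#' absent/\code{FALSE}/\code{"unstated"}; the PSA history is re-sorted
#' chronologically (oldest first, i.e. \code{months_ago} descending).
#' \code{free_text} is carried verbatim but never interpreted by the
#' deterministic core.
#'
#' @param record Named list with at least \code{case_id} and \code{age}.
#' @return An object of class \code{case_scenario}.
#' @examples
#' parse_case(list(case_id = "c1", age = 55))
#' @export
parse_case <- function(record) {
  if (!is.list(record)) schema_error("case record must be a mapping")
  if (is.null(record$case_id) || !is.character(record$case_id) ||
      length(record$case_id) != 1L || !nzchar(record$case_id)) {
    schema_error("case record requires a non-empty string 'case_id'", "case_id")
  }
  age <- record$age
  if (!is_scalar_number(age) || age != as.integer(age)) {
    schema_error("field 'age' must be an integer number of years", "age")
  }
  age <- as.integer(age)
  if (age < 18L || age > 120L) {
    schema_error(sprintf("field 'age' out of range [18, 120]: %d", age), "age")
  }

  comorbidities <- as.character(record$comorbidities %||% character())
  bad <- setdiff(comorbidities, charlson_vocabulary())
  if (length(bad)) {
    vocab_error(sprintf("unknown comorbidity code(s): %s",
                        paste(bad, collapse = ", ")),
                charlson_vocabulary())
  }
  comorbidities <- setdiff(unique(comorbidities), "none")

  flag <- function(name) {
    v <- record[[name]] %||% FALSE
    if (!is.logical(v) || length(v) != 1L || is.na(v)) {
      schema_error(sprintf("field '%s' must be a single logical", name), name)
    }
    v
  }

  dre <- as.character(record$dre %||% "not_done")
  if (length(dre) != 1L || !dre %in% dre_levels()) {
    schema_error(sprintf("field 'dre' must be one of: %s",
                         paste(dre_levels(), collapse = ", ")), "dre")
  }

  psa_history <- parse_psa_history(record$psa_history)

  risk_factors <- as.character(record$risk_factors %||% character())
  bad <- setdiff(risk_factors, risk_factor_levels())
  if (length(bad)) {
    vocab_error(sprintf("unknown risk factor(s): %s",
                        paste(bad, collapse = ", ")), risk_factor_levels())
  }

  preference <- as.character(record$preference %||% "unstated")
  if (length(preference) != 1L || !preference %in% preference_levels()) {
    schema_error("field 'preference' invalid", "preference")
  }

  category <- record$category
  if (!is.null(category)) {
    category <- as.character(category)
    if (length(category) != 1L || !category %in% category_levels()) {
      schema_error(sprintf("field 'category' must be one of: %s",
                           paste(category_levels(), collapse = ", ")),
                   "category")
    }
  }

  free_text <- record$free_text
  if (!is.null(free_text)) free_text <- as.character(free_text)[1L]

  structure(list(
    case_id = record$case_id,
    age = age,
    comorbidities = sort(comorbidities),
    luts = flag("luts"),
    hematuria = flag("hematuria"),
    active_uti = flag("active_uti"),
    dre = dre,
    psa_history = psa_history,
    risk_factors = sort(unique(risk_factors)),
    preference = preference,
    free_text = free_text,
    category = category
  ), class = "case_scenario")
}

parse_psa_history <- function(raw) {
  empty <- data.frame(value = numeric(), months_ago = integer(),
                      context = character(), stringsAsFactors = FALSE)
  if (is.null(raw) || length(raw) == 0L) return(empty)
  if (is.data.frame(raw)) raw <- lapply(seq_len(nrow(raw)), function(i) as.list(raw[i, ]))
  rows <- lapply(raw, function(r) {
    if (!is.list(r) || !is_scalar_number(r$value) || !is_scalar_number(r$months_ago)) {
      schema_error("each psa_history entry needs numeric 'value' and 'months_ago'",
                   "psa_history")
    }
    if (r$value < 0) schema_error("PSA value must be >= 0", "psa_history")
    if (r$months_ago < 0 || r$months_ago != as.integer(r$months_ago)) {
      schema_error("months_ago must be a non-negative integer", "psa_history")
    }
    ctx <- r$context
    if (!is.null(ctx) && !is.na(ctx)) {
      ctx <- as.character(ctx)
      if (!ctx %in% psa_context_levels()) {
        schema_error("psa_history context invalid", "psa_history")
      }
    } else ctx <- NA_character_
    data.frame(value = as.numeric(r$value),
               months_ago = as.integer(r$months_ago),
               context = ctx, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$months_ago)) {
    schema_error("at most one PSA reading per months_ago offset", "psa_history")
  }
  # oldest first
  out <- out[order(-out$months_ago), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Most recent PSA reading of a case
#'
#' @param case A \code{case_scenario}.
#' @return One-row data frame (the reading with the smallest
#'   \code{months_ago}) or \code{NULL} when the history is empty.
#' @export
latest_psa <- function(case) {
  h <- case$psa_history
  if (is.null(h) || nrow(h) == 0L) return(NULL)
  h[which.min(h$months_ago), , drop = FALSE]
}

#' Serialize a case scenario to canonical JSON
#'
#' Keys are emitted in sorted order so equal cases always serialize to the
#' same bytes; \code{parse_case(jsonlite::fromJSON(serialize_case(x)))}
#' round-trips.
#'
#' @param case A \code{case_scenario}.
#' @return A single JSON string.
#' @export
serialize_case <- function(case) {
  stopifnot(inherits(case, "case_scenario"))
  x <- unclass(case)
  x$psa_history <- if (nrow(case$psa_history)) {
    lapply(seq_len(nrow(case$psa_history)), function(i) {
      r <- case$psa_history[i, ]
      o <- list(months_ago = r$months_ago, value = r$value)
      if (!is.na(r$context)) o$context <- r$context
      o
    })
  } else NULL
  x <- x[!vapply(x, is.null, logical(1))]
  x <- x[order(names(x))]
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"))
}

#' Read a case record from disk
#'
#' Accepts \code{.json}, \code{.yaml} or \code{.yml} files conforming to the
#' case-record schema (see \code{inst/extdata/case_schema.json}).
#'
#' @param path File path.
#' @return A validated \code{case_scenario}.
#' @export
read_case <- function(path) {
  ext <- tolower(tools::file_ext(path))
  rec <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = FALSE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    schema_error(sprintf("unsupported case file extension: '%s'", ext)))
  parse_case(rec)
}

#' Write a case scenario as canonical JSON
#'
#' @param case A \code{case_scenario}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_case <- function(case, path) {
  writeLines(serialize_case(case), path)
  invisible(path)
}

#' @export
print.case_scenario <- function(x, ...) {
  cat(sprintf("<case %s> age %d", x$case_id, x$age))
  if (length(x$comorbidities)) {
    cat("; comorbidities:", paste(x$comorbidities, collapse = ", "))
  }
  lp <- latest_psa(x)
  if (!is.null(lp)) {
    cat(sprintf("; latest PSA %.1f ng/mL (%d mo ago)", lp$value, lp$months_ago))
  }
  if (x$dre != "not_done") cat("; DRE", x$dre)
  if (x$active_uti) cat("; active UTI")
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
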