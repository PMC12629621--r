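# Deterministic, config-driven encoding of the EAU and AUA PSA-testing
# rules, plus the reconciliation step that combines the two per-guideline
# answers into the final recommendation set.

#' Recommendation action vocabulary
#' @return Character vector of the recommendation actions.
#' @export
psa_actions <- function() {
  c("no_testing", "offer_psa_now", "routine_interval",
    "confirmatory_repeat_weeks", "refer_urology",
    "defer_treat_uti_then_repeat")
}

#' Load the guideline rule file
#'
#' @param path Optional path to a rule YAML; defaults to the packaged rule
#'   file (see \code{inst/extdata/guideline_rules.yaml}).
#' @return Named list with \code{eau} and \code{aua} parameter blocks.
#' @export
guideline_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "guideline_rules.yaml", package = "psarag")
  }
  cfg <- yaml::read_yaml(path)
  for (src in c("eau", "aua")) {
    if (is.null(cfg[[src]])) config_error(sprintf("rule file lacks '%s' block", src))
  }
  cfg
}

new_recommendation <- function(source, action, interval = NULL,
                               shared_decision = FALSE, rationale = character()) {
  stopifnot(action %in% psa_actions())
  if (action == "routine_interval") {
    stopifnot(is.numeric(interval), length(interval) == 2L,
              interval[1] <= interval[2])
    interval <- as.numeric(interval)
  } else {
    interval <- NULL
  }
  structure(list(source = source, action = action,
                 interval_months = interval,
                 shared_decision = isTRUE(shared_decision),
                 rationale = rationale),
            class = "psa_recommendation")
}

in_band <- function(age, rc) age >= rc$screening_age_min & age <= rc$screening_age_max

elevated_threshold <- function(rules, source) {
  rules[[tolower(source)]]$psa_elevated_threshold
}

# Count of readings at or above the guideline's elevation threshold; a
# repeat confirmation means at least two such readings.
n_elevated_readings <- function(case, thr) {
  sum(case$psa_history$value >= thr)
}

recommend_source <- function(case, gate, rules, source) {
  rc <- rules[[tolower(source)]]
  rid <- function(id) paste0(tolower(source), ".", id)
  shared <- if (isTRUE(rc$shared_decision_always)) TRUE
            else case$age >= (rc$shared_decision_age %||% Inf)

  if (!gate$eligible) {
    ids <- rid("gate_no_testing")
    lp <- latest_psa(case)
    if (!is.null(lp) && lp$value >= rc$psa_elevated_threshold) {
      ids <- c(ids, rid("comorbid_elevated_no_benefit"))
    }
    return(new_recommendation(source, "no_testing", rationale = ids))
  }

  lp <- latest_psa(case)
  base <- if (!is.null(lp)) {
    v <- lp$value
    thr <- rc$psa_elevated_threshold
    if (v >= thr) {
      if (v > rc$moderately_elevated_max) {
        new_recommendation(source, "refer_urology", shared_decision = shared,
                           rationale = rid("psa_over_10_refer"))
      } else if (n_elevated_readings(case, thr) >= 2L) {
        new_recommendation(source, "refer_urology", shared_decision = shared,
                           rationale = rid("confirmed_elevation_refer"))
      } else {
        new_recommendation(source, "confirmatory_repeat_weeks",
                           shared_decision = shared,
                           rationale = rid("moderately_elevated_confirm_repeat"))
      }
    } else if (in_band(case$age, rc)) {
      new_recommendation(source, "routine_interval",
                         interval = rc$routine_interval_months,
                         shared_decision = shared,
                         rationale = rid("routine_followup_interval"))
    } else if (case$age > rc$screening_age_max) {
      new_recommendation(source, "no_testing", shared_decision = shared,
                         rationale = rid("over_band_no_testing"))
    } else {
      new_recommendation(source, "no_testing", shared_decision = shared,
                         rationale = rid("below_band_no_testing"))
    }
  } else {
    if (in_band(case$age, rc)) {
      if (tolower(source) == "eau") {
        new_recommendation(source, "offer_psa_now", shared_decision = shared,
                           rationale = rid("offer_baseline_test"))
      } else {
        new_recommendation(source, "routine_interval",
                           interval = rc$routine_interval_months,
                           shared_decision = shared,
                           rationale = rid("routine_screening_interval"))
      }
    } else if (case$age < rc$screening_age_min &&
               length(case$risk_factors) > 0L &&
               case$age >= rc$early_risk_age_min) {
      new_recommendation(source, "offer_psa_now", shared_decision = shared,
                         rationale = rid("early_testing_risk_factors"))
    } else if (case$age < rc$screening_age_min) {
      new_recommendation(source, "no_testing", shared_decision = shared,
                         rationale = rid("below_band_no_testing"))
    } else {
      new_recommendation(source, "no_testing", shared_decision = shared,
                         rationale = rid("over_band_no_testing"))
    }
  }
  apply_special_rules(case, base, rules)
}

#' Per-guideline recommendation (EAU)
#'
#' Applies the codified EAU rules: gate-refused cases get no testing; a
#' latest PSA below 3.0 ng/mL in an eligible man in the screening band gets
#' routine 2-year follow-up; a moderately elevated PSA (3.0-10 ng/mL)
#' without prior confirmation gets a confirmatory repeat after a few weeks;
#' a confirmed elevation or a PSA above 10 ng/mL gets urology referral.
#' Special-case overrides (UTI, abnormal DRE) take precedence over the
#' PSA/age rules.
#'
#' @param case A \code{case_scenario}.
#' @param gate Its \code{gate_decision}.
#' @param rules Rule config from \code{\link{guideline_rules}}.
#' @return A \code{psa_recommendation} with the fired rule identifiers in
#'   \code{$rationale}.
#' @export
recommend_eau <- function(case, gate, rules = guideline_rules()) {
  recommend_source(case, gate, rules, "EAU")
}

#' Per-guideline recommendation (AUA)
#'
#' Mirrors \code{\link{recommend_eau}} with AUA parameters: an eligible man
#' aged 50-69 with unremarkable history gets regular screening every 2 to 4
#' years with shared decision-making; below the band without elevated risk,
#' no testing (still flagged for shared decision-making).
#'
#' @inheritParams recommend_eau
#' @return A \code{psa_recommendation}.
#' @export
recommend_aua <- function(case, gate, rules = guideline_rules()) {
  recommend_source(case, gate, rules, "AUA")
}

#' Special-case overrides
#'
#' Applied on top of the age/PSA base recommendation: an elevated PSA with
#' an active urinary tract infection is likely spurious, so testing is
#' deferred until after treatment with a repeat PSA; an abnormal digital
#' rectal examination warrants urology referral even when the PSA is
#' normal. Gate-refused recommendations pass through unchanged (no benefit
#' from further testing).
#'
#' @param case A \code{case_scenario}.
#' @param base The base \code{psa_recommendation}.
#' @param rules Rule config (used for the per-guideline elevation
#'   threshold).
#' @return A \code{psa_recommendation}.
#' @export
apply_special_rules <- function(case, base, rules = guideline_rules()) {
  src <- base$source
  rid <- function(id) paste0(tolower(src), ".", id)
  if (any(grepl("\\.gate_no_testing$", base$rationale))) return(base)
  lp <- latest_psa(case)
  thr <- elevated_threshold(rules, src)
  if (case$active_uti && !is.null(lp) && lp$value >= thr) {
    return(new_recommendation(src, "defer_treat_uti_then_repeat",
                              shared_decision = base$shared_decision,
                              rationale = rid("uti_spurious_defer_repeat")))
  }
  if (case$dre == "abnormal") {
    return(new_recommendation(src, "refer_urology",
                              shared_decision = base$shared_decision,
                              rationale = rid("abnormal_dre_refer")))
  }
  base
}

intervals_overlap <- function(a, b) {
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  max(a[1], b[1]) <= min(a[2], b[2])
}

#' Reconcile the two per-guideline answers
#'
#' Concordant pairs (same action, overlapping intervals when applicable)
#' merge into a single final recommendation carrying the intersection of
#' the intervals; discordant pairs are both retained, each labelled by
#' source, mirroring how differing guideline recommendations are presented
#' side by side.
#'
#' @param eau,aua \code{psa_recommendation}s for the same case.
#' @return Object of class \code{dual_recommendation}: \code{eau},
#'   \code{aua}, \code{concordant} and \code{final_actions} (length 1 when
#'   concordant, 2 otherwise).
#' @export
reconcile <- function(eau, aua) {
  stopifnot(inherits(eau, "psa_recommendation"),
            inherits(aua, "psa_recommendation"))
  concordant <- identical(eau$action, aua$action) &&
    intervals_overlap(eau$interval_months, aua$interval_months)
  final <- if (concordant) {
    merged_interval <- if (!is.null(eau$interval_months)) {
      c(max(eau$interval_months[1], aua$interval_months[1]),
        min(eau$interval_months[2], aua$interval_months[2]))
    } else NULL
    list(new_recommendation("EAU+AUA", eau$action, interval = merged_interval,
                            shared_decision = eau$shared_decision || aua$shared_decision,
                            rationale = union(eau$rationale, aua$rationale)))
  } else {
    list(eau, aua)
  }
  structure(list(eau = eau, aua = aua, concordant = concordant,
                 final_actions = final),
            class = "dual_recommendation")
}

#' End-to-end dual recommendation for one case
#'
#' Convenience wrapper: CCI score, gate, both per-guideline rule sets, then
#' reconciliation.
#'
#' @param case A \code{case_scenario}.
#' @param rules Rule config.
#' @param gate_cfg A \code{\link{gate_config}}.
#' @param weights Charlson weight table.
#' @return A \code{dual_recommendation}.
#' @export
recommend_dual <- function(case, rules = guideline_rules(),
                           gate_cfg = gate_config(),
                           weights = charlson_weights()) {
  cci <- cci_score(case, weights)
  gate <- screening_gate(case, cci, gate_cfg)
  reconcile(recommend_eau(case, gate, rules), recommend_aua(case, gate, rules))
}

recommendation_to_list <- function(rec) {
  list(source = rec$source, action = rec$action,
       interval_months = rec$interval_months,
       shared_decision = rec$shared_decision,
       rationale = as.list(rec$rationale))
}

#' Serialize a dual recommendation to stable JSON
#' @param dual A \code{dual_recommendation}.
#' @return A single JSON string (hash-stable across runs).
#' @export
serialize_dual <- function(dual) {
  x <- list(concordant = dual$concordant,
            eau = recommendation_to_list(dual$eau),
            aua = recommendation_to_list(dual$aua),
            final_actions = lapply(dual$final_actions, recommendation_to_list))
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"))
}

#' @export
print.psa_recommendation <- function(x, ...) {
  iv <- if (!is.null(x$interval_months)) {
    sprintf(" [%g-%g mo]", x$interval_months[1], x$interval_months[2])
  } else ""
  cat(sprintf("[%s] %s%s%s  (%s)\n", x$source, x$action, iv,
              if (x$shared_decision) " +shared-decision" else "",
              paste(x$rationale, collapse = ", ")))
  invisible(x)
}

#' @export
print.dual_recommendation <- function(x, ...) {
  cat(if (x$concordant) "Concordant recommendation:\n" else
        "Discordant recommendations (both presented):\n")
  for (r in x$final_actions) print(r)
  invisible(x)
}
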