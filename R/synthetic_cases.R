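# Seeded generator of gold-labelled case cohorts reproducing the study's
# five-category case mix, so every pipeline stage is testable without the
# unpublished scenario set. Gold labels are derived by running the rule
# engine on each generated case (self-consistent by construction);
# imperfect raters are simulated separately via degrade_ratings() or the
# scripted backend.

generation_error <- function(msg) {
  stop(errorCondition(msg, class = c("psarag_generation_error", "psarag_error")))
}

#' Cohort configuration
#'
#' Defaults reproduce the study's case mix: 44 cases split
#' 11/9/9/8/7 over the five categories, i.e. 20 screening (categories 1-2)
#' and 24 follow-up (categories 3-5) cases.
#'
#' @param counts Named or positional integer vector of per-category case
#'   counts (cat1..cat5).
#' @param seed Integer seed; all randomness in the generator flows from it
#'   (one \code{set.seed} call, categories generated in fixed order).
#' @param gate_cfg Gate configuration used both to steer generation and to
#'   derive gold labels.
#' @param rules,weights Engine configuration for gold-label derivation.
#' @return A \code{cohort_config}.
#' @export
cohort_config <- function(counts = c(11L, 9L, 9L, 8L, 7L), seed = 1L,
                          gate_cfg = gate_config(),
                          rules = guideline_rules(),
                          weights = charlson_weights()) {
  stopifnot(length(counts) == 5L, all(counts >= 0L))
  structure(list(counts = as.integer(counts), seed = as.integer(seed),
                 gate_cfg = gate_cfg, rules = rules, weights = weights),
            class = "cohort_config")
}

mild_conditions <- function() {
  c("diabetes_uncomplicated", "chronic_pulmonary_disease",
    "peptic_ulcer_disease", "mild_liver_disease", "myocardial_infarction")
}

heavy_condition_sets <- function() {
  list(c("metastatic_solid_tumor"),
       c("moderate_severe_liver_disease", "renal_disease",
         "congestive_heart_failure"),
       c("aids"),
       c("metastatic_solid_tumor", "chronic_pulmonary_disease"))
}

sample1 <- function(x) x[sample.int(length(x), 1L)]

free_text_template <- function(case) {
  lp <- latest_psa(case)
  paste0("A ", case$age, "-year-old man attends the outpatient clinic",
         if (length(case$comorbidities))
           paste0(" with a history of ",
                  paste(gsub("_", " ", case$comorbidities), collapse = ", ")),
         if (!is.null(lp))
           sprintf("; most recent PSA %.1f ng/mL (%d months ago)",
                   lp$value, lp$months_ago),
         if (case$active_uti) "; currently being treated for a urinary tract infection",
         if (case$dre == "abnormal") "; digital rectal examination is abnormal",
         ".")
}

build_case <- function(case_id, category, i, cfg) {
  rec <- list(case_id = case_id, category = category)
  if (category == "cat1_screen_recommended") {
    if (i %% 4L == 0L) {
      rec$age <- sample1(45:49)
      rec$risk_factors <- list(sample1(risk_factor_levels()))
    } else {
      rec$age <- sample1(50:69)
      if (stats::runif(1) < 0.4) rec$comorbidities <- list(sample1(mild_conditions()))
    }
    rec$dre <- sample1(c("not_done", "normal"))
    rec$preference <- sample1(c("requests_screening", "unstated"))
  } else if (category == "cat2_screen_not_recommended") {
    if (i %% 2L == 1L) {
      rec$age <- sample1(73:85)  # age gate
      if (stats::runif(1) < 0.5) rec$comorbidities <- list(sample1(mild_conditions()))
    } else {
      rec$age <- sample1(55:72)  # life-expectancy gate
      rec$comorbidities <- as.list(heavy_condition_sets()[[sample.int(4, 1)]])
    }
  } else if (category == "cat3_normal_followup") {
    rec$age <- sample1(50:69)
    last_mo <- sample1(0:3)
    hist <- list(list(value = round(stats::runif(1, 0.5, 2.8), 1),
                      months_ago = last_mo, context = "follow_up"))
    if (i %% 2L == 0L) {
      hist <- c(hist, list(list(value = round(stats::runif(1, 0.5, 2.8), 1),
                                months_ago = last_mo + 24L)))
    }
    rec$psa_history <- hist
    if (stats::runif(1) < 0.3) rec$comorbidities <- list(sample1(mild_conditions()))
  } else if (category == "cat4_elevated_psa") {
    rec$age <- sample1(50:69)
    variant <- i %% 4L
    rec$psa_history <- if (variant %in% c(0L, 1L)) {
      list(list(value = round(stats::runif(1, 3.2, 9.5), 1), months_ago = 0L))
    } else if (variant == 2L) {
      list(list(value = round(stats::runif(1, 4.5, 8.0), 1), months_ago = 2L),
           list(value = round(stats::runif(1, 4.5, 8.0), 1), months_ago = 0L))
    } else {
      list(list(value = round(stats::runif(1, 10.5, 25.0), 1), months_ago = 0L))
    }
  } else {  # cat5_other
    variant <- i %% 3L
    if (variant == 1L) {        # spurious elevation during a UTI
      rec$age <- sample1(50:69)
      rec$active_uti <- TRUE
      rec$psa_history <- list(list(value = round(stats::runif(1, 4.5, 9.0), 1),
                                   months_ago = 0L, context = "symptomatic"))
    } else if (variant == 2L) { # elevated PSA, significant comorbidity
      if (i %% 2L == 0L) {
        rec$age <- sample1(73:84)
      } else {
        rec$age <- sample1(60:72)
        rec$comorbidities <- as.list(heavy_condition_sets()[[sample.int(4, 1)]])
      }
      rec$psa_history <- list(list(value = round(stats::runif(1, 4.5, 12.0), 1),
                                   months_ago = 0L))
    } else {                    # abnormal DRE with a normal PSA
      rec$age <- sample1(50:69)
      rec$dre <- "abnormal"
      rec$psa_history <- list(list(value = round(stats::runif(1, 0.5, 2.4), 1),
                                   months_ago = 0L))
    }
  }
  case <- parse_case(rec)
  case$free_text <- free_text_template(case)
  case
}

category_predicate <- function(category, case, gate, dual, cfg) {
  actions <- vapply(dual$final_actions, `[[`, character(1), "action")
  lp <- latest_psa(case)
  switch(category,
    cat1_screen_recommended =
      gate$eligible && any(actions %in% c("offer_psa_now", "routine_interval")),
    cat2_screen_not_recommended = !gate$eligible && is.null(lp),
    cat3_normal_followup =
      gate$eligible && !is.null(lp) && lp$value < 3.0 &&
        "routine_interval" %in% actions,
    cat4_elevated_psa = gate$eligible && !is.null(lp) && lp$value >= 3.0,
    cat5_other = {
      if (case$active_uti) "defer_treat_uti_then_repeat" %in% actions
      else if (case$dre == "abnormal") "refer_urology" %in% actions
      else !gate$eligible && !is.null(lp) && lp$value >= 3.0
    })
}

#' Generate a gold-labelled synthetic cohort
#'
#' Each case is sampled to satisfy its category's defining constraints
#' (category 1: eligible profile warranting screening; 2: refused by the
#' age or life-expectancy gate; 3: normal PSA on follow-up; 4: elevated
#' PSA, unconfirmed/confirmed/above 10 ng/mL; 5: UTI-spurious elevation,
#' comorbid elevation, or abnormal DRE with normal PSA) and its gold label
#' is derived by running the rule engine on the case. Same seed, same
#' cohort, bit for bit.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param max_retries Bounded retries per case before a generation error.
#' @return List of elements \code{list(case = case_scenario,
#'   gold = gold_label)}, of length \code{sum(config$counts)}.
#' @export
generate_cohort <- function(config = cohort_config(), max_retries = 50L) {
  set.seed(config$seed)
  out <- list()
  idx <- 0L
  for (ci in seq_along(category_levels())) {
    category <- category_levels()[ci]
    for (i in seq_len(config$counts[ci])) {
      idx <- idx + 1L
      case_id <- sprintf("sim%03d", idx)
      ok <- FALSE
      for (attempt in seq_len(max_retries)) {
        case <- build_case(case_id, category, i, config)
        cci <- cci_score(case, config$weights)
        gate <- screening_gate(case, cci, config$gate_cfg)
        dual <- reconcile(recommend_eau(case, gate, config$rules),
                          recommend_aua(case, gate, config$rules))
        if (isTRUE(category_predicate(category, case, gate, dual, config))) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        generation_error(sprintf(
          "could not satisfy constraints of %s for case %d after %d retries (is the gate disabled?)",
          category, idx, max_retries))
      }
      out[[idx]] <- list(case = case, gold = gold_label(case_id, dual, category))
    }
  }
  out
}

#' Simulate imperfect raters over a cohort
#'
#' Produces graded ratings whose expected per-category error-subtype
#' frequencies equal the given profile, for exercising the aggregation,
#' agreement and comparison statistics at configurable noise levels.
#'
#' @param cohort Output of \code{\link{generate_cohort}}.
#' @param error_profile Named list: per category, a named numeric vector of
#'   rates over error subtypes (each in \eqn{[0, 1]}, summing to at most
#'   1); omitted categories are error-free.
#' @param n_raters Number of simulated raters. Default 5.
#' @param seed RNG seed.
#' @param arm Arm label stamped on the ratings.
#' @return Graded-rating data frame (cohort size times \code{n_raters}
#'   rows).
#' @export
degrade_ratings <- function(cohort, error_profile = list(), n_raters = 5L,
                            seed = 1L, arm = "sim") {
  for (cat in names(error_profile)) {
    rates <- unlist(error_profile[[cat]])
    if (length(bad <- setdiff(names(rates), error_levels()[-1]))) {
      domain_error(paste("unknown error subtype in profile:", bad[1]))
    }
    if (any(rates < 0) || any(rates > 1) || sum(rates) > 1) {
      domain_error("error rates must lie in [0, 1] and sum to at most 1")
    }
  }
  set.seed(seed)
  rows <- list()
  for (entry in cohort) {
    cat <- entry$gold$category
    rates <- unlist(error_profile[[cat]]) %||% numeric()
    for (r in seq_len(n_raters)) {
      err <- if (length(rates)) {
        sample(c(names(rates), "none"), 1L,
               prob = c(rates, 1 - sum(rates)))
      } else "none"
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = entry$gold$case_id, arm = arm,
        rater_id = paste0("r", r), category = cat,
        correct = err == "none", error = err, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a cohort to disk
#'
#' One canonical-JSON case file per case plus a gold-label CSV.
#'
#' @param cohort Output of \code{\link{generate_cohort}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gold_rows <- lapply(cohort, function(entry) {
    write_case(entry$case, file.path(dir, paste0(entry$case$case_id, ".json")))
    do.call(rbind, lapply(entry$gold$acceptable, function(a) {
      data.frame(case_id = entry$gold$case_id, category = entry$gold$category,
                 source = a$source, action = a$action,
                 interval_lo = if (is.null(a$interval_months)) NA_real_ else a$interval_months[1],
                 interval_hi = if (is.null(a$interval_months)) NA_real_ else a$interval_months[2],
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.csv(do.call(rbind, gold_rows),
                   file.path(dir, "gold_labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a gold-label CSV back into gold labels
#' @param path Path to \code{gold_labels.csv}.
#' @return Named list of \code{gold_label}s keyed by case id.
#' @export
read_gold_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (cid in unique(df$case_id)) {
    d <- df[df$case_id == cid, , drop = FALSE]
    acceptable <- lapply(seq_len(nrow(d)), function(i) {
      iv <- if (is.na(d$interval_lo[i])) NULL else c(d$interval_lo[i], d$interval_hi[i])
      list(source = d$source[i], action = d$action[i], interval_months = iv)
    })
    out[[cid]] <- structure(list(case_id = cid, acceptable = acceptable,
                                 category = d$category[1]),
                            class = "gold_label")
  }
  out
}
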