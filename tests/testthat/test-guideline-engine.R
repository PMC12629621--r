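eligible_gate <- function(case) screening_gate(case, cci_score(case))

test_that("a 55-year-old with PSA 2.8 gets 2-year routine follow-up, never a repeat", {
  wc <- worked_case()
  eau <- recommend_eau(wc, eligible_gate(wc))
  expect_identical(eau$action, "routine_interval")
  expect_equal(eau$interval_months, c(24, 24))
  expect_false(identical(eau$action, "confirmatory_repeat_weeks"))

  aua <- recommend_aua(wc, eligible_gate(wc))
  expect_identical(aua$action, "routine_interval")
  expect_equal(aua$interval_months, c(24, 48))

  dual <- reconcile(eau, aua)
  expect_true(dual$concordant)
  expect_length(dual$final_actions, 1)
  expect_equal(dual$final_actions[[1]]$interval_months, c(24, 24))
})

test_that("a moderately elevated unconfirmed PSA triggers a confirmatory repeat", {
  c42 <- make_case(age = 60, psa = 4.2)
  g <- eligible_gate(c42)
  expect_identical(recommend_eau(c42, g)$action, "confirmatory_repeat_weeks")
  expect_identical(recommend_aua(c42, g)$action, "confirmatory_repeat_weeks")

  confirmed <- make_case(age = 60, psa = c(4.5, 4.8), months_ago = c(2, 0))
  expect_identical(recommend_eau(confirmed, eligible_gate(confirmed))$action,
                   "refer_urology")
  high <- make_case(age = 60, psa = 14)
  expect_identical(recommend_eau(high, eligible_gate(high))$action,
                   "refer_urology")
})

test_that("screening offers follow the age bands and risk-factor extensions", {
  first <- make_case(age = 55)
  g <- eligible_gate(first)
  expect_identical(recommend_eau(first, g)$action, "offer_psa_now")
  aua <- recommend_aua(first, g)
  expect_identical(aua$action, "routine_interval")
  expect_true(aua$shared_decision)

  young <- make_case(age = 42)
  ya <- recommend_aua(young, eligible_gate(young))
  expect_identical(ya$action, "no_testing")
  expect_true(ya$shared_decision)

  risk <- make_case(age = 46, risk_factors = "family_history_prostate_ca")
  expect_identical(recommend_eau(risk, eligible_gate(risk))$action,
                   "offer_psa_now")
})

test_that("gate refusal dominates both guidelines", {
  old <- make_case(age = 75, psa = 8)
  g <- eligible_gate(old)
  expect_false(g$eligible)
  for (rec in list(recommend_eau(old, g), recommend_aua(old, g))) {
    expect_identical(rec$action, "no_testing")
  }
})

test_that("special rules override the PSA/age base recommendation", {
  uti <- make_case(age = 60, psa = 8, active_uti = TRUE)
  g <- eligible_gate(uti)
  expect_identical(recommend_eau(uti, g)$action, "defer_treat_uti_then_repeat")
  expect_identical(recommend_aua(uti, g)$action, "defer_treat_uti_then_repeat")

  dre <- make_case(age = 60, psa = 1.2, dre = "abnormal")
  expect_identical(recommend_eau(dre, eligible_gate(dre))$action,
                   "refer_urology")

  plain <- worked_case()
  base <- recommend_eau(plain, eligible_gate(plain))
  expect_identical(apply_special_rules(plain, base), base)
})

test_that("discordant guideline answers are both presented", {
  # eligible 71-year-old: inside the gate but above both screening bands
  c71 <- make_case(age = 71)
  g <- eligible_gate(c71)
  eau <- recommend_eau(c71, g)
  aua <- recommend_aua(c71, g)
  dual <- reconcile(eau, aua)
  expect_identical(dual$eau$action, dual$aua$action)  # both no_testing here

  mixed <- reconcile(
    recommend_eau(make_case(age = 55), g),   # offer_psa_now
    recommend_aua(make_case(age = 55), g))   # routine_interval
  expect_false(mixed$concordant)
  expect_length(mixed$final_actions, 2)
  expect_setequal(vapply(mixed$final_actions, `[[`, "", "source"),
                  c("EAU", "AUA"))
})

test_that("the engine is deterministic and closed over the action vocabulary", {
  cohort <- generate_cohort(cohort_config(seed = 5))
  for (entry in cohort) {
    d1 <- dual_for(entry$case)
    d2 <- dual_for(entry$case)
    expect_identical(serialize_dual(d1), serialize_dual(d2))
    for (rec in list(d1$eau, d1$aua)) {
      expect_true(rec$action %in% psa_actions())
      # interval present iff routine; rationale non-empty off no_testing
      expect_identical(!is.null(rec$interval_months),
                       rec$action == "routine_interval")
      if (rec$action != "no_testing") expect_gt(length(rec$rationale), 0)
    }
    expect_length(d1$final_actions, if (d1$concordant) 1L else 2L)
  }
})
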