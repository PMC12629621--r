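screen_gold <- function() {
  gold_label("g1", dual_for(make_case("g1", age = 55)), "cat1_screen_recommended")
}

eligible_gate_for <- function(age) {
  case <- make_case(age = age)
  screening_gate(case, cci_score(case))
}

make_routine_dual <- function(interval) {
  case <- make_case(age = 55, psa = 1.5)
  g <- eligible_gate_for(55)
  d <- reconcile(recommend_eau(case, g), recommend_aua(case, g))
  d$final_actions[[1]]$interval_months <- interval
  d$eau$interval_months <- interval
  d$aua$interval_months <- interval
  d
}

test_that("grading implements the either-guideline rule and the four subtypes", {
  gold <- screen_gold()  # EAU offer_psa_now, AUA routine [24,48]

  # response matching only one guideline is still correct
  one_sided <- reconcile(
    recommend_eau(make_case(age = 55), eligible_gate_for(55)),
    recommend_eau(make_case(age = 55), eligible_gate_for(55)))
  expect_true(grade(one_sided, gold)$correct)

  # no test offered although screening was recommended
  refusal <- dual_for(make_case(age = 55), gate_config(age_limit = 40))
  g <- grade(refusal, gold)
  expect_false(g$correct)
  expect_identical(g$error, "missed_failed_to_offer")

  # a 6-month interval against an acceptable [24,48] window is too short
  short <- make_routine_dual(c(6, 6))
  routine_gold <- gold_label("g2", make_routine_dual(c(24, 48)), "cat3_normal_followup")
  g2 <- grade(short, routine_gold)
  expect_identical(g2$error, "unnecessary_short_interval")

  long <- make_routine_dual(c(96, 120))
  expect_identical(grade(long, routine_gold)$error, "missed_long_interval")

  # a test offered when the gold is no testing at all
  no_test_gold <- gold_label("g3", dual_for(make_case(age = 75)), "cat2_screen_not_recommended")
  expect_identical(grade(make_routine_dual(c(24, 24)), no_test_gold)$error,
                   "unnecessary_did_not_require")
  expect_error(grade(make_routine_dual(c(24, 24)), NULL),
               class = "psarag_lookup_error")
})

test_that("every wrong action pair maps to exactly one error subtype", {
  golds <- list(
    gold_label("a", dual_for(make_case("a", age = 55)), "cat1_screen_recommended"),
    gold_label("b", dual_for(make_case("b", age = 75)), "cat2_screen_not_recommended"),
    gold_label("c", dual_for(make_case("c", age = 55, psa = 1.5)), "cat3_normal_followup"),
    gold_label("d", dual_for(make_case("d", age = 60, psa = 5)), "cat4_elevated_psa"),
    gold_label("e", dual_for(make_case("e", age = 60, psa = 1.0, dre = "abnormal")), "cat5_other"))
  g55 <- eligible_gate_for(55)
  presented <- list(
    no_testing = dual_for(make_case(age = 30)),
    offer = reconcile(recommend_eau(make_case(age = 55), g55),
                      recommend_eau(make_case(age = 55), g55)),
    routine = make_routine_dual(c(24, 48)),
    confirm = dual_for(make_case(age = 60, psa = 5)),
    refer = dual_for(make_case(age = 60, psa = 15)),
    defer = dual_for(make_case(age = 60, psa = 8, active_uti = TRUE)))
  for (gold in golds) {
    for (p in presented) {
      g <- grade(p, gold)
      expect_true(g$error %in% c("none", "unnecessary_short_interval",
                                 "unnecessary_did_not_require",
                                 "missed_long_interval",
                                 "missed_failed_to_offer"))
      expect_identical(g$correct, g$error == "none")
    }
  }
})

test_that("the reconstructed fixture reproduces the published marginals", {
  rt <- load_table1_fixture()
  expect_equal(nrow(rt), 3 * 220)

  llm <- rt[rt$arm == "llm", ]
  cat1 <- llm[llm$category == "cat1_screen_recommended", ]
  expect_equal(sum(cat1$error == "missed_failed_to_offer"), 5)
  cat3 <- llm[llm$category == "cat3_normal_followup", ]
  expect_equal(sum(cat3$error == "unnecessary_short_interval"), 5)
  expect_equal(sum(llm$error != "none"), 10)

  rep <- aggregate_ratings(rt)
  overall <- function(arm) rep[rep$arm == arm & rep$category == "overall", ]
  expect_equal(overall("llm")$accuracy_pct, 100 * 210 / 220, tolerance = 1e-9)
  expect_equal(overall("human_closed")$accuracy_pct, 100 * 137 / 220, tolerance = 1e-9)
  expect_equal(overall("human_open")$accuracy_pct, 100 * 163 / 220, tolerance = 1e-9)
  expect_equal(overall("human_closed")$total_errors, 83)

  # pooled screening/follow-up denominators and the headline pooled rates
  hc <- rep[rep$arm == "human_closed", ]
  expect_equal(hc$n[hc$category == "screening"], 100)
  expect_equal(hc$n[hc$category == "follow_up"], 120)
  expect_equal(hc$unnecessary_subtotal[hc$category == "follow_up"], 29)
  expect_equal(hc$missed_subtotal[hc$category == "screening"], 16)

  # conservation: subtypes sum to subtotals, subtotals to totals
  expect_equal(rep$unnecessary_short_interval + rep$unnecessary_did_not_require,
               rep$unnecessary_subtotal)
  expect_equal(rep$unnecessary_subtotal + rep$missed_subtotal, rep$total_errors)
  nz <- rep$n > 0
  expect_equal(rep$accuracy_pct[nz] + 100 * rep$total_errors[nz] / rep$n[nz],
               rep(100, sum(nz)))
})

test_that("empty categories aggregate to zero rows without division errors", {
  r <- data.frame(case_id = "x", arm = "a", rater_id = "r1",
                  category = "cat1_screen_recommended", correct = TRUE,
                  error = "none", stringsAsFactors = FALSE)
  rep <- aggregate_ratings(r)
  empty <- rep[rep$category == "cat5_other", ]
  expect_equal(empty$n, 0)
  expect_equal(empty$total_errors, 0)
  expect_true(is.na(empty$accuracy_pct))
})

test_that("Fleiss kappa matches the direct formula and its edge cases", {
  # unanimous per item with both categories present pools to kappa = 1
  m <- matrix("correct", 44, 5)
  m[1:2, ] <- "incorrect"
  expect_equal(fleiss_kappa(m), 1)

  # 2 items x 2 raters, one unanimous, one split: direct formula gives -1/3
  m2 <- matrix(c("c", "c", "c", "i"), 2, 2, byrow = TRUE)
  expect_equal(fleiss_kappa(m2), -1 / 3, tolerance = 1e-12)

  expect_error(fleiss_kappa(matrix("c", 5, 3)),
               class = "psarag_undefined_agreement")

  set.seed(99)
  for (i in 1:20) {
    r <- matrix(sample(c("a", "b", "c"), 30 * 4, replace = TRUE), 30, 4)
    k <- tryCatch(fleiss_kappa(r), error = function(e) NA)
    if (!is.na(k)) expect_true(k >= -1 && k <= 1)
  }
})

test_that("bootstrap kappa intervals are seeded, bounded and cover the estimate", {
  m <- matrix("correct", 44, 5)
  m[1:2, ] <- "incorrect"
  ci <- kappa_ci(m, n_boot = 200, seed = 7)
  expect_equal(ci$upper, 1)

  set.seed(123)
  r <- matrix(sample(c("correct", "incorrect"), 44 * 5, replace = TRUE), 44, 5)
  ci1 <- kappa_ci(r, n_boot = 1000, seed = 11)
  ci2 <- kappa_ci(r, n_boot = 1000, seed = 11)
  expect_identical(ci1, ci2)
  expect_lte(ci1$lower, ci1$kappa)
  expect_gte(ci1$upper, ci1$kappa)
  expect_error(kappa_ci(r, n_boot = 10), class = "psarag_domain_error")
})

test_that("accuracy comparisons agree with a hand-computed t statistic", {
  x <- c(rep(1, 8), rep(0, 2))  # 8/10 correct
  y <- c(rep(1, 5), rep(0, 5))  # 5/10 correct
  # oracle: pooled two-sample t computed from first principles
  v1 <- sum((x - mean(x))^2) / 9
  v2 <- sum((y - mean(y))^2) / 9
  sp2 <- (9 * v1 + 9 * v2) / 18
  t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 10 + 1 / 10))
  got <- compare_accuracy(x, y, method = "t")
  expect_equal(got$statistic, t_oracle, tolerance = 1e-12)

  same <- compare_accuracy(x, x, method = "two_proportion")
  expect_equal(same$p_value, 1)
  expect_equal(compare_accuracy(rep(1, 5), rep(1, 5), method = "t")$p_value, 1)

  rt <- load_table1_fixture()
  llm <- rt[rt$arm == "llm", ]
  for (arm in c("human_closed", "human_open")) {
    h <- rt[rt$arm == arm, ]
    expect_lt(compare_accuracy(llm, h, method = "t")$p_value, 0.001)
    expect_lt(compare_accuracy(llm, h, method = "two_proportion")$p_value, 0.001)
  }
})
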