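# Grading of recommendations against gold labels (binomial correct /
# incorrect with a four-way error taxonomy), aggregation into accuracy
# reports, Fleiss kappa with bootstrap confidence intervals, and
# accuracy-comparison tests.

error_levels <- function() {
  c("none", "unnecessary_short_interval", "unnecessary_did_not_require",
    "missed_long_interval", "missed_failed_to_offer")
}

test_offering_actions <- function() {
  c("offer_psa_now", "routine_interval", "confirmatory_repeat_weeks",
    "defer_treat_uti_then_repeat")
}

# Implied timing of each test-offering action, in months, used to decide
# whether a wrong test was offered too early (unnecessary, short interval)
# or too late (missed, long interval).
implied_interval <- function(action, interval = NULL) {
  switch(action,
    offer_psa_now = c(0, 0),
    routine_interval = interval,
    confirmatory_repeat_weeks = c(0.5, 1.5),
    defer_treat_uti_then_repeat = c(1, 3),
    NULL)
}

#' Gold label for a case
#'
#' The acceptable (source, action, interval) triples — one per guideline —
#' against which a response is graded: a response is correct when it is
#' concordant with either guideline.
#'
#' @param case_id Case identifier.
#' @param dual The reference \code{dual_recommendation} (or refusal
#'   semantics encoded as two \code{no_testing} entries).
#' @param category One of the five study categories.
#' @return A \code{gold_label}.
#' @export
gold_label <- function(case_id, dual, category) {
  acceptable <- lapply(list(dual$eau, dual$aua), function(r) {
    list(source = r$source, action = r$action,
         interval_months = r$interval_months)
  })
  structure(list(case_id = case_id, acceptable = acceptable,
                 category = category),
            class = "gold_label")
}

presented_actions <- function(pred) {
  if (inherits(pred, "pipeline_result")) {
    if (is.null(pred$dual)) {
      return(list(list(action = "no_testing", interval_months = NULL)))
    }
    pred <- pred$dual
  }
  if (inherits(pred, "dual_recommendation")) {
    return(lapply(pred$final_actions, function(r) {
      list(action = r$action, interval_months = r$interval_months)
    }))
  }
  if (inherits(pred, "psa_recommendation")) {
    return(list(list(action = pred$action, interval_months = pred$interval_months)))
  }
  domain_error("cannot grade object of this class")
}

triple_matches <- function(p, a) {
  if (!identical(p$action, a$action)) return(FALSE)
  intervals_overlap(p$interval_months, a$interval_months)
}

#' Grade a response against its gold label
#'
#' Correct iff any presented final action matches any acceptable triple
#' (equal action; overlapping intervals where applicable). Incorrect
#' responses get exactly one error subtype: a test offered when none was
#' acceptable is \code{unnecessary_did_not_require}; a test timed strictly
#' earlier than every acceptable test is \code{unnecessary_short_interval};
#' strictly later, \code{missed_long_interval}; and no test offered when
#' one was acceptable is \code{missed_failed_to_offer}. Gate refusals are
#' graded as \code{no_testing}.
#'
#' @param pred A \code{dual_recommendation}, \code{pipeline_result} or
#'   single \code{psa_recommendation}.
#' @param gold The case's \code{gold_label}.
#' @param arm Evaluation arm label (e.g. \code{"llm"}).
#' @param rater_id Rater (or run) identifier.
#' @return One-row data frame: \code{case_id}, \code{arm}, \code{rater_id},
#'   \code{category}, \code{correct}, \code{error}.
#' @export
grade <- function(pred, gold, arm = "llm", rater_id = "r1") {
  if (is.null(gold)) {
    stop(errorCondition("no gold label for case",
                        class = c("psarag_lookup_error", "psarag_error")))
  }
  pres <- presented_actions(pred)
  acc <- gold$acceptable
  correct <- any(vapply(pres, function(p) {
    any(vapply(acc, function(a) triple_matches(p, a), logical(1)))
  }, logical(1)))
  error <- if (correct) "none" else classify_error(pres, acc)
  data.frame(case_id = gold$case_id, arm = arm, rater_id = rater_id,
             category = gold$category, correct = correct, error = error,
             stringsAsFactors = FALSE)
}

classify_error <- function(pres, acc) {
  offers <- function(x) x$action %in% test_offering_actions()
  resp_offers <- any(vapply(pres, offers, logical(1)))
  gold_offers <- any(vapply(acc, offers, logical(1)))
  if (resp_offers && !gold_offers) return("unnecessary_did_not_require")
  if (!resp_offers && gold_offers) return("missed_failed_to_offer")
  if (resp_offers && gold_offers) {
    ri <- Filter(Negate(is.null), lapply(pres, function(p)
      implied_interval(p$action, p$interval_months)))
    gi <- Filter(Negate(is.null), lapply(acc, function(a)
      implied_interval(a$action, a$interval_months)))
    resp_hi <- max(vapply(ri, `[`, numeric(1), 2))
    resp_lo <- min(vapply(ri, `[`, numeric(1), 1))
    gold_lo <- min(vapply(gi, `[`, numeric(1), 1))
    gold_hi <- max(vapply(gi, `[`, numeric(1), 2))
    if (resp_hi < gold_lo) return("unnecessary_short_interval")
    if (resp_lo > gold_hi) return("missed_long_interval")
    return("unnecessary_did_not_require")
  }
  # neither offers a test yet they disagree (e.g. no_testing vs referral)
  if (any(vapply(acc, function(a) a$action == "refer_urology", logical(1)))) {
    "missed_failed_to_offer"
  } else {
    "unnecessary_did_not_require"
  }
}

consistency_error <- function(msg) {
  stop(errorCondition(msg, class = c("psarag_consistency_error", "psarag_error")))
}

#' Aggregate graded ratings into an accuracy/error report
#'
#' One row per arm and category (all five categories always reported, with
#' zero rows for empty ones), plus pooled \code{screening} (categories
#' 1-2), \code{follow_up} (categories 3-5) and \code{overall} rows.
#' Denominators are ratings (cases times raters). Subtotal and total
#' consistency is enforced by construction; mixed rater counts within a
#' category raise a consistency error.
#'
#' @param ratings Data frame of graded ratings (rows as produced by
#'   \code{\link{grade}}).
#' @return Data frame report with error-subtype counts, subtotals, total
#'   errors and accuracy percentages.
#' @export
aggregate_ratings <- function(ratings) {
  stopifnot(nrow(ratings) > 0L)
  bad <- setdiff(ratings$error, error_levels())
  if (length(bad)) consistency_error(paste("unknown error subtype:", bad[1]))
  pools <- list(screening = category_levels()[1:2],
                follow_up = category_levels()[3:5],
                overall = category_levels())
  rows <- list()
  for (arm in unique(ratings$arm)) {
    ra <- ratings[ratings$arm == arm, , drop = FALSE]
    for (cat in category_levels()) {
      rc <- ra[ra$category == cat, , drop = FALSE]
      if (nrow(rc)) {
        per_case <- table(rc$case_id)
        if (length(unique(as.integer(per_case))) > 1L) {
          consistency_error(sprintf(
            "mixed rater counts within arm '%s' category '%s'", arm, cat))
        }
      }
      rows[[length(rows) + 1L]] <- report_row(arm, cat, rc)
    }
    for (pool in names(pools)) {
      rp <- ra[ra$category %in% pools[[pool]], , drop = FALSE]
      rows[[length(rows) + 1L]] <- report_row(arm, pool, rp)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

report_row <- function(arm, label, r) {
  n <- nrow(r)
  cnt <- function(e) sum(r$error == e)
  short <- cnt("unnecessary_short_interval")
  dnr <- cnt("unnecessary_did_not_require")
  long <- cnt("missed_long_interval")
  fto <- cnt("missed_failed_to_offer")
  total <- short + dnr + long + fto
  data.frame(arm = arm, category = label, n = n,
             unnecessary_short_interval = short,
             unnecessary_did_not_require = dnr,
             unnecessary_subtotal = short + dnr,
             missed_long_interval = long,
             missed_failed_to_offer = fto,
             missed_subtotal = long + fto,
             total_errors = total,
             accuracy_pct = if (n > 0) 100 * (1 - total / n) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Items-by-raters rating matrix
#'
#' @param ratings Graded-rating data frame.
#' @param arm Optional arm to subset to.
#' @param value Column to tabulate: \code{"correct"} (binary
#'   correct/incorrect, the default) or any other rating column.
#' @return Character matrix, rows = items (cases), columns = raters; every
#'   cell filled (rectangularity enforced).
#' @export
rating_matrix <- function(ratings, arm = NULL, value = "correct") {
  if (!is.null(arm)) ratings <- ratings[ratings$arm == arm, , drop = FALSE]
  stopifnot(nrow(ratings) > 0L)
  v <- ratings[[value]]
  if (is.logical(v)) v <- ifelse(v, "correct", "incorrect")
  items <- sort(unique(ratings$case_id))
  raters <- sort(unique(ratings$rater_id))
  m <- matrix(NA_character_, length(items), length(raters),
              dimnames = list(items, raters))
  m[cbind(match(ratings$case_id, items), match(ratings$rater_id, raters))] <-
    as.character(v)
  if (anyNA(m)) consistency_error("rating matrix is not rectangular (missing cells)")
  m
}

#' Fleiss kappa
#'
#' Chance-corrected agreement for n raters assigning categorical ratings
#' to N items: \eqn{\kappa = (\bar P - \bar P_e)/(1 - \bar P_e)} with
#' category proportions pooled over items. When every cell holds one
#' single category, expected agreement is 1 and kappa is undefined; an
#' error of class \code{psarag_undefined_agreement} is raised rather than
#' returning a number.
#'
#' @param mat Items-by-raters character (or factor) matrix.
#' @return The kappa value.
#' @export
fleiss_kappa <- function(mat) {
  mat <- as.matrix(mat)
  n_items <- nrow(mat)
  n_raters <- ncol(mat)
  stopifnot(n_items >= 2L, n_raters >= 2L)
  cats <- sort(unique(as.character(mat)))
  counts <- t(apply(mat, 1L, function(row) {
    vapply(cats, function(k) sum(row == k), numeric(1))
  }))
  if (length(cats) == 1L) counts <- matrix(counts, ncol = 1L)
  P_i <- (rowSums(counts^2) - n_raters) / (n_raters * (n_raters - 1))
  P_bar <- mean(P_i)
  p_j <- colSums(counts) / (n_items * n_raters)
  P_e <- sum(p_j^2)
  if (P_e >= 1 - 1e-12) {
    stop(errorCondition(
      "agreement undefined: all ratings fall in one single category",
      class = c("psarag_undefined_agreement", "psarag_error")))
  }
  (P_bar - P_e) / (1 - P_e)
}

#' Bootstrap confidence interval for Fleiss kappa
#'
#' Nonparametric item bootstrap: items (rows) are resampled with
#' replacement, kappa recomputed on each resample, and the percentile
#' interval reported. Degenerate resamples (kappa undefined) are skipped
#' and counted; more than 50\% degenerate is an error.
#'
#' @param mat Items-by-raters rating matrix.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed RNG seed; fixed seed gives identical intervals.
#' @param conf Confidence level. Default 0.95.
#' @return List: \code{kappa} (point estimate), \code{lower}, \code{upper},
#'   \code{n_boot}, \code{n_degenerate}.
#' @export
kappa_ci <- function(mat, n_boot = 1000L, seed = 20251119L, conf = 0.95) {
  if (n_boot < 100L) domain_error("n_boot must be >= 100")
  mat <- as.matrix(mat)
  point <- fleiss_kappa(mat)
  set.seed(seed)
  ks <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(nrow(mat), replace = TRUE)
    tryCatch(fleiss_kappa(mat[idx, , drop = FALSE]),
             error = function(e) NA_real_)
  }, numeric(1))
  n_degenerate <- sum(is.na(ks))
  if (n_degenerate > n_boot / 2) {
    domain_error("more than half of bootstrap resamples had undefined agreement")
  }
  alpha <- (1 - conf) / 2
  q <- stats::quantile(ks, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  list(kappa = point, lower = q[1], upper = q[2],
       n_boot = n_boot, n_degenerate = n_degenerate)
}

#' Compare accuracy between two arms
#'
#' The binary correct/incorrect outcomes of two arms are compared with
#' either a two-proportion z-test (the documented default) or a Student
#' two-sample t test on the 0/1 outcomes. Arms with zero variance in both
#' groups and equal means return p = 1.
#'
#' @param arm_a,arm_b Graded-rating data frames (or logical vectors of
#'   correctness).
#' @param method \code{"two_proportion"} or \code{"t"}.
#' @return List: \code{method}, \code{statistic}, \code{p_value},
#'   \code{prop} (the two accuracy proportions), \code{n}.
#' @export
compare_accuracy <- function(arm_a, arm_b,
                             method = c("two_proportion", "t")) {
  method <- match.arg(method)
  x <- as_correct(arm_a)
  y <- as_correct(arm_b)
  n1 <- length(x); n2 <- length(y)
  p1 <- mean(x); p2 <- mean(y)
  if (method == "two_proportion") {
    if (p1 == p2) {
      z <- 0; p <- 1
    } else {
      pp <- (sum(x) + sum(y)) / (n1 + n2)
      z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
      p <- 2 * stats::pnorm(-abs(z))
    }
    list(method = method, statistic = z, p_value = p,
         prop = c(p1, p2), n = c(n1, n2))
  } else {
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (p1 == p2) return(list(method = method, statistic = 0, p_value = 1,
                                prop = c(p1, p2), n = c(n1, n2)))
      return(list(method = method, statistic = Inf * sign(p1 - p2),
                  p_value = 0, prop = c(p1, p2), n = c(n1, n2)))
    }
    tt <- stats::t.test(x, y, var.equal = TRUE)
    list(method = method, statistic = unname(tt$statistic),
         p_value = tt$p.value, prop = c(p1, p2), n = c(n1, n2))
  }
}

as_correct <- function(arm) {
  if (is.data.frame(arm)) as.numeric(arm$correct) else as.numeric(arm)
}

#' Reconstructed published rating fixture
#'
#' Rebuilds the three-arm (LLM, human closed-book, human open-book) graded
#' ratings of the study's 44 cases times 5 raters from the published
#' marginal error counts. Within each arm and category, errors are filled
#' into (case, rater) slots lexicographically (case-major), which is
#' arbitrary but fixed: the fixture guarantees the marginal counts, not the
#' true case/rater layout, so agreement statistics on the human arms are
#' not meaningful (the LLM arm, whose errors are unanimous per case, is).
#'
#' @param path Optional path to a counts CSV (columns arm, category,
#'   error, count); defaults to the packaged fixture.
#' @return Graded-rating data frame with 3 x 220 rows.
#' @export
load_table1_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_counts.csv", package = "psarag")
  }
  counts <- utils::read.csv(path, stringsAsFactors = FALSE)
  sizes <- c(cat1_screen_recommended = 11L, cat2_screen_not_recommended = 9L,
             cat3_normal_followup = 9L, cat4_elevated_psa = 8L,
             cat5_other = 7L)
  first <- cumsum(c(1L, unname(sizes)))[seq_along(sizes)]
  names(first) <- names(sizes)
  raters <- paste0("r", 1:5)
  out <- list()
  for (arm in unique(counts$arm)) {
    for (cat in names(sizes)) {
      ncase <- sizes[[cat]]
      case_ids <- sprintf("case%02d", first[[cat]] + seq_len(ncase) - 1L)
      slots <- expand.grid(rater_id = raters, case_id = case_ids,
                           stringsAsFactors = FALSE)[, c(2, 1)]
      slots <- slots[order(slots$case_id, slots$rater_id), ]
      err <- rep("none", nrow(slots))
      pos <- 1L
      for (e in error_levels()[-1]) {
        k <- counts$count[counts$arm == arm & counts$category == cat &
                            counts$error == e]
        k <- if (length(k)) sum(k) else 0L
        if (k > 0L) {
          err[pos:(pos + k - 1L)] <- e
          pos <- pos + k
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        case_id = slots$case_id, arm = arm, rater_id = slots$rater_id,
        category = cat, correct = err == "none", error = err,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write an evaluation report
#'
#' @param report Data frame from \code{\link{aggregate_ratings}}.
#' @param path Output path; \code{.csv} or \code{.json} by extension.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(report, path, row.names = FALSE)
  }
  invisible(path)
}
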