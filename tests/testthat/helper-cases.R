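# Shared fixtures: compact case constructors used across the suite.

make_case <- function(case_id = "t1", age = 55, psa = NULL, months_ago = 0,
                      comorbidities = NULL, active_uti = FALSE,
                      dre = "not_done", risk_factors = NULL, ...) {
  rec <- list(case_id = case_id, age = age, active_uti = active_uti,
              dre = dre, ...)
  if (!is.null(comorbidities)) rec$comorbidities <- as.list(comorbidities)
  if (!is.null(risk_factors)) rec$risk_factors <- as.list(risk_factors)
  if (!is.null(psa)) {
    rec$psa_history <- mapply(function(v, m) list(value = v, months_ago = m),
                              psa, months_ago, SIMPLIFY = FALSE)
  }
  parse_case(rec)
}

# The failure scenario analysed in depth by the study: a 55-year-old on
# follow-up with a screening PSA of 2.8 ng/mL.
worked_case <- function() make_case("worked", age = 55, psa = 2.8)

dual_for <- function(case, gate_cfg = gate_config()) {
  recommend_dual(case, gate_cfg = gate_cfg)
}

tiny_corpus_dir <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  writeLines(c("---", "source: EAU", "section: toy", "---",
               "psa threshold three nanograms test.",
               "",
               "repeat interval two years follow up.",
               "",
               "referral urology elevated confirmed."),
             file.path(dir, "eau_toy.md"))
  writeLines(c("---", "source: AUA", "section: toy", "---",
               "screening interval two to four years.",
               "",
               "shared decision making ages fifty to sixty nine."),
             file.path(dir, "aua_toy.md"))
  dir
}

# A backend that must never be reached (asserts gate short-circuiting).
forbidden_backend <- function() {
  structure(list(name = "forbidden",
                 complete = function(prompt) stop("backend was called")),
            class = "psarag_backend")
}
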