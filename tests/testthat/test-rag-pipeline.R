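test_that("chunking is deterministic, paragraph-bounded and source-tagged", {
  dir <- tiny_corpus_dir()
  a <- chunk_corpus(dir, chunk_config(max_tokens = 1000))
  b <- chunk_corpus(dir, chunk_config(max_tokens = 1000))
  expect_identical(vapply(a, `[[`, "", "chunk_id"),
                   vapply(b, `[[`, "", "chunk_id"))
  # large budget: one chunk per document, all paragraphs joined
  expect_length(a, 2)
  eau_chunk <- a[[which(vapply(a, `[[`, "", "source") == "EAU")]]
  expect_match(eau_chunk$text, "referral urology")
  expect_setequal(vapply(a, `[[`, "", "source"), c("EAU", "AUA"))

  # small budget splits on paragraph boundaries
  small <- chunk_corpus(dir, chunk_config(max_tokens = 6, overlap = 0))
  expect_gt(length(small), 2)

  empty <- withr::local_tempfile(fileext = ".md")
  writeLines(c("---", "source: EAU", "---"), empty)
  expect_warning(ch <- chunk_corpus(empty), "empty")
  expect_length(ch, 0)

  untagged <- withr::local_tempfile(fileext = ".md")
  writeLines("no front matter here", untagged)
  expect_error(chunk_corpus(untagged), class = "psarag_config_error")
})

test_that("BM25 scores match an independent hand computation", {
  dir <- tiny_corpus_dir()
  idx <- build_index(chunk_corpus(dir, chunk_config(max_tokens = 6, overlap = 0)))
  eau_docs <- idx$tokens[idx$sources == "EAU"]
  query <- "psa interval years"

  # independent oracle: per-document loop, textbook formula
  oracle <- function(qterms, docs, k1 = 1.2, b = 0.75) {
    N <- length(docs)
    avgdl <- mean(lengths(docs))
    vapply(docs, function(d) {
      s <- 0
      for (t in unique(qterms)) {
        nq <- sum(vapply(docs, function(x) t %in% x, logical(1)))
        f <- sum(d == t)
        if (f == 0 || nq == 0) next
        s <- s + log(1 + (N - nq + 0.5) / (nq + 0.5)) *
          (f * (k1 + 1)) / (f + k1 * (1 - b + b * length(d) / avgdl))
      }
      s
    }, numeric(1))
  }
  expected <- sort(oracle(c("psa", "interval", "years"), eau_docs),
                   decreasing = TRUE)
  got <- retrieve(query, idx, "EAU", k = 100, min_score = -Inf)
  expect_equal(vapply(got, `[[`, 0, "score"), expected, tolerance = 1e-12)
})

test_that("retrieval is ranked, filtered and deterministic", {
  idx <- build_index(chunk_corpus(tiny_corpus_dir(),
                                  chunk_config(max_tokens = 6, overlap = 0)))
  # self-retrieval: the verbatim text of a chunk ranks it first
  target <- idx$chunks[[which(idx$sources == "EAU")[1]]]
  res <- retrieve(target$text, idx, "EAU", k = 10)
  expect_identical(res[[1]]$chunk$chunk_id, target$chunk_id)

  all_res <- retrieve("psa interval", idx, "AUA", k = 100, min_score = -Inf)
  expect_equal(vapply(all_res, `[[`, 0L, "rank"), seq_along(all_res))
  expect_true(all(diff(vapply(all_res, `[[`, 0, "score")) <= 0))
  expect_true(all(vapply(all_res, function(r) r$chunk$source, "") == "AUA"))
  expect_identical(
    vapply(retrieve("psa interval", idx, "AUA", k = 100), `[[`, "", c("chunk", "chunk_id")),
    vapply(retrieve("psa interval", idx, "AUA", k = 100), `[[`, "", c("chunk", "chunk_id")))
  expect_error(retrieve("q", idx, "EAU", k = 0), class = "psarag_domain_error")
})

test_that("prompt bundles carry every passage verbatim and all four techniques", {
  idx <- build_index(chunk_corpus(
    system.file("extdata", "corpus", package = "psarag")))
  res <- retrieve(case_query(worked_case()), idx, "EAU", k = 2)
  b1 <- assemble_prompt(worked_case(), res)
  b2 <- assemble_prompt(worked_case(), res)
  expect_identical(b1$prompt, b2$prompt)
  for (r in res) expect_true(grepl(r$chunk$text, b1$prompt, fixed = TRUE))
  expect_match(b1$prompt, "expert consultant urologist")   # persona
  expect_match(b1$prompt, "step by step")                  # chain of thought
  expect_match(b1$prompt, "ONLY on the guideline passages") # constrained
  # the example output structure itself parses under the response parser
  rec <- parse_backend_response(b1$output_schema_example, "AUA")
  expect_s3_class(rec, "psa_recommendation")

  expect_error(assemble_prompt(worked_case(), res, template = "no slots at all"),
               class = "psarag_template_error")
})

test_that("mock generation reproduces the rule engine; bad output fails loudly", {
  cfg <- pipeline_config()
  wc <- worked_case()
  res <- retrieve(case_query(wc), cfg$index, "EAU", k = cfg$k)
  bundle <- assemble_prompt(wc, res)
  rec <- generate(wc, bundle, cfg$backend)
  engine <- recommend_eau(wc, screening_gate(wc, cci_score(wc)))
  expect_identical(rec$action, engine$action)
  expect_identical(rec$interval_months, engine$interval_months)
  expect_identical(rec$rationale, engine$rationale)

  prose <- scripted_backend(list("*" = "I think a repeat PSA would be wise."))
  err <- expect_error(generate(wc, bundle, prose), class = "psarag_parse_error")
  expect_match(err$raw_response, "repeat PSA")
  expect_false(inherits(err, "psarag_backend_error"))

  broken <- structure(list(complete = function(p) stop("socket timeout")),
                      class = "psarag_backend")
  expect_error(generate(wc, bundle, broken), class = "psarag_backend_error")
})

test_that("the scripted backend replays the hallucinated confirmatory repeat", {
  halluc <- scripted_backend(list("worked" = paste0(
    '{"action": "confirmatory_repeat_weeks", "shared_decision": true, ',
    '"cited_rules": ["eau.moderately_elevated_confirm_repeat"], ',
    '"reasoning": "the PSA is moderately elevated so a repeated test after a few weeks"}')))
  cfg <- pipeline_config(backend = halluc)
  out <- run_pipeline(worked_case(), cfg)
  expect_identical(out$dual$eau$action, "confirmatory_repeat_weeks")
  gold <- gold_label("worked", dual_for(worked_case()), "cat3_normal_followup")
  g <- grade(out, gold)
  expect_false(g$correct)
  expect_identical(g$error, "unnecessary_short_interval")
})

test_that("gate-refused cases short-circuit before any retrieval or backend call", {
  cfg <- pipeline_config(backend = forbidden_backend())
  out <- run_pipeline(make_case(age = 75), cfg)
  expect_false(out$gate$eligible)
  expect_null(out$dual)
  stages <- vapply(out$trace, `[[`, "", "stage")
  expect_identical(stages, c("cci", "gate"))
  expect_null(out$retrieval$EAU)
})

test_that("eligible cases run end-to-end and repeat runs are identical", {
  cfg <- pipeline_config()
  wc <- worked_case()
  runs <- lapply(1:5, function(i) run_pipeline(wc, cfg))
  jsons <- vapply(runs, function(r) serialize_dual(r$dual), character(1))
  expect_length(unique(jsons), 1)
  expect_identical(serialize_dual(runs[[1]]$dual),
                   serialize_dual(dual_for(wc)))
  stages <- vapply(runs[[1]]$trace, `[[`, "", "stage")
  expect_true(all(c("retrieve:EAU", "generate:AUA", "reconcile") %in% stages))
})

test_that("cited rules are always supported by a retrieved passage", {
  cfg <- pipeline_config()
  cohort <- generate_cohort(cohort_config(seed = 3))
  for (entry in cohort[seq(1, length(cohort), by = 3)]) {
    out <- run_pipeline(entry$case, cfg)
    if (is.null(out$dual)) next
    for (src in c("EAU", "AUA")) {
      ctx <- paste(vapply(out$retrieval[[src]],
                          function(r) r$chunk$text, ""), collapse = "\n")
      supported <- regmatches(ctx, gregexpr("\\[rule:([a-z0-9_.]+)\\]", ctx))[[1]]
      supported <- gsub("\\[rule:|\\]", "", supported)
      rec <- if (src == "EAU") out$dual$eau else out$dual$aua
      expect_true(all(rec$rationale %in% supported),
                  info = paste(entry$case$case_id, src,
                               paste(rec$rationale, collapse = ",")))
    }
  }
})

test_that("stage errors are annotated with the failing stage", {
  cfg <- pipeline_config(backend = forbidden_backend())
  err <- expect_error(run_pipeline(worked_case(), cfg),
                      class = "psarag_stage_error")
  expect_match(conditionMessage(err), "stage 'generate:EAU'")
})
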