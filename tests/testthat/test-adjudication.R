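q <- fixture_question()

fake_execution <- function(exit_status = 0L, stdout = "", stderr = "",
                           version = 1L, timed_out = FALSE) {
  structure(list(version = version, exit_status = as.integer(exit_status),
                 stdout = stdout, stderr = stderr, outputs = character(0),
                 duration = 0.1, timed_out = timed_out, sandbox = NULL,
                 env_ref = NULL),
            class = "execution_result")
}

fake_selection <- structure(
  list(question_id = q$question_id, primary_variables = c("STROKE", "educ"),
       confounders = c("AGE", "BMI"), rationale = ""),
  class = "variable_selection")

judge_reply <- function(qd = "pass", vd = "pass", pd = "pass") {
  list(question = qd, variable = vd, process = pd,
       feedback = "detailed feedback", confidence = 0.9)
}

test_that("interpretation reports carry extracted quantities and anomalies", {
  ok <- interpret_result(fake_execution(0L, stdout = "odds_ratio: 0.79"), q,
                         test_config, provider = scripted(
                           list(summary = "OR printed",
                                quantities = list(odds_ratio = 0.79))))
  expect_identical(unname(ok$extracted_quantities["odds_ratio"]), 0.79)
  expect_length(ok$anomalies, 0)

  bad <- interpret_result(fake_execution(1L, stderr = "Error: boom"), q,
                          test_config,
                          provider = scripted(list(summary = "failed")))
  expect_true(any(grepl("boom", bad$anomalies)))
})

test_that("a nonzero exit is unanswered mechanically, with zero provider calls", {
  p <- scripted_provider(character(0))  # any provider call would error
  rep_ <- structure(list(question_id = q$question_id, version = 1L,
                         summary = "s", extracted_quantities = numeric(0),
                         anomalies = "nonzero exit"),
                    class = "interpretation_report")
  v <- judge_result(rep_, fake_execution(2L, stderr = "Error"), q,
                    fake_selection, test_config, provider = p)
  expect_false(v$answered)
  expect_identical(replay_position(p), 0L)
  expect_identical(v$dimension_results$result[
    v$dimension_results$dimension == "error"], "fail")
  expect_true(nzchar(v$feedback))
})

test_that("the verdict is the conjunction of all four dimensions (16 combinations)", {
  rep_ <- structure(list(question_id = q$question_id, version = 1L,
                         summary = "s", extracted_quantities = numeric(0),
                         anomalies = character(0)),
                    class = "interpretation_report")
  pf <- c("pass", "fail")
  for (err in pf) for (qd in pf) for (vd in pf) for (pd in pf) {
    exec <- fake_execution(if (err == "pass") 0L else 1L)
    provider <- if (err == "pass")
      scripted(judge_reply(qd, vd, pd)) else scripted_provider(character(0))
    v <- judge_result(rep_, exec, q, fake_selection, test_config,
                      provider = provider)
    dims <- setNames(v$dimension_results$result,
                     v$dimension_results$dimension)
    expect_identical(v$answered, all(dims == "pass"))
    if (err == "pass")
      expect_identical(unname(dims[c("question", "variable", "process")]),
                       c(qd, vd, pd))
    else
      expect_false(v$answered)
  }
})

test_that("judging validates version agreement and provider output", {
  rep_ <- structure(list(question_id = q$question_id, version = 2L,
                         summary = "s", extracted_quantities = numeric(0),
                         anomalies = character(0)),
                    class = "interpretation_report")
  expect_error(
    judge_result(rep_, fake_execution(0L, version = 1L), q, fake_selection,
                 test_config, provider = scripted(judge_reply())),
    class = "adra_precondition")
  rep1 <- rep_; rep1$version <- 1L
  expect_error(
    judge_result(rep1, fake_execution(0L), q, fake_selection, test_config,
                 provider = scripted(list(question = "maybe"),
                                     list(question = "maybe"))),
    class = "adra_provider_format")
})

test_that("debugging merges a fix, bumps the version, and respects the budget", {
  art <- code_artifact("qid", "r", 'stop("bug")')
  verdict <- structure(list(question_id = "qid", answered = FALSE,
                            feedback = "script stops unconditionally"),
                       class = "verdict")
  fix <- debug_artifact(art, verdict, round = 1L, test_config,
                        provider = scripted(list(fragment = "cat(2)"),
                                            list(source = "cat(2)")))
  expect_identical(fix$artifact$version, 2L)
  expect_identical(fix$patch$base_version, 1L)
  expect_identical(fix$patch$merged_source, "cat(2)")
  expect_identical(fix$patch$round, 1L)

  expect_error(
    debug_artifact(art, verdict, round = 5L, test_config,
                   provider = scripted_provider(character(0))),
    class = "adra_budget_exhausted")
  answered <- structure(list(answered = TRUE), class = "verdict")
  expect_error(
    debug_artifact(art, answered, round = 1L, test_config,
                   provider = scripted_provider(character(0))),
    class = "adra_precondition")
})

test_that("debug chains keep versions strictly increasing and gapless", {
  art <- code_artifact("qid", "r", "v1")
  verdict <- structure(list(answered = FALSE, feedback = "f"),
                       class = "verdict")
  versions <- art$version
  for (r in 1:4) {
    fix <- debug_artifact(art, verdict, round = r, test_config,
                          provider = scripted(
                            list(fragment = paste0("v", r + 1)),
                            list(source = paste0("v", r + 1))))
    art <- fix$artifact
    versions <- c(versions, art$version)
  }
  expect_identical(versions, 1:5)
})

test_that("failure classification separates environment from code errors", {
  expect_identical(classify_failure(fake_execution(
    127L, stderr = "sh: 1: bwa-mem3: not found")), "environment")
  expect_identical(classify_failure(fake_execution(
    127L, stderr = "bash: tool: command not found")), "environment")
  expect_identical(classify_failure(fake_execution(
    1L, stderr = "Error in library(notthere): there is no package called 'notthere'")),
    "environment")
  expect_identical(classify_failure(fake_execution(
    1L, stderr = "Error: object 'x' not found")), "code")
  expect_identical(classify_failure(fake_execution(
    1L, stderr = "Traceback ... ZeroDivisionError")), "code")
})

test_that("narratives require an answered verdict and carry the headline quantity", {
  rep_ <- structure(list(question_id = q$question_id, version = 1L,
                         summary = "OR printed",
                         extracted_quantities = c(odds_ratio = 0.79),
                         anomalies = character(0)),
                    class = "interpretation_report")
  yes <- structure(list(question_id = q$question_id, answered = TRUE),
                   class = "verdict")
  no <- structure(list(question_id = q$question_id, answered = FALSE),
                  class = "verdict")
  n <- analyze_result(yes, rep_, q, test_config, provider = scripted(
    list(conclusion = "education lowers stroke odds by 21%",
         effects = list("odds_ratio = 0.79"))))
  expect_identical(unname(n$primary_quantity), 0.79)
  expect_match(n$effect_statements, "0.79")
  expect_error(analyze_result(no, rep_, q, test_config,
                              provider = scripted_provider(character(0))),
               class = "adra_precondition")
})
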