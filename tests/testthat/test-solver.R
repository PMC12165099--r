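report <- fixture_report()
q <- fixture_question()

test_that("variable selection validates names and resolves overlaps toward primary", {
  sel <- select_variables(q, report, test_config, provider = scripted(
    list(primary = list("STROKE", "educ"), confounders = list("AGE", "BMI"),
         rationale = "as asked")))
  expect_identical(sel$primary_variables, c("STROKE", "educ"))
  expect_identical(sel$confounders, c("AGE", "BMI"))

  stubborn <- scripted(
    list(primary = list("EDUC_X"), confounders = list()),
    list(primary = list("EDUC_X"), confounders = list()))
  expect_error(select_variables(q, report, test_config, provider = stubborn),
               class = "adra_provider_format")

  overlap <- select_variables(q, report, test_config, provider = scripted(
    list(primary = list("STROKE", "AGE"), confounders = list("AGE", "BMI"))))
  expect_identical(overlap$confounders, "BMI")
  expect_match(attr(overlap, "resolution_log"), "AGE")
})

test_that("task plans are contiguously indexed, renumbering gaps with a warning", {
  sel <- structure(list(question_id = q$question_id,
                        primary_variables = "STROKE",
                        confounders = character(0), rationale = ""),
                   class = "variable_selection")
  plan <- plan_tasks(q, sel, test_config, provider = scripted(
    list(language = "r", steps = list(
      list(index = 1, description = "quality check", tools = list("fastqc")),
      list(index = 3, description = "fit model", tools = list())))))
  expect_identical(plan$steps$index, 1:2)
  expect_match(attr(plan, "warnings"), "renumbered")

  single <- plan_tasks(q, sel, test_config, provider = scripted(
    list(steps = list(list(index = 1, description = "only step")))))
  expect_identical(sub_question_count(single), 1L)

  sixstep <- plan_tasks(q, sel, test_config, provider = scripted(
    list(language = "shell", steps = lapply(1:6, function(i)
      list(index = i, description = paste("step", i),
           tools = list(paste0("tool", i)))))))
  expect_identical(sub_question_count(sixstep), 6L)

  expect_error(
    plan_tasks(q, sel, test_config,
               provider = scripted(list(steps = list()),
                                   list(steps = list()))),
    class = "adra_provider_format")
})

test_that("code generation detects language and passes tools through in order", {
  sel <- structure(list(question_id = q$question_id,
                        primary_variables = "STROKE",
                        confounders = character(0), rationale = ""),
                   class = "variable_selection")
  plan <- plan_tasks(q, sel, test_config, provider = scripted(
    list(language = "r", steps = list(
      list(index = 1, description = "a", tools = list("samtools")),
      list(index = 2, description = "b", tools = list("bcftools")),
      list(index = 3, description = "c", tools = list("bedtools"))))))
  art <- make_code(plan, sel, report, test_config, provider = scripted(
    list(language = "r", source = "cat(1+1)")))
  expect_identical(art$language, "r")
  expect_identical(art$version, 1L)
  expect_identical(art$required_software, c("samtools", "bcftools", "bedtools"))

  expect_error(
    make_code(plan, sel, report, test_config,
              provider = scripted(list(source = ""), list(source = "  "))),
    class = "adra_provider_format")
})

test_that("language detection precedence: metadata, then shebang, then extension", {
  expect_identical(adra:::detect_language("python", "#!/usr/bin/env Rscript"),
                   "python")
  expect_identical(adra:::detect_language(NULL, "#!/usr/bin/env Rscript\nx"),
                   "r")
  expect_identical(adra:::detect_language(NULL, "#!/bin/bash\nls"), "shell")
  expect_identical(adra:::detect_language(NULL, "print(1)", hint = "a.py"),
                   "python")
  expect_identical(adra:::detect_language(NULL, "echo hi"), "shell")
})

test_that("execution captures output, exit status, and flags timeouts", {
  ok <- execute_artifact(code_artifact("q", "r", "cat(1 + 1)"))
  expect_identical(ok$exit_status, 0L)
  expect_identical(ok$stdout, "2")

  bad <- execute_artifact(code_artifact("q", "r", 'stop("deliberate")'))
  expect_true(bad$exit_status != 0L)
  expect_match(bad$stderr, "deliberate")

  t0 <- Sys.time()
  slow <- execute_artifact(code_artifact("q", "r", "Sys.sleep(60)"),
                           limits = execution_limits(timeout = 2))
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_true(slow$timed_out)
  expect_true(slow$exit_status != 0L)
  expect_lt(elapsed, 10)
})

test_that("execution is sandboxed: writes land in the sandbox, not the caller's tree", {
  probe_dir <- tempfile("probe-")
  dir.create(probe_dir)
  before <- list.files(probe_dir, recursive = TRUE)
  res <- execute_artifact(code_artifact(
    "q", "r", 'writeLines("out", "result.txt"); cat("done")'))
  expect_identical(res$outputs, "result.txt")
  expect_true(file.exists(file.path(res$sandbox, "result.txt")))
  expect_identical(list.files(probe_dir, recursive = TRUE), before)
  expect_false(startsWith(res$sandbox, getwd()))
})

test_that("a missing interpreter raises an environment error, not a code error", {
  err <- tryCatch(
    execute_artifact(code_artifact("q", "r", "cat(1)"),
                     limits = execution_limits(
                       interpreters = c(r = "definitely-absent-binary"))),
    error = identity)
  expect_true(is_adra_error(err, "environment_error"))
})

test_that("solve chain is reproducible for a fixed transcript", {
  sel_resp <- list(primary = list("STROKE", "educ"),
                   confounders = list("AGE"))
  plan_resp <- list(language = "r", steps = list(
    list(index = 1, description = "fit", tools = list())))
  code_resp <- list(language = "r", source = 'cat("odds_ratio: 0.79\n")')
  run_once <- function() {
    sel <- select_variables(q, report, test_config, provider = scripted(sel_resp))
    plan <- plan_tasks(q, sel, test_config, provider = scripted(plan_resp))
    art <- make_code(plan, sel, report, test_config, provider = scripted(code_resp))
    res <- execute_artifact(art)
    list(sel = sel, plan = plan, art = art,
         out = res$stdout, status = res$exit_status)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a, b)
})
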