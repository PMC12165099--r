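test_that("a full replay answers all three questions with zero debug events", {
  ledger <- run_scenario("stroke-education")
  expect_identical(ledger$summary$attempted, 3L)
  expect_identical(ledger$summary$answered, 3L)
  modules <- vapply(ledger$events, `[[`, "", "module")
  expect_false("codeDebugger" %in% modules)
  expect_true(all(ledger$questions$resolved_debug_round == 0L))
  # the first question ends answered with an extracted odds-type quantity
  rec <- ledger$records[[ledger$questions$question_id[1]]]
  expect_identical(names(rec$narrative$primary_quantity), "odds_ratio")
  expect_identical(unname(rec$narrative$primary_quantity), 0.79)
})

test_that("a two-round repair yields versions 1 to 3 and a final answered verdict", {
  ledger <- run_scenario("debug-recovery")
  expect_identical(ledger$summary$answered, 1L)
  qid <- ledger$questions$question_id[1]
  expect_identical(ledger$questions$resolved_debug_round[1], 2L)
  patched <- Filter(function(e) e$module == "codeDebugger" &&
                      e$kind == "patched", ledger$events)
  expect_identical(vapply(patched, function(e) e$payload$version, integer(1)),
                   2:3)
  expect_identical(ledger$records[[qid]]$artifact$version, 3L)
})

test_that("an unfixable bug burns exactly four debug rounds then ends unanswered", {
  ledger <- run_scenario("unfixable-bug")
  expect_identical(ledger$summary$answered, 0L)
  expect_identical(ledger$summary$unanswered, 1L)
  patched <- Filter(function(e) e$module == "codeDebugger" &&
                      e$kind == "patched", ledger$events)
  expect_length(patched, 4)
  kinds <- vapply(ledger$events, `[[`, "", "kind")
  expect_true("budget-exhausted" %in% kinds)
  # versions 1..5 were executed, strictly increasing and gapless
  executed <- Filter(function(e) e$module == "executor", ledger$events)
  expect_identical(vapply(executed, function(e) e$payload$version, integer(1)),
                   1:5)
  # no judge provider dimensions ever passed: every exit was nonzero
  judged <- Filter(function(e) e$kind == "judged", ledger$events)
  expect_true(all(!vapply(judged, function(e) e$payload$answered, logical(1))))
})

test_that("four evolution rounds produce a lineage chain of depth 4", {
  ledger <- run_scenario("four-round-evolution")
  expect_identical(ledger$summary$answered, 5L)
  expect_identical(sort(ledger$questions$round), 0:4)
  qs <- lapply(ledger$records, `[[`, "question")
  lin <- question_lineage(qs)
  expect_identical(max(lin$depth), 4L)
  deep_events <- Filter(function(e) e$module == "deepQuestioner",
                        ledger$events)
  expect_length(deep_events, 4)
})

test_that("replaying the same transcript reproduces the ledger except timestamps", {
  dirs <- replicate(2, tempfile("rep-"))
  f <- vapply(dirs, function(d)
    ledger_fingerprint(run_scenario("stroke-education", dir = d)),
    character(1))
  expect_identical(unname(f[1]), unname(f[2]))
  # and a different scenario has a different fingerprint
  g <- ledger_fingerprint(run_scenario("debug-recovery"))
  expect_false(g == f[1])
})

test_that("pass rates by debug round are non-decreasing and counted correctly", {
  mk_ledger <- function(resolved) {
    structure(list(
      config = list(max_debug_rounds = 4L),
      questions = data.frame(
        question_id = paste0("q", seq_along(resolved)),
        resolved_debug_round = resolved)),
      class = "run_ledger")
  }
  # 50 solved at round 0, 10 at round 1, 5 at round 2, 35 never (of 100)
  resolved <- c(rep(0L, 50), rep(1L, 10), rep(2L, 5), rep(NA_integer_, 35))
  rates <- pass_rate_by_round(mk_ledger(resolved))
  expect_equal(unname(rates), c(0.50, 0.60, 0.65, 0.65, 0.65))
  expect_true(all(diff(rates) >= 0))
  expect_equal(unname(pass_rate_by_round(mk_ledger(rep(0L, 4)))),
               rep(1, 5))
  expect_equal(unname(pass_rate_by_round(mk_ledger(rep(NA_integer_, 4)))),
               rep(0, 5))
  for (s in 1:25) {
    set.seed(s)
    resolved <- sample(c(0:4, NA), 30, replace = TRUE)
    expect_true(all(diff(pass_rate_by_round(mk_ledger(resolved))) >= 0))
  }
})

test_that("ablated modules leave zero events and are bypassed, not stubbed", {
  sc <- script_transcripts("stroke-education")
  # ablating variableGetter and taskPlanner removes one provider call each
  # per question: drop those scripted responses from the transcript
  responses <- sc$responses
  keep <- rep(TRUE, length(responses))
  solve_starts <- c(4, 10, 16)  # per-question blocks of 6 after 3 shared calls
  keep[c(solve_starts, solve_starts + 1)] <- FALSE
  provider <- scripted_provider(responses[keep])
  config <- sc$config
  config$ablation <- c("variableGetter", "taskPlanner")
  ledger <- run_cycle(config, provider = provider)
  modules <- vapply(ledger$events, `[[`, "", "module")
  expect_false(any(modules %in% c("variableGetter", "taskPlanner")))
  expect_identical(ledger$summary$answered, 3L)
  # bypass: every plan is the single-step fallback
  expect_true(all(ledger$questions$n_subquestions == 1L))

  config2 <- sc$config
  config2$ablation <- "dataCleaner"
  ledger2 <- run_cycle(config2,
                       provider = scripted_provider(sc$responses))
  expect_false("dataCleaner" %in% vapply(ledger2$events, `[[`, "", "module"))
})

test_that("sub-question accounting averages plan steps across the ledger", {
  ledger <- run_scenario("stroke-education")
  expect_identical(ledger$summary$total_subquestions, 9L)  # 3 plans x 3 steps
  expect_equal(ledger$summary$mean_subquestions, 3)
  plan <- ledger$records[[ledger$questions$question_id[1]]]$plan
  expect_identical(sub_question_count(plan), 3L)
})

test_that("ledgers round-trip through JSON Lines", {
  ledger <- run_scenario("stroke-education")
  path <- tempfile(fileext = ".jsonl")
  write_ledger(ledger, path)
  back <- read_ledger(path)
  expect_identical(length(back$events), length(ledger$events))
  expect_identical(back$summary$answered, ledger$summary$answered)
  expect_identical(back$questions$question_id, ledger$questions$question_id)
  expect_identical(back$config$dataset_id, ledger$config$dataset_id)
})

test_that("a question whose solve errors terminally does not abort the cycle", {
  sc <- script_transcripts("stroke-education")
  # the first question's selection gets persistent garbage (initial ask and
  # re-ask both invalid), so its solve raises a provider-format error; the
  # cycle must still complete the other two questions.
  garbage <- jresp(list(primary = list("NOPE"), confounders = list()))
  responses <- c(sc$responses[1:3], garbage, garbage,
                 sc$responses[4:length(sc$responses)])
  ledger <- run_cycle(sc$config, provider = scripted_provider(responses))
  expect_identical(ledger$summary$attempted, 3L)
  expect_identical(ledger$summary$answered, 2L)
  kinds <- vapply(ledger$events, `[[`, "", "kind")
  expect_true("question-error" %in% kinds)
})
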