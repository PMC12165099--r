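#' The autonomous research cycle
#'
#' Wires the full loop: profile the dataset, raise and review questions,
#' then for each retained question select variables, plan tasks, generate
#' code, execute, judge, repair (code errors to the debugger, environmental
#' failures to environment configuration) within bounded debug rounds,
#' narrate and validate answered findings, and deepen them into the next
#' evolution round. Every step appends an event to an append-only run
#' ledger, the unit of evaluation; module errors are contained per question
#' and never abort the cycle.
#'
#' @name orchestrator
NULL

ablatable_modules <- c("taskPlanner", "variableGetter", "dataCleaner")

#' Run configuration
#'
#' @param dataset_path delimited table path.
#' @param dataset_id identifier recorded in the ledger.
#' @param provider a [provider_config()].
#' @param n_candidates question batch size (default 100, the standard
#'   evaluation batch).
#' @param max_debug_rounds repair budget per question (default 4).
#' @param max_evolution_rounds deepening budget (default 4).
#' @param ablation subset of `c("taskPlanner", "variableGetter",
#'   "dataCleaner")`; ablated modules are skipped entirely, not stubbed.
#' @param prompt_mode `"full"` or `"basic"` template mode.
#' @param seed integer recorded in the ledger.
#' @param limits an [execution_limits()].
#' @param cleaning a [cleaning_policy()].
#' @param corpus optional literature corpus for validation of answered
#'   questions.
#' @param catalog optional sibling-dataset catalog for dataset matching.
#' @param registry optional [tool_registry()] for environment configuration.
#' @param descriptions optional named variable descriptions.
#' @param n_follow_ups follow-ups requested per deepening.
#' @param delim dataset delimiter.
#' @return object of class `run_config`.
#' @export
run_config <- function(dataset_path, dataset_id = basename(dataset_path),
                       provider, n_candidates = 100L, max_debug_rounds = 4L,
                       max_evolution_rounds = 4L, ablation = character(0),
                       prompt_mode = c("full", "basic"), seed = 1L,
                       limits = execution_limits(),
                       cleaning = cleaning_policy(), corpus = NULL,
                       catalog = NULL, registry = NULL, descriptions = NULL,
                       n_follow_ups = 1L, delim = ",") {
  prompt_mode <- match.arg(prompt_mode)
  bad <- setdiff(ablation, ablatable_modules)
  if (length(bad))
    adra_abort("domain", paste0("not an ablatable module: ", bad[1]))
  if (max_debug_rounds < 0 || max_evolution_rounds < 0)
    adra_abort("domain", "round budgets must be non-negative")
  structure(
    list(dataset_path = dataset_path, dataset_id = dataset_id,
         provider = provider, n_candidates = as.integer(n_candidates),
         max_debug_rounds = as.integer(max_debug_rounds),
         max_evolution_rounds = as.integer(max_evolution_rounds),
         ablation = ablation, prompt_mode = prompt_mode,
         seed = as.integer(seed), limits = limits, cleaning = cleaning,
         corpus = corpus, catalog = catalog, registry = registry,
         descriptions = descriptions, n_follow_ups = as.integer(n_follow_ups),
         delim = delim),
    class = "run_config"
  )
}

new_ledger_state <- function() {
  st <- new.env(parent = emptyenv())
  st$events <- list()
  st
}

add_event <- function(st, module, kind, payload = list()) {
  st$events[[length(st$events) + 1L]] <- list(
    seq = length(st$events) + 1L,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
    module = module, kind = kind, payload = payload)
  invisible(NULL)
}

# Bypass plan when the planner is ablated: the code maker receives the
# question directly as a single step.
fallback_plan <- function(question, selection) {
  steps <- data.frame(index = 1L, description = question$text,
                      stringsAsFactors = FALSE)
  steps$tools <- list(character(0))
  steps$external <- list(character(0))
  structure(list(question_id = question$question_id, steps = steps,
                 language_hint = "r"),
            class = "task_plan", warnings = character(0))
}

# Bypass selection when the variable getter is ablated: the full
# non-identifier variable list is passed as primary, no confounders.
fallback_selection <- function(question, report) {
  structure(list(question_id = question$question_id,
                 primary_variables = report_variable_names(report),
                 confounders = character(0), rationale = "ablated"),
            class = "variable_selection", resolution_log = character(0))
}

# Solve one question: select -> plan -> code -> execute -> judge, with env
# repairs and bounded debug rounds. Returns the per-question record and
# appends events.
solve_question <- function(question, report, config, store, provider, st) {
  ab <- config$ablation
  selection <- if ("variableGetter" %in% ab) {
    fallback_selection(question, report)
  } else {
    sel <- select_variables(question, report, config$provider, store, provider)
    add_event(st, "variableGetter", "selected",
              list(question_id = question$question_id,
                   primary = sel$primary_variables,
                   confounders = sel$confounders))
    sel
  }
  plan <- if ("taskPlanner" %in% ab) {
    fallback_plan(question, selection)
  } else {
    pl <- plan_tasks(question, selection, config$provider, store, provider,
                     registry = config$registry)
    add_event(st, "taskPlanner", "planned",
              list(question_id = question$question_id,
                   n_steps = sub_question_count(pl)))
    pl
  }
  artifact <- make_code(plan, selection, report, config$provider, store,
                        provider)
  add_event(st, "codeMaker", "generated",
            list(question_id = question$question_id,
                 language = artifact$language, version = artifact$version))
  if (!is.null(config$registry)) {
    manifest <- configure_environment(artifact, config$registry)
    add_event(st, "dockerMaker", "configured",
              list(question_id = question$question_id,
                   resolved = names(manifest$resolved),
                   failures = manifest$failures))
  }

  debug_round <- 0L
  env_repairs <- 0L
  verdict <- NULL
  narrative <- NULL
  report_i <- NULL
  repeat {
    execution <- tryCatch(
      execute_artifact(artifact, limits = config$limits),
      adra_environment_error = function(e) e)
    if (inherits(execution, "condition")) {
      # No interpreter at all: synthesize a failed execution so the ledger
      # and verdict stay well-formed, and route to environment repair.
      execution <- structure(
        list(version = artifact$version, exit_status = 127L,
             stdout = "", stderr = paste0(conditionMessage(execution),
                                          ": command not found"),
             outputs = character(0), duration = 0, timed_out = FALSE,
             sandbox = NULL, env_ref = NULL),
        class = "execution_result")
    }
    add_event(st, "executor", "executed",
              list(question_id = question$question_id,
                   version = execution$version,
                   exit_status = execution$exit_status,
                   timed_out = execution$timed_out,
                   duration = execution$duration))
    report_i <- interpret_result(execution, question, config$provider, store,
                                 provider)
    add_event(st, "resultJudger", "interpreted",
              list(question_id = question$question_id,
                   version = report_i$version,
                   anomalies = length(report_i$anomalies)))
    verdict <- judge_result(report_i, execution, question, selection,
                            config$provider, store, provider)
    add_event(st, "resultJudger", "judged",
              list(question_id = question$question_id,
                   version = execution$version, answered = verdict$answered,
                   dimensions = stats::setNames(
                     verdict$dimension_results$result,
                     verdict$dimension_results$dimension)))
    if (verdict$answered) break
    if (execution$exit_status != 0L &&
        classify_failure(execution) == "environment" && env_repairs < 1L) {
      env_repairs <- env_repairs + 1L
      if (!is.null(config$registry)) configure_environment(artifact, config$registry)
      add_event(st, "dockerMaker", "environment-repair",
                list(question_id = question$question_id,
                     version = artifact$version))
      next
    }
    if (debug_round >= config$max_debug_rounds) {
      add_event(st, "codeDebugger", "budget-exhausted",
                list(question_id = question$question_id,
                     version = artifact$version,
                     rounds = debug_round))
      break
    }
    debug_round <- debug_round + 1L
    fix <- debug_artifact(artifact, verdict, debug_round, config$provider,
                          store, provider,
                          max_debug_rounds = config$max_debug_rounds)
    artifact <- fix$artifact
    add_event(st, "codeDebugger", "patched",
              list(question_id = question$question_id,
                   round = debug_round, version = artifact$version))
  }
  answered <- isTRUE(verdict$answered)
  if (answered) {
    narrative <- analyze_result(verdict, report_i, question, config$provider,
                                store, provider)
    add_event(st, "resultAnalyzer", "narrated",
              list(question_id = question$question_id,
                   conclusion = narrative$conclusion))
  }
  list(question = question, selection = selection, plan = plan,
       artifact = artifact, verdict = verdict, narrative = narrative,
       answered = answered,
       resolved_debug_round = if (answered) debug_round else NA_integer_,
       n_subquestions = sub_question_count(plan))
}

#' Run one autonomous research cycle
#'
#' @param config a [run_config()].
#' @param provider optional provider object overriding the registry lookup
#'   (a [scripted_provider()] makes the whole run a deterministic replay).
#' @return object of class `run_ledger`: `config` (dataset id, seed,
#'   ablation, prompt mode), `events` (append-only, strictly ordered),
#'   `questions` (data.frame summary per question), `summary` (terminal
#'   counts and rates), plus `records` (full per-question solve records).
#' @export
run_cycle <- function(config, provider = NULL) {
  store <- template_store(mode = config$prompt_mode)
  st <- new_ledger_state()
  tab <- load_table(config$dataset_path, delim = config$delim)
  profiles <- profile_variables(tab, descriptions = config$descriptions)
  add_event(st, "dataInterpreter", "profiled",
            list(dataset_id = config$dataset_id, n_rows = nrow(tab),
                 n_variables = length(profiles)))
  cleaning_log <- character(0)
  if (!"dataCleaner" %in% config$ablation) {
    cleaned <- clean_data(tab, config$cleaning)
    tab <- cleaned$table
    cleaning_log <- cleaned$log
    profiles <- profile_variables(tab, descriptions = config$descriptions)
    add_event(st, "dataCleaner", "cleaned",
              list(edits = length(cleaning_log), n_rows = nrow(tab)))
  }
  pairs <- build_pairs(profiles, config$provider, store, provider)
  add_event(st, "dataInterpreter", "paired", list(n_pairs = length(pairs)))
  report <- data_report(config$dataset_id, tab, profiles, pairs, cleaning_log)

  candidates <- raise_questions(report, config$n_candidates, config$provider,
                                store, provider)
  add_event(st, "questionRaiser", "raised",
            list(n = length(candidates),
                 dropped = length(attr(candidates, "dropped"))))
  rev <- if (length(candidates)) {
    review_questions(candidates, config$provider, store, provider)
  } else list(retained = list(), rejected = list(),
              decisions = data.frame())
  add_event(st, "questionRaiser", "reviewed",
            list(retained = length(rev$retained),
                 rejected = length(rev$rejected)))

  queue <- rev$retained
  records <- list()
  all_questions <- c(rev$retained, rev$rejected)
  while (length(queue)) {
    q <- queue[[1]]
    queue <- queue[-1]
    rec <- tryCatch(
      solve_question(q, report, config, store, provider, st),
      adra_error = function(e) {
        add_event(st, "orchestrator", "question-error",
                  list(question_id = q$question_id,
                       error = conditionMessage(e)))
        NULL
      })
    if (is.null(rec)) {
      q$status <- "unanswered"
      records[[q$question_id]] <- list(question = q, answered = FALSE,
                                       resolved_debug_round = NA_integer_,
                                       n_subquestions = NA_integer_)
      next
    }
    rec$question$status <- if (rec$answered) "answered" else "unanswered"
    records[[q$question_id]] <- rec
    if (rec$answered) {
      if (!is.null(config$corpus)) {
        lv <- validate_literature(rec$question, config$corpus,
                                  config$provider, store, provider)
        add_event(st, "resultValidator", "literature",
                  list(question_id = q$question_id,
                       previously_studied = lv$previously_studied,
                       supporting = lv$supporting_records))
      }
      if (!is.null(config$catalog)) {
        matches <- match_datasets(rec$question, config$catalog,
                                  config$provider, store, provider)
        add_event(st, "resultValidator", "datasets-matched",
                  list(question_id = q$question_id, matches = matches))
      }
      if (rec$question$round < config$max_evolution_rounds) {
        follow_ups <- deepen_question(rec$question, rec$narrative,
                                      config$provider, store, provider,
                                      n_follow_ups = config$n_follow_ups)
        add_event(st, "deepQuestioner", "deepened",
                  list(question_id = q$question_id,
                       n_follow_ups = length(follow_ups),
                       round = rec$question$round + 1L))
        if (length(follow_ups)) {
          frev <- review_questions(follow_ups, config$provider, store,
                                   provider)
          add_event(st, "questionRaiser", "reviewed",
                    list(retained = length(frev$retained),
                         rejected = length(frev$rejected)))
          queue <- c(queue, frev$retained)
          all_questions <- c(all_questions, frev$retained, frev$rejected)
        }
      }
    }
  }

  qdf <- do.call(rbind, lapply(records, function(r) data.frame(
    question_id = r$question$question_id,
    parent_id = r$question$parent_id %||% NA_character_,
    round = r$question$round, status = r$question$status,
    resolved_debug_round = r$resolved_debug_round,
    n_subquestions = r$n_subquestions, stringsAsFactors = FALSE)))
  if (is.null(qdf)) qdf <- data.frame(
    question_id = character(0), parent_id = character(0), round = integer(0),
    status = character(0), resolved_debug_round = integer(0),
    n_subquestions = integer(0), stringsAsFactors = FALSE)
  rownames(qdf) <- NULL
  summary <- list(
    raised = length(candidates), retained = length(rev$retained),
    attempted = nrow(qdf),
    answered = sum(qdf$status == "answered"),
    unanswered = sum(qdf$status == "unanswered"),
    total_subquestions = sum(qdf$n_subquestions, na.rm = TRUE),
    mean_subquestions = if (nrow(qdf)) mean(qdf$n_subquestions, na.rm = TRUE)
                        else NA_real_)
  add_event(st, "orchestrator", "terminal", summary)
  structure(
    list(config = list(dataset_id = config$dataset_id, seed = config$seed,
                       ablation = config$ablation,
                       prompt_mode = config$prompt_mode,
                       max_debug_rounds = config$max_debug_rounds,
                       max_evolution_rounds = config$max_evolution_rounds),
         events = st$events, questions = qdf, summary = summary,
         records = records),
    class = "run_ledger"
  )
}

#' Pass rate by debug round
#'
#' Rate at round r is the fraction of attempted questions answered at debug
#' round r or earlier (round 0 is the original code); non-decreasing in r by
#' construction.
#'
#' @param ledger a `run_ledger`.
#' @param max_rounds highest round to report (defaults to the run's budget).
#' @return named numeric vector, names `"0"`..`"max_rounds"`.
#' @export
pass_rate_by_round <- function(ledger, max_rounds = NULL) {
  max_rounds <- max_rounds %||% ledger$config$max_debug_rounds
  qdf <- ledger$questions
  n <- nrow(qdf)
  rates <- vapply(0:max_rounds, function(r) {
    if (n == 0) return(0)
    mean(!is.na(qdf$resolved_debug_round) & qdf$resolved_debug_round <= r)
  }, numeric(1))
  stats::setNames(rates, as.character(0:max_rounds))
}

# Recursively drop volatile fields so replayed ledgers compare byte-equal.
strip_volatile <- function(x) {
  if (is.list(x)) {
    x[names(x) %in% c("timestamp", "duration", "sandbox")] <- NULL
    lapply(x, strip_volatile)
  } else x
}

#' Deterministic fingerprint of a ledger
#'
#' Serializes the ledger's events and summary with timestamps, durations and
#' sandbox paths removed; two replays of the same transcript yield identical
#' fingerprints.
#'
#' @param ledger a `run_ledger`.
#' @return character scalar hash.
#' @export
ledger_fingerprint <- function(ledger) {
  core <- list(config = ledger$config,
               events = strip_volatile(ledger$events),
               questions = ledger$questions,
               summary = ledger$summary)
  content_hash(jsonlite::toJSON(core, auto_unbox = TRUE, digits = NA,
                                null = "null", force = TRUE))
}

#' Persist / load a run ledger as JSON Lines
#'
#' One event per line, followed by one `summary` line and one `questions`
#' line.
#'
#' @param ledger a `run_ledger`.
#' @param path file path.
#' @return `path` invisibly; `read_ledger()` returns a list with `events`,
#'   `summary`, `questions`, `config`.
#' @export
write_ledger <- function(ledger, path) {
  lines <- c(
    lapply(ledger$events, function(e) c(list(record = "event"), e)),
    list(c(list(record = "config"), ledger$config)),
    list(list(record = "summary", summary = ledger$summary)),
    list(list(record = "questions",
              questions = ledger$questions)))
  write_jsonl(lines, path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  recs <- read_jsonl(path)
  kinds <- vapply(recs, function(r) r$record, character(1))
  list(events = lapply(recs[kinds == "event"], function(r) r[-1]),
       config = recs[kinds == "config"][[1]][-1],
       summary = recs[kinds == "summary"][[1]]$summary,
       questions = as.data.frame(recs[kinds == "questions"][[1]]$questions,
                                 stringsAsFactors = FALSE))
}

#' @export
print.run_ledger <- function(x, ...) {
  cat("<run_ledger>", x$config$dataset_id, "\n")
  cat(sprintf("  questions: %d attempted, %d answered, %d unanswered\n",
              x$summary$attempted, x$summary$answered, x$summary$unanswered))
  cat(sprintf("  sub-questions: %d total (mean %.2f per question)\n",
              x$summary$total_subquestions, x$summary$mean_subquestions))
  cat(sprintf("  events: %d\n", length(x$events)))
  invisible(x)
}
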