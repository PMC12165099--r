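#' Result adjudication, debugging, and narration
#'
#' Two-step judging: an Interpreter summarizes the execution output, then a
#' Judger decides whether the question was answered on four dimensions —
#' error (any execution error fails mechanically, with no provider call),
#' question (the specific question is addressed), variable (confounders
#' appropriately considered) and process (methodology and logic correctly
#' followed). A question is answered only when all four pass. Failing code
#' is repaired by a Debugger + Merger pair within a bounded number of rounds
#' (default 4); failures that look environmental (missing interpreters or
#' commands) are routed to environment configuration instead of the
#' debugger.
#'
#' @name adjudication
NULL

judge_dimensions <- c("error", "question", "variable", "process")

#' Interpret an execution result
#'
#' Produces a report even for failed executions; a nonzero exit contributes
#' the head of stderr to the anomaly list without consulting the provider.
#'
#' @param execution an `execution_result`.
#' @param question the `research_question` under analysis.
#' @param config,store,provider provider plumbing.
#' @return object of class `interpretation_report`: `question_id`, `version`,
#'   `summary`, `extracted_quantities` (named numeric), `anomalies`.
#' @export
interpret_result <- function(execution, question, config,
                             store = template_store(), provider = NULL) {
  anomalies <- character(0)
  if (execution$exit_status != 0L) {
    head_err <- substr(execution$stderr, 1, 500)
    anomalies <- c(anomalies, paste0("nonzero exit (",
                                     execution$exit_status, "): ", head_err))
  }
  if (isTRUE(execution$timed_out))
    anomalies <- c(anomalies, "execution timed out")
  check <- function(parsed) {
    if (!is.list(parsed) || is.null(parsed$summary))
      return("expected JSON object with 'summary'")
    NULL
  }
  parsed <- render_and_ask(
    config, store, "interpret_result",
    bindings = list(question = question$text,
                    stdout = substr(execution$stdout, 1, 4000),
                    stderr = substr(execution$stderr, 1, 2000),
                    exit_status = execution$exit_status),
    check = check, provider = provider)
  q <- parsed$quantities %||% list()
  quantities <- if (length(q))
    stats::setNames(as.numeric(unlist(q)), names(unlist(q)))
  else stats::setNames(numeric(0), character(0))
  structure(
    list(question_id = question$question_id, version = execution$version,
         summary = as.character(parsed$summary)[1],
         extracted_quantities = quantities,
         anomalies = c(anomalies, as.character(unlist(parsed$anomalies %||% character(0))))),
    class = "interpretation_report"
  )
}

#' Judge whether an execution answered the question
#'
#' The error dimension is decided mechanically from the exit status: a
#' nonzero exit fails it — and therefore the verdict — with zero provider
#' calls, and the remaining dimensions are marked failed as not assessed.
#' On a clean exit, one provider call adjudicates the question, variable and
#' process dimensions given the interpretation report, output tails and
#' variable selection. A detailed feedback text is always populated.
#'
#' @param report the `interpretation_report` for this execution.
#' @param execution the `execution_result` (same artifact version).
#' @param question the `research_question`.
#' @param selection the `variable_selection` (may be NULL when the selector
#'   was ablated).
#' @param config,store,provider provider plumbing.
#' @return object of class `verdict`: `question_id`, `answered`,
#'   `dimension_results` (data.frame of `dimension`, `result`, `reason`),
#'   `feedback`, optional `confidence` in \[0,1\].
#' @export
judge_result <- function(report, execution, question, selection = NULL,
                         config, store = template_store(), provider = NULL) {
  if (report$version != execution$version)
    adra_abort("precondition",
               "report and execution refer to different artifact versions")
  if (execution$exit_status != 0L) {
    dims <- data.frame(
      dimension = judge_dimensions,
      result = c("fail", rep("fail", 3)),
      reason = c(paste0("execution error, exit ", execution$exit_status,
                        if (isTRUE(execution$timed_out)) " (timeout)" else ""),
                 rep("not assessed: execution failed", 3)),
      stringsAsFactors = FALSE)
    return(structure(
      list(question_id = question$question_id, answered = FALSE,
           dimension_results = dims,
           feedback = paste0("Execution failed before any result could be ",
                             "assessed. stderr: ",
                             substr(execution$stderr, 1, 500)),
           confidence = NULL),
      class = "verdict"))
  }
  provider_dims <- setdiff(judge_dimensions, "error")
  check <- function(parsed) {
    if (!is.list(parsed)) return("expected a JSON object")
    for (d in provider_dims) {
      v <- parsed[[d]]
      if (is.null(v) || !as.character(v) %in% c("pass", "fail"))
        return(paste0("dimension '", d, "' must be 'pass' or 'fail'"))
    }
    if (is.null(parsed$feedback)) return("missing 'feedback'")
    if (!is.null(parsed$confidence)) {
      cv <- suppressWarnings(as.numeric(parsed$confidence))
      if (is.na(cv) || cv < 0 || cv > 1) return("confidence must be in [0,1]")
    }
    NULL
  }
  parsed <- render_and_ask(
    config, store, "judge_result",
    bindings = list(
      question = question$text,
      summary = report$summary,
      quantities = paste(names(report$extracted_quantities),
                         report$extracted_quantities,
                         sep = "=", collapse = ", "),
      stdout_tail = substr(execution$stdout,
                           max(1, nchar(execution$stdout) - 2000),
                           nchar(execution$stdout)),
      variables = if (is.null(selection)) "(no variable selection)" else
        paste(selection$primary_variables, collapse = ", "),
      confounders = if (is.null(selection)) "(none)" else
        paste(selection$confounders, collapse = ", ")),
    check = check, provider = provider)
  results <- c("pass", vapply(provider_dims, function(d)
    as.character(parsed[[d]]), character(1)))
  reasons <- c("exit status 0", vapply(provider_dims, function(d)
    as.character(parsed[[paste0(d, "_reason")]] %||% ""), character(1)))
  dims <- data.frame(dimension = judge_dimensions, result = results,
                     reason = reasons, stringsAsFactors = FALSE)
  structure(
    list(question_id = question$question_id,
         answered = all(dims$result == "pass"),
         dimension_results = dims,
         feedback = as.character(parsed$feedback)[1],
         confidence = if (!is.null(parsed$confidence))
           as.numeric(parsed$confidence) else NULL),
    class = "verdict"
  )
}

# Shell "command not found" comes as "foo: command not found" (bash) or
# "foo: not found" (dash); R's "object 'x' not found" must stay a code error.
env_error_patterns <- c("command not found", ": not found",
                        "No such file or directory.*(interpreter|Rscript|python|perl)",
                        "no interpreter", "cannot open shared object",
                        "error while loading shared libraries",
                        "there is no package called")

#' Classify an execution failure as environmental or code
#'
#' Pattern-matched on stderr (the pattern list is user-extensible):
#' missing-command and missing-library signatures route to environment
#' configuration, everything else to the code debugger.
#'
#' @param execution a failed `execution_result`.
#' @param patterns regex vector of environmental signatures.
#' @return `"environment"` or `"code"`.
#' @export
classify_failure <- function(execution, patterns = env_error_patterns) {
  if (any(vapply(patterns, function(p)
    grepl(p, execution$stderr, ignore.case = TRUE), logical(1))))
    "environment" else "code"
}

#' Repair a failing artifact (one debug round)
#'
#' Two provider steps: the Debugger proposes a corrected fragment from the
#' verdict feedback, then the Merger integrates fragment and original into a
#' complete script. The new artifact's version is the base version plus one;
#' a round beyond `max_debug_rounds` signals a budget-exhausted error, the
#' terminal unanswered state.
#'
#' @param artifact the failing [code_artifact()].
#' @param verdict the unanswered `verdict`.
#' @param round debug round number, 1-based.
#' @param config,store,provider provider plumbing.
#' @param max_debug_rounds bound on repair rounds (default 4).
#' @return list with `patch` (class `debug_patch`: `base_version`,
#'   `corrected_fragment`, `merged_source`, `round`) and `artifact` (the new
#'   [code_artifact()]).
#' @export
debug_artifact <- function(artifact, verdict, round, config,
                           store = template_store(), provider = NULL,
                           max_debug_rounds = 4L) {
  if (isTRUE(verdict$answered))
    adra_abort("precondition", "cannot debug an answered verdict")
  if (round > max_debug_rounds)
    adra_abort("budget_exhausted",
               paste0("debug budget exhausted after ", max_debug_rounds,
                      " rounds"))
  check_frag <- function(parsed) {
    if (!is.list(parsed) || is.null(parsed$fragment) ||
        !nzchar(trimws(as.character(parsed$fragment)[1])))
      return("expected JSON object with non-empty 'fragment'")
    NULL
  }
  frag <- render_and_ask(
    config, store, "debug_fragment",
    bindings = list(source = artifact$source, feedback = verdict$feedback),
    check = check_frag, provider = provider)
  fragment <- as.character(frag$fragment)[1]
  check_merge <- function(parsed) {
    if (!is.list(parsed) || is.null(parsed$source) ||
        !nzchar(trimws(as.character(parsed$source)[1])))
      return("expected JSON object with non-empty 'source'")
    NULL
  }
  merged <- render_and_ask(
    config, store, "merge_code",
    bindings = list(source = artifact$source, fragment = fragment),
    check = check_merge, provider = provider)
  merged_source <- as.character(merged$source)[1]
  new_artifact <- code_artifact(
    artifact$question_id, artifact$language, merged_source,
    required_software = artifact$required_software,
    version = artifact$version + 1L)
  patch <- structure(
    list(base_version = artifact$version, corrected_fragment = fragment,
         merged_source = merged_source, round = as.integer(round)),
    class = "debug_patch")
  list(patch = patch, artifact = new_artifact)
}

#' Narrate an answered result
#'
#' Turns an answered verdict's interpretation into a conclusion and effect
#' statements for validation and deepening. Calling it on an unanswered
#' verdict is a precondition error: narratives exist only for answered
#' questions.
#'
#' @param verdict an answered `verdict`.
#' @param report the `interpretation_report`.
#' @param question the `research_question`.
#' @param config,store,provider provider plumbing.
#' @return object of class `analysis_narrative`: `question_id`,
#'   `conclusion`, `effect_statements`, `primary_quantity` (named numeric of
#'   length 0 or 1, carried from the report for consistency checks).
#' @export
analyze_result <- function(verdict, report, question, config,
                           store = template_store(), provider = NULL) {
  if (!isTRUE(verdict$answered))
    adra_abort("precondition", "narratives exist only for answered verdicts")
  check <- function(parsed) {
    if (!is.list(parsed) || is.null(parsed$conclusion))
      return("expected JSON object with 'conclusion'")
    NULL
  }
  parsed <- render_and_ask(
    config, store, "analyze_result",
    bindings = list(question = question$text, summary = report$summary,
                    quantities = paste(names(report$extracted_quantities),
                                       report$extracted_quantities,
                                       sep = "=", collapse = ", ")),
    check = check, provider = provider)
  structure(
    list(question_id = question$question_id,
         conclusion = as.character(parsed$conclusion)[1],
         effect_statements = as.character(unlist(parsed$effects %||% character(0))),
         primary_quantity = utils::head(report$extracted_quantities, 1)),
    class = "analysis_narrative"
  )
}
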