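#' Question solving: variables, plan, code, execution
#'
#' Turns a research question into a variable selection, a chain-of-thought
#' task plan with tool recommendations, a runnable analysis script, and a
#' captured execution result. For fixed transcripts and inputs the whole
#' chain is bit-reproducible except wall-clock durations.
#'
#' @name solver
NULL

#' Select analysis variables for a question
#'
#' The provider proposes primary variables and potential confounders from the
#' profiled schema. Unknown names trigger one re-ask and then a
#' provider-format error. If a variable appears in both sets, the primary
#' role wins and it is dropped from the confounders (logged in the
#' `resolution_log` attribute): confounders are adjustments, not exposures.
#'
#' @param question a `research_question`.
#' @param report the [data_report()].
#' @param config,store,provider provider plumbing as elsewhere.
#' @return object of class `variable_selection` with `question_id`,
#'   `primary_variables`, `confounders`, `rationale`.
#' @export
select_variables <- function(question, report, config,
                             store = template_store(), provider = NULL) {
  known <- report_variable_names(report, include_identifiers = TRUE)
  check <- function(parsed) {
    if (!is.list(parsed) || is.null(parsed$primary))
      return("expected JSON object with 'primary' and 'confounders'")
    unknown <- setdiff(c(unlist(parsed$primary), unlist(parsed$confounders)),
                       known)
    if (length(unknown)) return(paste0("unknown variable: ", unknown[1]))
    if (length(unlist(parsed$primary)) == 0) return("'primary' must be non-empty")
    NULL
  }
  parsed <- render_and_ask(
    config, store, "select_variables",
    bindings = list(question = question$text,
                    data_report = report_text(report)),
    check = check, provider = provider)
  primary <- as.character(unlist(parsed$primary))
  confounders <- as.character(unlist(parsed$confounders))
  overlap <- intersect(primary, confounders)
  log <- character(0)
  if (length(overlap)) {
    confounders <- setdiff(confounders, primary)
    log <- paste0("dropped from confounders (already primary): ", overlap)
  }
  structure(
    list(question_id = question$question_id,
         primary_variables = primary, confounders = confounders,
         rationale = as.character(parsed$rationale %||% "")),
    class = "variable_selection", resolution_log = log
  )
}

#' Plan analysis tasks for a question
#'
#' Chain-of-thought planning: the provider breaks the question into an
#' ordered sequence of steps, each with recommended tools. Steps arriving
#' with non-contiguous indices are renumbered 1..n (a warning entry is kept
#' in the `warnings` attribute); tools present in `registry` are marked
#' registry tools, all others external.
#'
#' @param question a `research_question`.
#' @param selection a `variable_selection`.
#' @param config,store,provider provider plumbing.
#' @param registry optional [tool_registry()] used to flag recommended tools.
#' @return object of class `task_plan` with `question_id`, `steps`
#'   (data.frame of `index`, `description`, `tools` list-column,
#'   `external` list-column) and `language_hint`.
#' @export
plan_tasks <- function(question, selection, config, store = template_store(),
                       provider = NULL, registry = NULL) {
  check <- function(parsed) {
    steps <- parsed$steps
    if (is.null(steps)) return("expected JSON object with 'steps'")
    df <- tryCatch(as.data.frame(steps, stringsAsFactors = FALSE),
                   error = function(e) NULL)
    if (is.null(df) || nrow(df) == 0) return("plan must contain at least one step")
    if (!"description" %in% names(df)) return("steps need 'description'")
    NULL
  }
  parsed <- render_and_ask(
    config, store, "plan_tasks",
    bindings = list(
      question = question$text,
      variables = paste(selection$primary_variables, collapse = ", "),
      confounders = paste(selection$confounders, collapse = ", ")),
    check = check, provider = provider)
  df <- as.data.frame(parsed$steps, stringsAsFactors = FALSE)
  warnings <- character(0)
  idx <- if ("index" %in% names(df)) as.integer(df$index) else seq_len(nrow(df))
  df <- df[order(idx), , drop = FALSE]
  idx <- sort(idx)
  if (!identical(idx, seq_len(nrow(df)))) {
    warnings <- sprintf("renumbered steps: received indices %s",
                        paste(idx, collapse = ","))
  }
  tools <- if ("tools" %in% names(df)) {
    lapply(seq_len(nrow(df)), function(i) as.character(unlist(df$tools[i])))
  } else rep(list(character(0)), nrow(df))
  registered <- if (is.null(registry)) character(0) else registry_tools(registry)
  steps <- data.frame(index = seq_len(nrow(df)),
                      description = df$description,
                      stringsAsFactors = FALSE)
  steps$tools <- tools
  steps$external <- lapply(tools, function(tl) setdiff(tl, registered))
  structure(
    list(question_id = question$question_id, steps = steps,
         language_hint = as.character(parsed$language %||% "r")),
    class = "task_plan", warnings = warnings
  )
}

#' Number of sub-questions in a plan
#'
#' One plan step is one sub-question, the unit of efficiency accounting.
#'
#' @param plan a `task_plan`.
#' @return integer step count.
#' @export
sub_question_count <- function(plan) nrow(plan$steps)

supported_languages <- c("shell", "r", "python", "perl")

#' Construct a code artifact
#' @param question_id owning question.
#' @param language one of shell, r, python, perl.
#' @param source non-empty script text.
#' @param required_software tools the script needs, in plan order.
#' @param version artifact version, starting at 1 and incremented by debug.
#' @return object of class `code_artifact`.
#' @export
code_artifact <- function(question_id, language, source,
                          required_software = character(0), version = 1L) {
  if (!language %in% supported_languages)
    adra_abort("domain", paste0("unsupported language: ", language))
  if (!nzchar(trimws(source)))
    adra_abort("provider_format", "artifact source must be non-empty")
  if (version < 1L) adra_abort("domain", "version must be >= 1")
  structure(list(question_id = question_id, language = language,
                 source = source,
                 required_software = as.character(required_software),
                 version = as.integer(version)),
            class = "code_artifact")
}

# Language detection precedence: transcript metadata > shebang > extension
# hint; unresolvable means shell.
detect_language <- function(meta_language = NULL, source = "", hint = NULL) {
  if (!is.null(meta_language) && nzchar(meta_language) &&
      meta_language %in% supported_languages)
    return(meta_language)
  first <- strsplit(source, "\n", fixed = TRUE)[[1]][1]
  if (is.na(first)) first <- ""
  if (startsWith(first, "#!")) {
    if (grepl("Rscript", first)) return("r")
    if (grepl("python", first)) return("python")
    if (grepl("perl", first)) return("perl")
    if (grepl("(ba|z|da)?sh", first)) return("shell")
  }
  if (!is.null(hint)) {
    ext <- tolower(tools::file_ext(hint))
    lang <- c(r = "r", py = "python", pl = "perl", sh = "shell")[ext]
    if (!is.na(lang)) return(unname(lang))
  }
  "shell"
}

#' Generate analysis code for a plan
#'
#' The provider returns the script plus optional metadata (`language`,
#' `filename`). The artifact's required software is the ordered union of the
#' plan's recommended tools.
#'
#' @param plan a `task_plan`.
#' @param selection the `variable_selection`.
#' @param report the [data_report()].
#' @param config,store,provider provider plumbing.
#' @return a [code_artifact()] at version 1.
#' @export
make_code <- function(plan, selection, report, config,
                      store = template_store(), provider = NULL) {
  check <- function(parsed) {
    if (!is.list(parsed) || is.null(parsed$source) ||
        !nzchar(trimws(as.character(parsed$source)[1])))
      return("expected JSON object with non-empty 'source'")
    NULL
  }
  steps_text <- paste(sprintf("%d. %s", plan$steps$index,
                              plan$steps$description), collapse = "\n")
  parsed <- render_and_ask(
    config, store, "make_code",
    bindings = list(steps = steps_text,
                    variables = paste(selection$primary_variables, collapse = ", "),
                    confounders = paste(selection$confounders, collapse = ", "),
                    dataset_id = report$dataset_id,
                    language = plan$language_hint),
    check = check, provider = provider)
  source <- as.character(parsed$source)[1]
  language <- detect_language(parsed$language, source, parsed$filename)
  tools <- unique(unlist(plan$steps$tools))
  code_artifact(plan$question_id, language, source,
                required_software = as.character(tools %||% character(0)))
}

interpreter_for <- c(r = "Rscript", python = "python", shell = "sh",
                     perl = "perl")

#' Execution limits
#' @param timeout wall-clock cap in seconds (default 600).
#' @param max_output_bytes per-stream captured-output cap (default 10 MB).
#' @param interpreters named character vector overriding the
#'   language-to-interpreter mapping (used to point at container runtimes).
#' @return object of class `execution_limits`.
#' @export
execution_limits <- function(timeout = 600, max_output_bytes = 10e6,
                             interpreters = interpreter_for) {
  structure(list(timeout = timeout, max_output_bytes = max_output_bytes,
                 interpreters = interpreters),
            class = "execution_limits")
}

#' Execute a code artifact in a sandbox directory
#'
#' Each execution gets a fresh temporary working directory; the script may
#' write outputs only there. Datasets should be passed by absolute path and
#' opened read-only by the generated code. Stdout and stderr are captured in
#' full up to the per-stream cap; a timeout is recorded as a nonzero exit
#' with `timed_out = TRUE`. A missing interpreter raises an environment
#' error (condition class `adra_environment_error`), which the orchestrator
#' routes to environment configuration rather than the code debugger.
#'
#' @param artifact a [code_artifact()].
#' @param env optional environment manifest reference recorded on the result.
#' @param limits an [execution_limits()].
#' @return object of class `execution_result` with `version`, `exit_status`,
#'   `stdout`, `stderr`, `outputs`, `duration`, `timed_out`, `sandbox`,
#'   `env_ref`.
#' @export
execute_artifact <- function(artifact, env = NULL,
                             limits = execution_limits()) {
  interp <- limits$interpreters[[artifact$language]]
  if (is.null(interp) || !nzchar(Sys.which(interp)))
    adra_abort("environment_error",
               paste0("no interpreter for language '", artifact$language,
                      "' (looked for '", interp %||% "?", "')"),
               data = list(language = artifact$language))
  sandbox <- tempfile("adra-sandbox-")
  dir.create(sandbox)
  ext <- c(r = "R", python = "py", shell = "sh", perl = "pl")[[artifact$language]]
  script <- file.path(sandbox, paste0("analysis.", ext))
  writeLines(artifact$source, script)
  out_file <- file.path(sandbox, ".stdout")
  err_file <- file.path(sandbox, ".stderr")
  old <- setwd(sandbox)
  on.exit(setwd(old), add = TRUE)
  t0 <- Sys.time()
  status <- suppressWarnings(system2(
    interp, shQuote(script), stdout = out_file, stderr = err_file,
    timeout = limits$timeout))
  duration <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  setwd(old)
  timed_out <- identical(status, 124L)
  read_capped <- function(f) {
    if (!file.exists(f)) return("")
    txt <- paste(readLines(f, warn = FALSE), collapse = "\n")
    if (nchar(txt, type = "bytes") > limits$max_output_bytes)
      txt <- substr(txt, 1, limits$max_output_bytes)
    txt
  }
  outputs <- setdiff(list.files(sandbox), basename(c(script, out_file, err_file)))
  structure(
    list(version = artifact$version, exit_status = as.integer(status),
         stdout = read_capped(out_file), stderr = read_capped(err_file),
         outputs = outputs, duration = duration, timed_out = timed_out,
         sandbox = sandbox, env_ref = env),
    class = "execution_result"
  )
}
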