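#' Research questions: raising, reviewing, deepening
#'
#' Candidate questions are generated from a data report (the raiser), then
#' filtered for research value (the reviewer, a second provider step), and —
#' once answered — deepened into follow-up questions that carry full lineage
#' through evolution rounds.
#'
#' @name question-engine
NULL

#' Construct a research question
#'
#' Question ids are a content hash of the question text plus dataset id, so a
#' replayed run produces identical ids and ledgers can be compared across
#' runs.
#'
#' @param text question text.
#' @param dataset_id dataset the question is about.
#' @param source `"raiser"`, `"deep"` or `"external"`.
#' @param parent_id id of the deepened parent (required when source is
#'   `"deep"`).
#' @param round evolution round; 0 exactly for raiser/external questions.
#' @param status one of `"open"`, `"answered"`, `"unanswered"`, `"invalid"`.
#' @return object of class `research_question`.
#' @export
research_question <- function(text, dataset_id,
                              source = c("raiser", "deep", "external"),
                              parent_id = NULL, round = 0L,
                              status = "open") {
  source <- match.arg(source)
  round <- as.integer(round)
  if (source %in% c("raiser", "external") && round != 0L)
    adra_abort("domain", "raiser/external questions must be round 0")
  if (source == "deep" && (is.null(parent_id) || round < 1L))
    adra_abort("domain", "deep questions need a parent and round >= 1")
  structure(
    list(question_id = paste0("q-", content_hash(c(text, dataset_id, round,
                                                   parent_id %||% ""))),
         text = text, dataset_id = dataset_id, source = source,
         parent_id = parent_id, round = round, status = status,
         score_card = NULL),
    class = "research_question"
  )
}

#' @export
print.research_question <- function(x, ...) {
  cat(sprintf("<research_question %s> round %d [%s, %s]\n  %s\n",
              x$question_id, x$round, x$source, x$status, x$text))
  invisible(x)
}

# Questions must mention at least one profiled variable by name; candidates
# that do not are dropped with a logged reason, not errors (the provider is
# allowed to be imperfect, the pipeline is not).
mentions_variable <- function(text, variables) {
  any(vapply(variables, function(v)
    grepl(v, text, fixed = TRUE), logical(1)))
}

#' Raise candidate research questions from a data report
#'
#' One provider call produces up to `n_candidates` candidates; candidates
#' that mention no profiled variable are dropped (with the drop recorded in
#' the `dropped` attribute). Raising uses the provider's default temperature
#' by design: ideation benefits from sampling diversity.
#'
#' @param report a [data_report()].
#' @param n_candidates maximum number of candidates; 0 returns an empty list
#'   without any provider call.
#' @param config a [provider_config()].
#' @param store a [template_store()].
#' @param provider optional provider override.
#' @return list of round-0 `research_question`s with attribute `dropped`
#'   (character vector of rejected candidate texts and reasons).
#' @export
raise_questions <- function(report, n_candidates = 100L, config,
                            store = template_store(), provider = NULL) {
  vars <- report_variable_names(report)
  if (length(vars) == 0)
    adra_abort("empty_input", "report has no non-identifier variable")
  if (n_candidates == 0L) return(structure(list(), dropped = character(0)))
  check <- function(parsed) {
    if (!is.character(parsed) || length(parsed) < 1)
      return("expected a JSON array of question strings")
    NULL
  }
  texts <- render_and_ask(
    config, store, "raise_questions",
    bindings = list(data_report = report_text(report),
                    n_candidates = n_candidates),
    check = check, provider = provider)
  texts <- utils::head(texts, n_candidates)
  keep <- vapply(texts, mentions_variable, logical(1), variables = vars)
  dropped <- if (any(!keep))
    paste0("dropped (mentions no profiled variable): ", texts[!keep])
  else character(0)
  qs <- lapply(texts[keep], research_question, dataset_id = report$dataset_id,
               source = "raiser")
  structure(qs, dropped = dropped)
}

#' Review candidate questions for research value
#'
#' A second provider step returns one retain/reject decision per candidate.
#' Review never alters question text; rejected questions get status
#' `"invalid"` but are returned alongside the decisions so ledgers keep full
#' lineage.
#'
#' @param candidates non-empty list of `research_question`s.
#' @param config,store,provider as in [raise_questions()].
#' @return list with `retained` (questions still open), `rejected`
#'   (status flipped to invalid) and `decisions` (data.frame of
#'   `question_id`, `retained`, `reason`, one row per candidate).
#' @export
review_questions <- function(candidates, config, store = template_store(),
                             provider = NULL) {
  if (length(candidates) == 0)
    adra_abort("empty_input", "no candidates to review")
  ids <- vapply(candidates, function(q) q$question_id, character(1))
  check <- function(parsed) {
    df <- tryCatch(as.data.frame(parsed, stringsAsFactors = FALSE),
                   error = function(e) NULL)
    if (is.null(df) || !all(c("question_id", "retained") %in% names(df)))
      return("entries need 'question_id' and 'retained'")
    if (nrow(df) != length(ids) || !setequal(df$question_id, ids))
      return(paste0("need exactly one decision per candidate (",
                    length(ids), " expected, ", nrow(df), " received)"))
    NULL
  }
  listing <- paste(vapply(candidates, function(q)
    paste0(q$question_id, ": ", q$text), character(1)), collapse = "\n")
  parsed <- render_and_ask(config, store, "review_questions",
                           bindings = list(questions = listing),
                           check = check, provider = provider)
  df <- as.data.frame(parsed, stringsAsFactors = FALSE)
  df$retained <- as.logical(df$retained)
  if (!"reason" %in% names(df)) df$reason <- ""
  df <- df[match(ids, df$question_id), c("question_id", "retained", "reason")]
  rownames(df) <- NULL
  retained <- candidates[df$retained]
  rejected <- lapply(candidates[!df$retained], function(q) {
    q$status <- "invalid"
    q
  })
  list(retained = retained, rejected = rejected, decisions = df)
}

#' Deepen an answered question into follow-ups
#'
#' Generates follow-up questions from an answered question and its analysis
#' narrative. Outputs carry `source = "deep"`, the parent's id, and the
#' parent's round plus one, so lineage is reconstructible from `parent_id`
#' alone.
#'
#' @param question an answered `research_question`.
#' @param finding the `analysis_narrative` for the question (see
#'   [analyze_result()]).
#' @param config,store,provider as in [raise_questions()].
#' @param n_follow_ups maximum number of follow-ups requested.
#' @return list of round `question$round + 1` questions.
#' @export
deepen_question <- function(question, finding, config,
                            store = template_store(), provider = NULL,
                            n_follow_ups = 3L) {
  if (question$status != "answered")
    adra_abort("precondition", "only answered questions can be deepened")
  check <- function(parsed) {
    if (!is.character(parsed) || length(parsed) < 1)
      return("expected a JSON array of question strings")
    NULL
  }
  texts <- render_and_ask(
    config, store, "deepen_question",
    bindings = list(question = question$text,
                    conclusion = finding$conclusion,
                    n_follow_ups = n_follow_ups),
    check = check, provider = provider)
  lapply(utils::head(texts, n_follow_ups), research_question,
         dataset_id = question$dataset_id, source = "deep",
         parent_id = question$question_id, round = question$round + 1L)
}

#' Reconstruct lineage from a set of questions
#'
#' @param questions list of `research_question`s.
#' @return data.frame of `question_id`, `parent_id`, `round`, `depth` where
#'   depth is the number of parent hops to the round-0 root. Errors if the
#'   parent structure has a cycle or a missing root.
#' @export
question_lineage <- function(questions) {
  ids <- vapply(questions, function(q) q$question_id, character(1))
  parents <- vapply(questions, function(q) q$parent_id %||% NA_character_,
                    character(1))
  rounds <- vapply(questions, function(q) q$round, integer(1))
  depth <- integer(length(ids))
  for (i in seq_along(ids)) {
    seen <- character(0)
    j <- i
    while (!is.na(parents[j])) {
      if (ids[j] %in% seen)
        adra_abort("domain", paste0("lineage cycle at ", ids[j]))
      seen <- c(seen, ids[j])
      nxt <- match(parents[j], ids)
      if (is.na(nxt))
        adra_abort("not_found", paste0("parent not present: ", parents[j]))
      if (rounds[nxt] != rounds[j] - 1L)
        adra_abort("domain", "rounds along lineage must increase by exactly 1")
      j <- nxt
      depth[i] <- depth[i] + 1L
    }
  }
  data.frame(question_id = ids, parent_id = parents, round = rounds,
             depth = depth, stringsAsFactors = FALSE)
}
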