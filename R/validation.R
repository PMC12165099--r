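#' Validation of positive findings
#'
#' Two branches: literature validation decides from a title+abstract corpus
#' whether a question has been studied before (and cites the supporting
#' records), and data validation matches sibling datasets by metadata,
#' re-runs the full solve loop on them, and compares the headline effect for
#' consistency.
#'
#' @name validation
NULL

#' Literature record
#' @param record_id unique id.
#' @param title non-empty title.
#' @param abstract abstract text.
#' @return object of class `literature_record`.
#' @export
literature_record <- function(record_id, title, abstract = "") {
  if (!nzchar(title)) adra_abort("domain", "title must be non-empty")
  structure(list(record_id = record_id, title = title, abstract = abstract),
            class = "literature_record")
}

# Deterministic lexical retrieval: rank records by shared lowercase word
# tokens with the question, keep the top k. Providers see a shortlist, not
# the whole corpus.
rank_corpus <- function(question_text, corpus, k = 20L) {
  tok <- function(x) unique(strsplit(tolower(gsub("[^a-z0-9 ]", " ",
                                                  tolower(x))), "\\s+")[[1]])
  qt <- setdiff(tok(question_text), c("", "is", "the", "a", "of", "in",
                                      "with", "this", "and"))
  overlap <- vapply(corpus, function(r)
    length(intersect(qt, tok(paste(r$title, r$abstract)))), integer(1))
  ord <- order(overlap, decreasing = TRUE)
  corpus[ord[seq_len(min(k, length(corpus)))]]
}

#' Decide whether a question was previously studied
#'
#' The provider receives the question and the top-k lexically matching
#' records and must cite supporting record ids (possibly none). Citations
#' outside the corpus trigger one re-ask, then a provider-format error, so
#' the verdict can never fabricate literature. `previously_studied` is true
#' exactly when at least one record is cited.
#'
#' @param question a `research_question`.
#' @param corpus non-empty list of [literature_record()]s.
#' @param config,store,provider provider plumbing.
#' @param k shortlist size for the lexical pre-filter (default 20).
#' @return object of class `literature_verdict`: `question_id`,
#'   `previously_studied`, `supporting_records`.
#' @export
validate_literature <- function(question, corpus, config,
                                store = template_store(), provider = NULL,
                                k = 20L) {
  if (length(corpus) == 0)
    adra_abort("empty_input", "corpus must be non-empty")
  shortlist <- rank_corpus(question$text, corpus, k)
  ids <- vapply(corpus, function(r) r$record_id, character(1))
  check <- function(parsed) {
    cited <- as.character(unlist(parsed$record_ids %||% character(0)))
    bad <- setdiff(cited, ids)
    if (length(bad)) return(paste0("cited id outside corpus: ", bad[1]))
    NULL
  }
  listing <- paste(vapply(shortlist, function(r)
    paste0(r$record_id, ": ", r$title, " — ", substr(r$abstract, 1, 300)),
    character(1)), collapse = "\n")
  parsed <- render_and_ask(
    config, store, "validate_literature",
    bindings = list(question = question$text, records = listing),
    check = check, provider = provider)
  cited <- as.character(unlist(parsed$record_ids %||% character(0)))
  structure(
    list(question_id = question$question_id,
         previously_studied = length(cited) > 0,
         supporting_records = cited),
    class = "literature_verdict"
  )
}

#' Match sibling datasets for cross-dataset validation
#'
#' @param question a `research_question`.
#' @param catalog list of dataset metadata records, each
#'   `list(dataset_id, description, variables, path)`. An empty catalog
#'   returns an empty match without any provider call.
#' @param config,store,provider provider plumbing.
#' @return character vector of matched dataset ids (possibly empty).
#' @export
match_datasets <- function(question, catalog, config,
                           store = template_store(), provider = NULL) {
  if (length(catalog) == 0) return(character(0))
  ids <- vapply(catalog, function(d) d$dataset_id, character(1))
  check <- function(parsed) {
    got <- as.character(unlist(parsed$dataset_ids %||% character(0)))
    bad <- setdiff(got, ids)
    if (length(bad)) return(paste0("unknown dataset id: ", bad[1]))
    NULL
  }
  listing <- paste(vapply(catalog, function(d)
    paste0(d$dataset_id, ": ", d$description, " [",
           paste(d$variables, collapse = ", "), "]"), character(1)),
    collapse = "\n")
  parsed <- render_and_ask(
    config, store, "match_datasets",
    bindings = list(question = question$text, catalog = listing),
    check = check, provider = provider)
  as.character(unlist(parsed$dataset_ids %||% character(0)))
}

# Sign of the headline effect: ratio-type quantities (odds/hazard/risk
# ratios) are compared on the log scale, everything else on the raw scale.
effect_sign <- function(quantity) {
  if (length(quantity) != 1 || is.na(quantity)) return(NA_integer_)
  name <- tolower(names(quantity) %||% "")
  if (grepl("odds|ratio|\\bor\\b|\\brr\\b|\\bhr\\b|hazard", name))
    sign(log(unname(quantity)))
  else sign(unname(quantity))
}

#' Re-run an answered question on a sibling dataset
#'
#' Invokes the full solve loop (via `solve_fn`, normally a closure around
#' [run_cycle()]'s per-question solver) on the sibling dataset and compares
#' the headline extracted quantity's direction with the original finding:
#' both odds-type quantities below 1 (or above 1) is consistent. When the
#' sibling run is unanswered, consistency is undefined (`NA`) and the notes
#' say why. The original run's ledger is never touched.
#'
#' @param question the original, answered `research_question`.
#' @param original_finding the original `analysis_narrative`.
#' @param dataset_id sibling dataset id.
#' @param solve_fn `function(question, dataset_id)` returning
#'   `list(verdict, narrative)` for the sibling run.
#' @return object of class `cross_dataset_result`: `question_id`,
#'   `dataset_id`, `verdict`, `consistent` (logical or NA),
#'   `comparison_notes`.
#' @export
revalidate <- function(question, original_finding, dataset_id, solve_fn) {
  if (question$status != "answered")
    adra_abort("precondition",
               "only questions answered on their origin dataset are revalidated")
  sibling <- solve_fn(question, dataset_id)
  if (!isTRUE(sibling$verdict$answered)) {
    return(structure(
      list(question_id = question$question_id, dataset_id = dataset_id,
           verdict = sibling$verdict, consistent = NA,
           comparison_notes = "sibling run unanswered; consistency undefined"),
      class = "cross_dataset_result"))
  }
  s0 <- effect_sign(original_finding$primary_quantity)
  s1 <- effect_sign(sibling$narrative$primary_quantity)
  consistent <- if (is.na(s0) || is.na(s1)) NA else s0 == s1
  notes <- if (is.na(consistent))
    "no comparable headline quantity on one side"
  else sprintf("original sign %+d vs sibling sign %+d: %s", s0, s1,
               if (consistent) "consistent" else "inconsistent")
  structure(
    list(question_id = question$question_id, dataset_id = dataset_id,
         verdict = sibling$verdict, consistent = consistent,
         comparison_notes = notes),
    class = "cross_dataset_result"
  )
}
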