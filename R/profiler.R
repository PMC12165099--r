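#' Dataset profiling and cleaning
#'
#' The entry point of every research cycle: load a delimited table, classify
#' each variable, apply a cleaning policy, ask the provider for
#' prior-knowledge variable pairs, and assemble the data report that question
#' generation consumes.
#'
#' @name dataset-profiler
NULL

#' Load a delimited table
#'
#' @param path file path; first row must be a header.
#' @param delim field delimiter, `","` (default) or `"\t"`.
#' @return data.frame with one column per header field, strings kept as-is.
#' @export
load_table <- function(path, delim = ",") {
  if (!file.exists(path)) adra_abort("io", paste0("no such file: ", path))
  if (file.size(path) == 0) adra_abort("empty_input", "empty input file")
  fields <- utils::count.fields(path, sep = delim, quote = "\"")
  if (length(fields) == 0 || all(is.na(fields)))
    adra_abort("empty_input", "empty input file")
  bad <- which(fields != fields[1])
  if (length(bad))
    adra_abort("parse", paste0("ragged row at line ", bad[1] + 0L,
                               ": expected ", fields[1], " fields, found ",
                               fields[bad[1]]))
  tab <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), comment.char = "")
  dup <- names(tab)[duplicated(names(tab))]
  if (length(dup))
    adra_abort("duplicate_column",
               paste0("duplicate column name: ", dup[1]))
  tab
}

#' Profile the variables of a table
#'
#' Classification is a pure function of the table bytes. Default thresholds:
#' at most 2 distinct non-missing values is binary; at most
#' `categorical_max_levels` distinct values that are non-numeric or
#' integer-coded is categorical; anything else numeric is continuous; a
#' column whose name matches `id_pattern` with all-unique values is an
#' identifier; a column parseable as dates is datetime. An all-missing
#' column is profiled as an identifier with `missing_fraction` 1.
#'
#' @param table data.frame from [load_table()].
#' @param descriptions optional named character vector of free-text variable
#'   descriptions.
#' @param categorical_max_levels distinct-value ceiling for categorical.
#' @param id_pattern regex flagging identifier-like column names.
#' @return list of `variable_profile` objects, one per column, in column
#'   order.
#' @export
profile_variables <- function(table, descriptions = NULL,
                              categorical_max_levels = 10L,
                              id_pattern = "(?i)(^id$|_id$|^id_|randid|subject)") {
  if (nrow(table) == 0 || ncol(table) == 0)
    adra_abort("empty_input", "cannot profile an empty table")
  lapply(names(table), function(name) {
    x <- table[[name]]
    n <- length(x)
    miss <- sum(is.na(x)) / n
    xs <- x[!is.na(x)]
    distinct <- unique(xs)
    kind <- if (length(xs) == 0) {
      "identifier"
    } else if (grepl(id_pattern, name, perl = TRUE) &&
               length(distinct) == length(xs)) {
      "identifier"
    } else if (inherits(x, "Date") || inherits(x, "POSIXt")) {
      "datetime"
    } else if (length(distinct) <= 2L) {
      "binary"
    } else if (!is.numeric(x) ||
               (length(distinct) <= categorical_max_levels &&
                all(xs == floor(xs)))) {
      "categorical"
    } else {
      "continuous"
    }
    summary <- switch(kind,
      binary = ,
      categorical = {
        counts <- table(xs)
        list(levels = names(counts), counts = as.integer(counts))
      },
      continuous = list(min = min(xs), median = stats::median(xs),
                        max = max(xs), mean = mean(xs)),
      identifier = list(n_distinct = length(distinct)),
      datetime = list(min = as.character(suppressWarnings(min(xs))),
                      max = as.character(suppressWarnings(max(xs))))
    )
    structure(
      list(name = name, kind = kind, missing_fraction = miss,
           summary = summary,
           description = if (!is.null(descriptions)) descriptions[[name]] else NULL),
      class = "variable_profile"
    )
  })
}

#' Cleaning policy
#'
#' The default policy is deliberately conservative: configured sentinel codes
#' are mapped to missing, and rows missing the outcome are dropped only when
#' an outcome is named (the paper leaves the cleaner's rules open; dropping
#' rows globally would silently shrink every analysis).
#'
#' @param sentinel_codes values recoded to missing wherever they occur.
#' @param drop_missing_outcome optional outcome column name; rows with a
#'   missing outcome are removed.
#' @return object of class `cleaning_policy`.
#' @export
cleaning_policy <- function(sentinel_codes = c(-9), drop_missing_outcome = NULL) {
  structure(list(sentinel_codes = sentinel_codes,
                 drop_missing_outcome = drop_missing_outcome),
            class = "cleaning_policy")
}

#' Clean a table under a policy
#'
#' Idempotent: cleaning a cleaned table is a no-op. Every modification adds
#' one log entry per affected cell (sentinel recodes) or row (outcome drops),
#' so the log length equals the number of edits. Row order is preserved.
#'
#' @param table data.frame.
#' @param policy a [cleaning_policy()].
#' @return list with elements `table` (cleaned) and `log` (character vector).
#' @export
clean_data <- function(table, policy = cleaning_policy()) {
  log <- character(0)
  for (col in names(table)) {
    hits <- which(!is.na(table[[col]]) & table[[col]] %in% policy$sentinel_codes)
    if (length(hits)) {
      table[[col]][hits] <- NA
      log <- c(log, sprintf("recoded sentinel to missing: column %s, row %d",
                            col, hits))
    }
  }
  out <- policy$drop_missing_outcome
  if (!is.null(out)) {
    if (!out %in% names(table))
      adra_abort("not_found", paste0("outcome column not in table: ", out))
    drop <- which(is.na(table[[out]]))
    if (length(drop)) {
      log <- c(log, sprintf("dropped row %d: missing outcome %s", drop, out))
      table <- table[-drop, , drop = FALSE]
      rownames(table) <- NULL
    }
  }
  if (nrow(table) == 0)
    adra_abort("empty_after_cleaning", "cleaning policy removed all rows")
  list(table = table, log = log)
}

valid_pair_relations <- c("outcome_candidate", "exposure_candidate",
                          "confounder_candidate", "demographic")

#' Build prior-knowledge variable pairs
#'
#' Asks the provider to classify profiled variables into roles
#' (outcome / exposure / confounder candidate, demographic), giving question
#' generation and variable selection a structured prior over the schema. A
#' variable may appear under several roles.
#'
#' @param profiles list from [profile_variables()].
#' @param config a [provider_config()].
#' @param store a [template_store()].
#' @param provider optional provider object overriding the registry.
#' @return list of `variable_pair` objects
#'   (`subject`, `relation`, `rationale`).
#' @export
build_pairs <- function(profiles, config, store = template_store(),
                        provider = NULL) {
  if (length(profiles) == 0)
    adra_abort("empty_input", "no profiles to pair")
  known <- vapply(profiles, function(p) p$name, character(1))
  check <- function(parsed) {
    if (!is.data.frame(parsed) && !is.list(parsed)) return("expected a JSON array")
    df <- as.data.frame(parsed, stringsAsFactors = FALSE)
    if (!all(c("subject", "relation") %in% names(df)))
      return("entries need 'subject' and 'relation'")
    if (!all(df$subject %in% known))
      return(paste0("unknown variable: ",
                    setdiff(df$subject, known)[1]))
    if (!all(df$relation %in% valid_pair_relations))
      return(paste0("invalid relation: ",
                    setdiff(df$relation, valid_pair_relations)[1]))
    NULL
  }
  parsed <- render_and_ask(
    config, store, "variable_pairs",
    bindings = list(profile_summary = profiles_text(profiles),
                    relations = paste(valid_pair_relations, collapse = ", ")),
    check = check, provider = provider)
  df <- as.data.frame(parsed, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    structure(list(subject = df$subject[i], relation = df$relation[i],
                   rationale = if ("rationale" %in% names(df))
                     df$rationale[i] else ""),
              class = "variable_pair")
  })
}

# Human-readable one-line-per-variable summary used in prompts.
profiles_text <- function(profiles) {
  paste(vapply(profiles, function(p) {
    desc <- if (!is.null(p$description)) paste0(" — ", p$description) else ""
    sprintf("%s [%s, %.0f%% missing]%s", p$name, p$kind,
            100 * p$missing_fraction, desc)
  }, character(1)), collapse = "\n")
}

#' Assemble a data report
#'
#' The report is the contract between profiling and question generation:
#' dataset id, row count of the cleaned table, one profile per column, the
#' prior-knowledge pairs and the cleaning log.
#'
#' @param dataset_id identifier for the dataset.
#' @param table cleaned data.frame.
#' @param profiles list from [profile_variables()] over `table`.
#' @param pairs list from [build_pairs()] (may be empty).
#' @param cleaning_log character vector from [clean_data()].
#' @return object of class `data_report`.
#' @export
data_report <- function(dataset_id, table, profiles, pairs = list(),
                        cleaning_log = character(0)) {
  if (length(profiles) != ncol(table))
    adra_abort("domain", "profiles must cover every column exactly once")
  structure(
    list(dataset_id = dataset_id, n_rows = nrow(table), profiles = profiles,
         pairs = pairs, cleaning_log = cleaning_log),
    class = "data_report"
  )
}

#' @export
print.data_report <- function(x, ...) {
  cat("<data_report>", x$dataset_id, "\n")
  cat("  rows:", x$n_rows, " variables:", length(x$profiles), "\n")
  kinds <- table(vapply(x$profiles, function(p) p$kind, character(1)))
  cat("  kinds:", paste(names(kinds), as.integer(kinds), sep = "=",
                        collapse = ", "), "\n")
  cat("  cleaning edits:", length(x$cleaning_log), "\n")
  invisible(x)
}

report_variable_names <- function(report, include_identifiers = FALSE) {
  keep <- vapply(report$profiles, function(p)
    include_identifiers || p$kind != "identifier", logical(1))
  vapply(report$profiles[keep], function(p) p$name, character(1))
}

# Compact textual form of a report for prompt bindings.
report_text <- function(report) {
  paste0(
    "Dataset: ", report$dataset_id, " (", report$n_rows, " rows)\n",
    "Variables:\n", profiles_text(report$profiles),
    if (length(report$pairs)) paste0(
      "\nVariable roles:\n",
      paste(vapply(report$pairs, function(p)
        paste0(p$subject, ": ", p$relation), character(1)), collapse = "\n"))
    else ""
  )
}
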