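# Shared helpers: JSON response shorthand, scripted providers over R objects,
# and a small profiled report used across modules.

jresp <- function(x) as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                                   digits = NA))

# Scripted provider whose entries may be R objects (auto-encoded as JSON) or
# plain strings.
scripted <- function(...) {
  entries <- lapply(list(...), function(e)
    if (is.character(e) && length(e) == 1) e else jresp(e))
  scripted_provider(unlist(entries))
}

test_config <- provider_config("test", temperature = 0)

fixture_table <- function(n = 60, seed = 7) {
  gen <- generate_clinical_table(clinical_table_spec(
    n_rows = n, seed = seed, sentinel_fraction = 0, missingness = c()))
  gen$table
}

fixture_report <- function(n = 60, seed = 7) {
  tab <- fixture_table(n, seed)
  data_report("fixture", tab, profile_variables(tab))
}

fixture_question <- function(text = "Is educ associated with STROKE?",
                             status = "open") {
  q <- research_question(text, dataset_id = "fixture", source = "raiser")
  q$status <- status
  q
}

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

write_csv_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
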