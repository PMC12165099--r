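test_that("load_table parses delimited text and rejects malformed input", {
  df <- data.frame(AGE = c(50, 61, 47), SEX = c(1, 2, 1))
  path <- write_csv_fixture(df)
  tab <- load_table(path)
  expect_identical(dim(tab), c(3L, 2L))
  expect_identical(names(tab), c("AGE", "SEX"))

  # a tab-delimited twin parses to the identical table
  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(df, tsv, sep = "\t", row.names = FALSE)
  expect_identical(load_table(tsv, delim = "\t"), tab)

  dup <- tempfile()
  writeLines(c("AGE,AGE", "1,2"), dup)
  expect_error(load_table(dup), class = "adra_duplicate_column")

  ragged <- tempfile()
  writeLines(c("A,B", "1,2", "3"), ragged)
  err <- tryCatch(load_table(ragged), error = identity)
  expect_true(is_adra_error(err, "parse"))
  expect_match(conditionMessage(err), "line 3")

  empty <- tempfile()
  file.create(empty)
  expect_error(load_table(empty), class = "adra_empty_input")
})

test_that("variable kinds are inferred deterministically from values", {
  tab <- data.frame(
    flag = c(0, 1, 1, 0),
    cat = c("a", "b", "c", "a"),
    cont = c(1.5, 2.7, 3.14, 8.9),
    id_col = c("x1", "x2", "x3", "x4")
  )
  profs <- profile_variables(tab)
  kinds <- setNames(vapply(profs, `[[`, "", "kind"),
                    vapply(profs, `[[`, "", "name"))
  expect_identical(unname(kinds[c("flag", "cat", "id_col")]),
                   c("binary", "categorical", "identifier"))
  # 4 distinct non-integer reals stay continuous despite low cardinality
  expect_identical(unname(kinds["cont"]), "continuous")
  cont200 <- data.frame(x = rnorm(200))
  expect_identical(profile_variables(cont200)[[1]]$kind, "continuous")
  # profiling is a pure function of the table
  expect_identical(profile_variables(tab), profs)
})

test_that("profiles of the generated clinical table match the generator's schema", {
  gen <- generate_clinical_table(clinical_table_spec(n_rows = 400, seed = 3,
                                                     sentinel_fraction = 0,
                                                     missingness = c()))
  profs <- profile_variables(gen$table)
  got <- data.frame(name = vapply(profs, `[[`, "", "name"),
                    kind = vapply(profs, `[[`, "", "kind"),
                    stringsAsFactors = FALSE)
  expect_identical(got, gen$truth$schema)
  expect_true(all(vapply(profs, `[[`, 0, "missing_fraction") == 0))
})

test_that("an all-missing column is profiled, not an error", {
  tab <- data.frame(x = c(NA, NA, NA), y = 1:3)
  p <- profile_variables(tab)[[1]]
  expect_identical(p$kind, "identifier")
  expect_identical(p$missing_fraction, 1)
})

test_that("cleaning maps sentinels to missing, logs every edit, and is idempotent", {
  tab <- data.frame(BMI = c(25, -9, 31, -9, 28), STROKE = c(1, 0, NA, 1, NA))
  pol <- cleaning_policy(sentinel_codes = -9,
                         drop_missing_outcome = "STROKE")
  res <- clean_data(tab, pol)
  expect_identical(nrow(res$table), 3L)
  expect_identical(length(res$log), 4L)  # 2 sentinel cells + 2 dropped rows
  expect_true(all(is.na(res$table$BMI[res$table$BMI == -9])) ||
                !any(res$table$BMI == -9, na.rm = TRUE))
  again <- clean_data(res$table, pol)
  expect_identical(again$table, res$table)
  expect_length(again$log, 0)

  ident <- clean_data(tab, cleaning_policy(sentinel_codes = numeric(0)))
  expect_identical(ident$table, tab)
  expect_length(ident$log, 0)

  allgone <- data.frame(STROKE = c(NA, NA))
  expect_error(clean_data(allgone, pol), class = "adra_empty_after_cleaning")
})

test_that("cleaning log counts injected sentinels exactly", {
  spec <- clinical_table_spec(n_rows = 2000, seed = 11,
                              sentinel_fraction = 0.05, missingness = c())
  gen <- generate_clinical_table(spec)
  res <- clean_data(gen$table, cleaning_policy(sentinel_codes = -9))
  n_recodes <- sum(grepl("sentinel", res$log))
  expect_identical(n_recodes, gen$truth$n_sentinels)
  # injected fraction lands near the configured 5%
  expect_lt(abs(n_recodes / 2000 - 0.05), 0.01)
})

test_that("build_pairs validates provider output against the profile set", {
  profs <- profile_variables(fixture_table())
  good <- scripted(list(list(subject = "STROKE",
                             relation = "outcome_candidate",
                             rationale = "event")))
  pairs <- build_pairs(profs, test_config, provider = good)
  expect_length(pairs, 1)
  expect_identical(pairs[[1]]$subject, "STROKE")

  # one bad reply, then a corrected one on the re-ask: accepted
  healed <- scripted(
    list(list(subject = "NOT_A_VAR", relation = "outcome_candidate")),
    list(list(subject = "AGE", relation = "confounder_candidate")))
  pairs2 <- build_pairs(profs, test_config, provider = healed)
  expect_identical(pairs2[[1]]$subject, "AGE")

  # persistent nonsense: provider-format error after one re-ask
  stubborn <- scripted(
    list(list(subject = "NOT_A_VAR", relation = "outcome_candidate")),
    list(list(subject = "STILL_WRONG", relation = "banana")))
  expect_error(build_pairs(profs, test_config, provider = stubborn),
               class = "adra_provider_format")
})

test_that("data_report enforces one profile per column", {
  tab <- fixture_table(20)
  profs <- profile_variables(tab)
  expect_error(data_report("d", tab, profs[-1]), class = "adra_domain")
  rep <- data_report("d", tab, profs)
  expect_identical(rep$n_rows, 20L)
})
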