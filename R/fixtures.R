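#' Synthetic fixtures
#'
#' Generators that make every stage of the framework testable offline:
#' clinical tables with planted effects and a ground-truth sheet, scripted
#' software-dependency universes for the installation tree, and literature
#' corpora with planted already-studied questions. All generators are pure
#' functions of their spec plus seed.
#'
#' @name synthetic-fixtures
NULL

#' Specification of a synthetic clinical table
#'
#' The default schema emulates a Framingham-style cardiovascular cohort
#' table: a subject identifier, demographics (AGE, SEX, educ), risk factors
#' (BMI, CURSMOKE) and binary outcomes (STROKE, ANYCHD, ANGINA). Continuous
#' covariates are normal, binaries Bernoulli, education an ordinal 1-4
#' categorical; distribution parameters are generic since real per-variable
#' distributions are not public. The default planted effect lowers stroke
#' log-odds by 0.236 (about a 21% odds reduction) per unit of standardized
#' education, adjusted for AGE and BMI — an effect size typical of the
#' education-stroke association the framework's worked example analyses.
#'
#' @param n_rows number of subjects.
#' @param planted_effects list of `list(outcome, exposure, beta,
#'   confounders)`; `beta` is on the log-odds scale per standard deviation of
#'   the exposure. Confounders enter the outcome model with log-odds 0.2 per
#'   SD so adjustment genuinely matters.
#' @param missingness named numeric vector of per-variable missing fractions.
#' @param sentinel_fraction fraction of BMI entries replaced by the sentinel
#'   code instead of honest missingness.
#' @param sentinel_code the sentinel value (default -9).
#' @param seed integer; fully determines the output.
#' @return object of class `clinical_table_spec`.
#' @export
clinical_table_spec <- function(n_rows = 5000L,
                                planted_effects = list(list(
                                  outcome = "STROKE", exposure = "educ",
                                  beta = -0.236,
                                  confounders = c("AGE", "BMI"))),
                                missingness = c(educ = 0.02),
                                sentinel_fraction = 0.05,
                                sentinel_code = -9,
                                seed = 1L) {
  structure(list(n_rows = as.integer(n_rows),
                 planted_effects = planted_effects,
                 missingness = missingness,
                 sentinel_fraction = sentinel_fraction,
                 sentinel_code = sentinel_code, seed = as.integer(seed)),
            class = "clinical_table_spec")
}

clinical_schema <- function() {
  data.frame(
    name = c("RANDID", "AGE", "SEX", "educ", "BMI", "CURSMOKE",
             "STROKE", "ANYCHD", "ANGINA"),
    kind = c("identifier", "continuous", "binary", "categorical",
             "continuous", "binary", "binary", "binary", "binary"),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic clinical table with planted effects
#'
#' Binary outcomes are drawn from a logistic model whose linear predictor
#' contains the planted exposure effect (per SD of the exposure) and a fixed
#' 0.2 log-odds per SD for each declared confounder; the intercept targets a
#' baseline prevalence of roughly 0.25. Covariates for outcomes with no
#' planted effect are independent of everything. The ground-truth sheet
#' records every planted parameter plus the number of injected sentinel
#' cells, so expected values in downstream tests never require
#' re-simulation.
#'
#' @param spec a [clinical_table_spec()].
#' @return list with `table` (data.frame), `truth` (list: `effects`
#'   data.frame of outcome/exposure/beta, `n_sentinels`, `schema`,
#'   `sentinel_code`).
#' @export
generate_clinical_table <- function(spec = clinical_table_spec()) {
  schema <- clinical_schema()
  outs <- vapply(spec$planted_effects, function(e) e$outcome, character(1))
  vars <- unlist(lapply(spec$planted_effects,
                        function(e) c(e$exposure, e$confounders)))
  missing_vars <- setdiff(c(outs, vars), schema$name)
  if (length(missing_vars))
    adra_abort("domain", paste0("planted effect on unknown variable: ",
                                missing_vars[1]))
  n <- spec$n_rows
  with_seed(spec$seed, {
    tab <- data.frame(
      RANDID = sample(1e6, n),
      AGE = round(stats::rnorm(n, 50, 8.5), 1),
      SEX = stats::rbinom(n, 1, 0.45) + 1L,
      educ = sample(1:4, n, replace = TRUE, prob = c(0.42, 0.30, 0.17, 0.11)),
      BMI = round(stats::rnorm(n, 25.8, 4.1), 2),
      CURSMOKE = stats::rbinom(n, 1, 0.49)
    )
    std <- function(x) as.numeric(scale(x))
    for (out in c("STROKE", "ANYCHD", "ANGINA")) {
      lp <- stats::qlogis(0.25)
      for (e in spec$planted_effects) {
        if (e$outcome != out) next
        lp <- lp + e$beta * std(tab[[e$exposure]])
        for (cf in e$confounders) lp <- lp + 0.2 * std(tab[[cf]])
      }
      tab[[out]] <- stats::rbinom(n, 1, stats::plogis(lp))
    }
    tab <- tab[schema$name]
    for (v in names(spec$missingness)) {
      idx <- which(stats::runif(n) < spec$missingness[[v]])
      tab[[v]][idx] <- NA
    }
    n_sent <- 0L
    if (spec$sentinel_fraction > 0) {
      idx <- which(stats::runif(n) < spec$sentinel_fraction & !is.na(tab$BMI))
      tab$BMI[idx] <- spec$sentinel_code
      n_sent <- length(idx)
    }
    effects <- if (length(spec$planted_effects)) data.frame(
      outcome = outs,
      exposure = vapply(spec$planted_effects, function(e) e$exposure, character(1)),
      beta = vapply(spec$planted_effects, function(e) e$beta, numeric(1)),
      stringsAsFactors = FALSE
    ) else data.frame(outcome = character(0), exposure = character(0),
                      beta = numeric(0))
    list(table = tab,
         truth = list(effects = effects, n_sentinels = n_sent,
                      schema = schema, sentinel_code = spec$sentinel_code))
  })
}

#' Reference logistic fit for planted effects
#'
#' The independent check on the generator: an ordinary `glm` logistic fit of
#' the outcome on the standardized exposure plus standardized confounders,
#' returning the exposure estimate and its 95% Wald interval on the log-odds
#' scale — directly comparable to the planted `beta`.
#'
#' @param table generated table (sentinels should be cleaned first if
#'   injected into a model variable).
#' @param outcome,exposure,confounders variable names.
#' @return list of `estimate`, `ci_low`, `ci_high`.
#' @export
reference_logistic_fit <- function(table, outcome, exposure,
                                   confounders = character(0)) {
  std <- function(x) as.numeric(scale(x))
  df <- data.frame(y = table[[outcome]], x = std(table[[exposure]]))
  for (cf in confounders) df[[cf]] <- std(table[[cf]])
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
  est <- unname(stats::coef(fit)["x"])
  se <- summary(fit)$coefficients["x", "Std. Error"]
  list(estimate = est, ci_low = est - stats::qnorm(0.975) * se,
       ci_high = est + stats::qnorm(0.975) * se)
}

# --- software universes ------------------------------------------------------

#' Generate a scripted software-dependency universe
#'
#' Randomly scripts a finite install world: each software gets up to
#' `max_methods` installation methods; each method up to `max_deps`
#' dependencies drawn from the other software names (so dependency chains —
#' and deliberately, cycles — occur) and a finite outcome sequence of code
#' errors possibly ending in success. Some software gets no method at all
#' and some methods never succeed, exercising every failure path of the
#' installation tree.
#'
#' @param n_software number of software records (1-6 keeps the brute-force
#'   oracle sweep fast).
#' @param max_methods,max_deps per-software and per-method caps.
#' @param seed integer seed; fully determines the universe.
#' @param p_success probability that a method's outcome script ends in
#'   success.
#' @param p_dep probability of each potential dependency edge.
#' @param p_no_method probability a software has zero methods.
#' @return list of class `software_universe` with element `software`.
#' @export
generate_software_universe <- function(n_software = 4L, max_methods = 3L,
                                       max_deps = 3L, seed = 1L,
                                       p_success = 0.6, p_dep = 0.35,
                                       p_no_method = 0.1) {
  stopifnot(n_software >= 1, max_methods >= 1)
  names_ <- paste0("s", seq_len(n_software))
  with_seed(seed, {
    software <- lapply(names_, function(nm) {
      n_methods <- if (stats::runif(1) < p_no_method) 0L
                   else sample(seq_len(max_methods), 1)
      methods <- lapply(seq_len(n_methods), function(mi) {
        others <- setdiff(names_, nm)
        deps <- others[stats::runif(length(others)) < p_dep]
        if (length(deps) > max_deps) deps <- deps[seq_len(max_deps)]
        n_err <- sample(0:2, 1)
        outcomes <- c(rep("code_error", n_err),
                      if (stats::runif(1) < p_success) "success")
        if (length(outcomes) == 0) outcomes <- "code_error"
        list(description = paste0("install ", nm, " via method ", mi),
             deps = deps, outcomes = outcomes)
      })
      list(methods = methods)
    })
    structure(list(software = stats::setNames(software, names_)),
              class = "software_universe")
  })
}

#' Brute-force reference evaluator for scripted installs
#'
#' An independent recursive evaluation of whether a software can be installed
#' from a scripted universe under the same outcome semantics as
#' [install_software()], written without any tree, stack or event
#' bookkeeping. Used to cross-check the backtracking implementation on
#' generated universes.
#'
#' @param universe a [generate_software_universe()] universe.
#' @param root software name.
#' @param max_attempts per-method attempt budget.
#' @return `"installed"` or `"failed"`.
#' @export
reference_install_outcome <- function(universe, root, max_attempts = 5L) {
  cursors <- new.env(parent = emptyenv())
  installed <- character(0)
  failed <- character(0)
  can <- function(name, stack) {
    if (name %in% installed) return(TRUE)
    if (name %in% failed) return(FALSE)
    methods <- universe$software[[name]]$methods
    ok <- FALSE
    for (mi in seq_along(methods)) {
      m <- methods[[mi]]
      key <- paste0(name, "#", mi)
      attempts <- 0L
      while (attempts < max_attempts) {
        attempts <- attempts + 1L
        missing <- setdiff(as.character(m$deps %||% character(0)), installed)
        if (length(missing)) {
          dep_ok <- TRUE
          for (d in missing) {
            if (d %in% c(stack, name) || !can(d, c(stack, name))) {
              dep_ok <- FALSE
              break
            }
          }
          if (!dep_ok) break
          next
        }
        n <- (cursors[[key]] %||% 0L) + 1L
        cursors[[key]] <- n
        out <- if (n <= length(m$outcomes)) m$outcomes[[n]] else "code_error"
        if (out == "success") {
          ok <- TRUE
          break
        }
      }
      if (ok) break
    }
    if (ok) installed <<- c(installed, name) else failed <<- c(failed, name)
    ok
  }
  if (can(root, character(0))) "installed" else "failed"
}

# --- planted literature corpora ----------------------------------------------

#' Generate a literature corpus with planted prior work
#'
#' Builds `n_questions` question texts over the clinical schema; for the
#' first half, a title+abstract record restating the question is planted in
#' the corpus (ground truth: previously studied), the rest have no matching
#' record. Decoy records on unrelated topics pad the corpus.
#'
#' @param n_questions total questions (half in-corpus, half out).
#' @param n_decoys unrelated records added to the corpus.
#' @param seed integer seed.
#' @return list with `questions` (list of `research_question`), `corpus`
#'   (list of `literature_record`), `ground_truth` (named logical: question
#'   id -> previously studied), `matching_records` (named list: question id
#'   -> planted record id, for in-corpus questions).
#' @export
generate_planted_corpus <- function(n_questions = 100L, n_decoys = 50L,
                                    seed = 1L) {
  stopifnot(n_questions >= 2)
  outcomes <- c("stroke", "coronary heart disease", "angina",
                "hypertension", "diabetes")
  exposures <- c("education", "body mass index", "smoking", "age", "sex",
                 "physical activity", "alcohol intake", "cholesterol")
  with_seed(seed, {
    combos <- expand.grid(o = outcomes, e = exposures,
                          f = c("risk of", "incidence of", "odds of"),
                          stringsAsFactors = FALSE)
    combos <- combos[sample(nrow(combos), n_questions), ]
    texts <- sprintf("Is %s associated with the %s %s in this cohort?",
                     combos$e, combos$f, combos$o)
    questions <- lapply(seq_along(texts), function(i)
      research_question(texts[i], dataset_id = "synthetic-cohort",
                        source = "external"))
    n_in <- floor(n_questions / 2)
    ids <- vapply(questions, function(q) q$question_id, character(1))
    ground_truth <- stats::setNames(seq_along(ids) <= n_in, ids)
    corpus <- list()
    matching <- list()
    for (i in seq_len(n_in)) {
      rid <- sprintf("rec-%03d", i)
      corpus[[length(corpus) + 1L]] <- literature_record(
        rid,
        title = sprintf("Association of %s with %s: a cohort study",
                        combos$e[i], combos$o[i]),
        abstract = paste0("We examined whether ", combos$e[i],
                          " is associated with the ", combos$f[i], " ",
                          combos$o[i],
                          " in a longitudinal cohort. The association was significant."))
      matching[[ids[i]]] <- rid
    }
    for (j in seq_len(n_decoys)) {
      corpus[[length(corpus) + 1L]] <- literature_record(
        sprintf("decoy-%03d", j),
        title = sprintf("Technical note %d on laboratory assay calibration", j),
        abstract = "Calibration of laboratory assays unrelated to cohort epidemiology.")
    }
    list(questions = questions, corpus = corpus,
         ground_truth = ground_truth, matching_records = matching)
  })
}
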