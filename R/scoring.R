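#' Question scoring and score statistics
#'
#' A scoring agent rates each question on two dimensions — difficulty and
#' quality — each the unweighted mean of named 1-100 subscores defined by a
#' data-driven rubric store. Downstream statistics cover the evolution trend
#' across rounds (ordinary least squares), the fraction of questions
#' addressed, and agent-vs-expert agreement (correlation, regression slope,
#' pairwise t-tests).
#'
#' @name question-scoring
NULL

#' Load a scoring rubric
#'
#' One text file per subdimension criterion, under `difficulty/` and
#' `quality/` subdirectories. The packaged default keeps the field's named
#' quality criteria (clarity, feasibility, originality, soundness,
#' complexity) and three generic difficulty criteria; both lists are
#' user-extensible by pointing `dir` at another store.
#'
#' @param dir rubric directory.
#' @return list with `difficulty` and `quality`, each a named character
#'   vector of criterion texts.
#' @export
rubric_store <- function(dir = system.file("rubric", package = "adra")) {
  read_dim <- function(d) {
    files <- list.files(file.path(dir, d), pattern = "\\.txt$", full.names = TRUE)
    if (length(files) == 0)
      adra_abort("not_found", paste0("rubric dimension '", d, "' has no criteria"))
    stats::setNames(
      vapply(files, function(f)
        paste(readLines(f, warn = FALSE), collapse = "\n"), character(1)),
      tools::file_path_sans_ext(basename(files)))
  }
  list(difficulty = read_dim("difficulty"), quality = read_dim("quality"))
}

#' Score a question on difficulty and quality
#'
#' The provider must return one integer in \[1, 100\] per rubric criterion;
#' out-of-range or missing subscores trigger one re-ask, then a
#' provider-format error. Dimension scores are the unweighted arithmetic
#' means of their subscores.
#'
#' @param question a `research_question`.
#' @param rubric a [rubric_store()].
#' @param config a [provider_config()].
#' @param store a [template_store()].
#' @param provider optional provider override.
#' @return object of class `score_card` with `difficulty_subscores`,
#'   `quality_subscores`, `difficulty`, `quality`.
#' @export
score_question <- function(question, rubric = rubric_store(), config,
                           store = template_store(), provider = NULL) {
  dims <- list(difficulty = names(rubric$difficulty),
               quality = names(rubric$quality))
  check <- function(parsed) {
    for (dim in names(dims)) {
      sub <- parsed[[dim]]
      if (is.null(sub)) return(paste0("missing dimension '", dim, "'"))
      sub <- unlist(sub)
      if (!all(dims[[dim]] %in% names(sub)))
        return(paste0("missing subscore for ",
                      setdiff(dims[[dim]], names(sub))[1]))
      vals <- suppressWarnings(as.numeric(sub[dims[[dim]]]))
      if (anyNA(vals) || any(vals < 1 | vals > 100) || any(vals != floor(vals)))
        return("subscores must be integers in [1, 100]")
    }
    NULL
  }
  rubric_text <- paste(
    vapply(names(dims), function(dim) paste0(
      toupper(dim), ":\n",
      paste0("- ", dims[[dim]], ": ", rubric[[dim]], collapse = "\n")),
      character(1)),
    collapse = "\n")
  parsed <- render_and_ask(
    config, store, "score_question",
    bindings = list(question = question$text, rubric = rubric_text),
    check = check, provider = provider)
  take <- function(dim) {
    v <- unlist(parsed[[dim]])[dims[[dim]]]
    stats::setNames(as.integer(v), dims[[dim]])
  }
  d <- take("difficulty"); q <- take("quality")
  structure(list(question_id = question$question_id,
                 difficulty_subscores = d, quality_subscores = q,
                 difficulty = mean(d), quality = mean(q)),
            class = "score_card")
}

#' Map a 1-100 agent score onto the 1-10 expert scale
#'
#' Exactly linear: the agent's score divided by 10, so 100 maps to 10 and 1
#' to 0.1.
#'
#' @param score numeric in \[1, 100\].
#' @return `score / 10`.
#' @export
normalize_to_expert_scale <- function(score) {
  if (any(score < 1 | score > 100))
    adra_abort("domain", "score must lie in [1, 100]")
  score / 10
}

#' Score trend across evolution rounds
#'
#' Ordinary least squares of score on round index over all (round, score)
#' points, with a 95% confidence interval and two-sided p-value for the
#' slope.
#'
#' @param scores_by_round named list mapping round index (as names, e.g.
#'   `"0"`) to numeric score vectors; at least two non-empty rounds.
#' @return object of class `trend_estimate` with `slope`, `intercept`,
#'   `ci_low`, `ci_high`, `p_value`, `n_points`.
#' @export
evolution_trend <- function(scores_by_round) {
  rounds <- suppressWarnings(as.numeric(names(scores_by_round)))
  if (length(scores_by_round) < 2 || anyNA(rounds) ||
      any(lengths(scores_by_round) == 0))
    adra_abort("insufficient_data",
               "need at least two non-empty rounds with numeric round labels")
  df <- data.frame(
    round = rep(rounds, lengths(scores_by_round)),
    score = unlist(scores_by_round, use.names = FALSE))
  fit <- stats::lm(score ~ round, data = df)
  # a zero-residual fit is legitimate here (handled below); silence the
  # "essentially perfect fit" advisory
  co <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(co["round", "Estimate"])
  p <- if (nrow(df) > 2 && is.finite(co["round", "Std. Error"]) &&
           co["round", "Std. Error"] > 0)
    unname(co["round", "Pr(>|t|)"]) else NA_real_
  ci <- tryCatch(suppressWarnings(stats::confint(fit, "round", level = 0.95)),
                 error = function(e) c(NA_real_, NA_real_))
  # A perfectly collinear fit (zero residual) has a degenerate CI; report the
  # point estimate with zero width rather than NA bounds.
  if (anyNA(ci) || any(!is.finite(ci))) ci <- c(slope, slope)
  if (is.na(p)) p <- if (abs(slope) > 0) 0 else 1
  structure(list(slope = slope,
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 ci_low = min(ci), ci_high = max(ci),
                 p_value = min(max(p, 0), 1), n_points = nrow(df)),
            class = "trend_estimate")
}

#' Percentage of questions successfully addressed
#'
#' @param n_success number successfully addressed.
#' @param n_total positive total.
#' @return integer percent, rounded half-up (17 of 25 is 68; 7 of 8 is 88).
#' @export
fraction_addressed <- function(n_success, n_total) {
  if (n_total <= 0) adra_abort("domain", "n_total must be positive")
  if (n_success < 0 || n_success > n_total)
    adra_abort("domain", "need 0 <= n_success <= n_total")
  as.integer(round_half_up(100 * n_success / n_total))
}

#' Agent-versus-expert agreement analysis
#'
#' Pearson correlation and OLS slope of expert on agent scores (paired by
#' question), plus two-sided t-tests between every pair of question groups
#' for each scorer, with the direction of the mean difference. Welch's
#' unequal-variance test is the default; set `equal_var = TRUE` for the
#' classical Student test.
#'
#' @param agent_scores,expert_scores numeric vectors paired by question
#'   (same length, at least 3).
#' @param groups optional factor of question groups (e.g. question source)
#'   for the pairwise comparisons.
#' @param equal_var logical; assume equal variances in the t-tests.
#' @return object of class `agreement_result` with `correlation`,
#'   `regression_slope`, `p_value` and `paired_comparisons` (data.frame of
#'   `scorer`, `group_a`, `group_b`, `t_statistic`, `p_value`, `direction`).
#' @export
agreement_analysis <- function(agent_scores, expert_scores, groups = NULL,
                               equal_var = FALSE) {
  if (length(agent_scores) != length(expert_scores))
    adra_abort("pairing", "agent and expert scores must be paired by question")
  if (length(agent_scores) < 3)
    adra_abort("insufficient_data", "need at least 3 paired questions")
  ct <- stats::cor.test(agent_scores, expert_scores)
  fit <- stats::lm(expert_scores ~ agent_scores)
  comparisons <- data.frame(scorer = character(0), group_a = character(0),
                            group_b = character(0), t_statistic = numeric(0),
                            p_value = numeric(0), direction = integer(0),
                            stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    lv <- levels(groups)
    scorers <- list(agent = agent_scores, expert = expert_scores)
    for (s in names(scorers)) {
      x <- scorers[[s]]
      for (i in seq_along(lv)) for (j in seq_along(lv)) {
        if (j <= i) next
        a <- x[groups == lv[i]]; b <- x[groups == lv[j]]
        if (length(a) < 2 || length(b) < 2) next
        tt <- stats::t.test(a, b, var.equal = equal_var)
        comparisons <- rbind(comparisons, data.frame(
          scorer = s, group_a = lv[i], group_b = lv[j],
          t_statistic = unname(tt$statistic), p_value = tt$p.value,
          direction = sign(mean(a) - mean(b)), stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(correlation = unname(ct$estimate),
                 regression_slope = unname(stats::coef(fit)["agent_scores"]),
                 p_value = ct$p.value,
                 paired_comparisons = comparisons),
            class = "agreement_result")
}
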