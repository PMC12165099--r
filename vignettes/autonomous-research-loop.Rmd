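---
title: "Methods: the autonomous research loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the autonomous research loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adra)
```

`adra` implements a provider-agnostic framework for autonomous data-driven
research on structured biomedical tables. One research cycle moves through
four conceptual phases — question, code, configure, judge — realised by
eleven cooperating modules: a data interpreter and cleaner, a question
raiser/reviewer pair, a variable getter, a task planner, a code maker, an
environment configurator, an executor, a result judge (interpreter + judger),
a code debugger (debugger + merger), a result analyzer/validator, and a
deep questioner that turns answered questions into the next evolution round.
This vignette records the model behind each stage, the tunable parameters and
their defaults, the numerical conventions, and the design decisions taken
where the design was genuinely open.

## Provider gateway and determinism

Every text generation flows through one contract: a `provider_config()`
(provider id, model name, temperature, retry budget) and `complete()`.
Two providers ship with the package: a `function_provider()` adapter for real
backends and a `scripted_provider()` that replays a recorded transcript
strictly in request order. A `recording_provider()` wraps any backend and
captures `(request_hash, prompt, response, ordinal)` entries as JSON Lines;
replaying a recorded transcript reproduces every downstream artifact
byte-identically (checked by ledger fingerprints, which hash the run with
timestamps, durations and sandbox paths removed).

Temperature defaults follow the production convention the framework
emulates: question raising uses the provider's own default (ideation
benefits from sampling diversity); every other call uses temperature 0, and
real providers must honor 0 as their most deterministic mode. Transient
provider failures are retried with exponential backoff up to `max_retries`
(default 2; the production retry count is not public, so it is exposed as
configuration); a retry never consumes a transcript entry.

Structured outputs use a JSON convention: each module renders a prompt
template (`{name}` placeholders, one file per template under `full/` and
`basic/` modes), asks the provider, parses the reply as JSON, re-asks once
with the parse error prepended, and only then raises a provider-format
error. The `basic` mode replaces each engineered prompt with a minimal task
description so the contribution of the prompt engineering itself can be
measured; both modes share a placeholder contract.

## Dataset profiling and cleaning

`profile_variables()` classifies each column from its values alone, so
profiling is a pure function of the table bytes. Thresholds (all exposed as
arguments): at most 2 distinct non-missing values is binary; at most 10
distinct values that are non-numeric or integer-coded is categorical;
anything else numeric is continuous; an identifier-like name with all-unique
values is an identifier; an all-missing column is profiled as an identifier
with missing fraction 1 rather than an error.

The default `cleaning_policy()` is deliberately the least destructive rule
set that still matters: configured sentinel codes (default `-9`) are recoded
to missing cell-by-cell, and rows are dropped only for a missing outcome and
only when an outcome is named. Every edit appends one log entry, so the log
length equals the number of modifications (conservation of edits), and
cleaning is idempotent. Prior-knowledge variable pairs
(outcome/exposure/confounder candidates, demographics) are requested from
the provider once per run and passed to question generation and variable
selection as a structured prior over the schema.

## Questions, lineage, and evolution

The raiser proposes up to `n_candidates` questions (default 100, the
standard evaluation batch size) from the data report; candidates that
mention no profiled variable by name are dropped with a logged reason. The
reviewer — a second provider step — returns exactly one retain/reject
decision per candidate; rejected questions become `invalid` but stay in the
ledger for lineage completeness, and review never mutates question text.

Question ids are content hashes of text plus dataset id (plus round and
parent for deepened questions), so replayed runs produce identical ids.
Deepening an answered question yields follow-ups with `source = "deep"`,
`parent_id` set, and round incremented by exactly one; lineage is therefore
reconstructible from `parent_id` alone and forms a forest whose root-to-leaf
paths increase in round by one per hop. Ties in any selection over scored
questions break lexicographically on question id.

## Scoring and its statistics

The scoring agent rates two dimensions, difficulty and quality, each the
unweighted arithmetic mean of named 1–100 integer subscores. The quality
criteria are the field's named five (clarity, feasibility, originality,
soundness, complexity); the difficulty criteria default to three generic
ones (knowledge depth, methodological complexity, data demands). Because no
canonical public inventory of subdimension wordings exists, the rubric is a
data-driven store — one text file per criterion — and user-extensible;
nothing in the code depends on the criterion names. Agent scores map onto
the 1–10 expert scale by exact division by 10.

`evolution_trend()` is ordinary least squares of score on round index over
all (round, score) points with a 95% confidence interval and a two-sided
slope p-value; a zero-residual fit reports a zero-width interval rather than
`NA`. `agreement_analysis()` pairs agent and expert scores by question and
reports the Pearson correlation, the OLS slope of expert on agent, and
pairwise two-sided t-tests between question groups for each scorer with the
direction of the mean difference. Welch's unequal-variance test is the
default (`equal_var = FALSE`) because equal variances across question
sources is not a defensible assumption; the classical Student test is one
flag away.

## The installation tree

Environment configuration resolves registry tools by lookup (most recently
built compatible image wins, a deterministic tie-break) and installs
everything else with a backtracking installation tree. The algorithm:

1. The requested software becomes the root software node; a `SearchMethod`
   provider appends candidate method nodes in its returned order.
2. Each method is attempted by an `Install` provider with a per-method
   attempt budget (`max_attempts`, default 5). Every attempt ends in one of
   three outcomes: *success* (the software node is pruned and, at the root,
   a new image is registered), *code error* (retried while attempts remain,
   then the method node is pruned), or *missing dependencies* (each named
   dependency is installed recursively as a child software node; if any
   dependency fails the method is pruned immediately, regardless of attempts
   left).
3. A software node fails when all its method nodes have failed; the tree
   being emptied is exactly a successful installation.

Two decisions deserve record. First, **every `Install` call consumes one
attempt**, whatever its outcome: an install attempt generates installation
code whether it later reports success, a code error, or missing
dependencies, so attempts are the natural unit of code generation. This also
gives the unconditional guarantees the tests verify — termination on any
finite scripted universe, and total install calls bounded by the sum of
attempt budgets over visited method nodes. Second, a dependency already on
the active root-to-leaf stack is a **cycle** and fails that method
immediately; sibling dependencies install sequentially in reported order,
matching the single installation stack. Within one run, installed and failed
software are memoized: a software that failed once is not re-searched, and
the registry only ever grows.

The `Install`/`SearchMethod` boundary is pluggable. Tests and offline runs
use a scripted simulator over a generated software universe; the simulator
reports missing dependencies (without consuming a scripted outcome) whenever
a method's declared dependencies are not yet installed, then yields its
finite outcome script one entry per actual execution, with exhaustion
reading as further code errors. The implementation is cross-checked against
an independent brute-force recursive evaluator
(`reference_install_outcome()`, no tree/stack/event bookkeeping) on 1000
seeded universes of up to 6 software, 3 methods each, 3 dependencies per
method — small enough that the sweep runs in seconds, large enough to cover
deep chains, never-succeeding methods, method-less software, and cycles.

## Adjudication, debugging, and routing

Judging is two-step. The interpreter summarizes the execution (always — a
failed execution yields a report whose anomalies include the stderr head)
and extracts named quantities. The judger then decides four dimensions:
*error*, *question*, *variable*, *process*. The error dimension is purely
mechanical: a nonzero exit fails it — and the verdict — with **zero provider
calls**, the other three dimensions being recorded as failed-not-assessed so
the conjunction rule (answered if and only if all four pass) holds on every
verdict. On a clean exit one provider call adjudicates the remaining three
dimensions given the report, output tail and variable selection, and always
returns detailed feedback. An optional provider-reported confidence in
\[0, 1\] supports ROC construction over a batch of judgments.

Failing code is repaired by a debugger/merger pair — fragment first, then a
complete merged script, never a raw diff — with versions increasing by
exactly one per round and a hard budget of `max_debug_rounds` (default 4).
Failures whose stderr matches environmental signatures (shell
command-not-found variants, missing interpreters, missing shared libraries
or packages; the pattern list is user-extensible) are routed to environment
configuration instead of the debugger and do not consume a debug round or a
version; one environment repair is attempted per question before falling
back to the debugger. R's `object not found` deliberately stays a code
error.

## Validation

Literature validation never hands the provider the whole corpus: a
deterministic lexical pre-filter ranks records by shared word tokens with
the question and passes the top k (default 20). The provider must cite
supporting record ids from the corpus — citations outside it are
provider-format errors after one re-ask — and `previously_studied` is true
exactly when the citation list is non-empty, so the verdict can never
fabricate literature.

Cross-dataset validation re-runs the full solve loop on a matched sibling
dataset and compares the headline extracted quantity by **sign agreement**:
ratio-type quantities (odds, risk, hazard ratios) compare the sign of their
logarithm, everything else the raw sign. Only binary validated/not-validated
outcomes are defensible without a published numeric tolerance; a magnitude
tolerance can be layered on by the caller. A sibling run that ends
unanswered leaves consistency undefined (`NA`) with an explanatory note, and
revalidation never mutates the original ledger.

## Metrics conventions

Percentages and efficiency multiples round **half away from zero** (87.5
reports as 88); this single convention reproduces every printed rate and
multiple the package recomputes. Zero-denominator metrics are `NA` markers,
never exceptions, so batch evaluation cannot abort. AUROC is the rank-based
Mann–Whitney statistic with ties counted half. The pass-rate bootstrap is
per-replicate **subsampling without replacement** (default fraction 0.8),
not the classical with-replacement bootstrap, and is seeded. Efficiency is
sub-questions solved per person-day: one plan step is one sub-question, a
sub-question counts as solved only when its parent question's verdict is
answered, and the per-person rate divides by the team size attributable to
the system's output.

## The synthetic generators, and what passing tests mean

`generate_clinical_table()` emulates a Framingham-style cardiovascular
cohort: identifier, AGE, SEX, four-level education, BMI, current smoking,
and three binary outcomes. Binary outcomes come from a logistic model whose
linear predictor carries the planted exposure effect per standard deviation
plus 0.2 log-odds per standard deviation for each declared confounder, with
an intercept targeting a baseline prevalence near 0.25. The default planted
effect is −0.236 log-odds of stroke per SD of education (about a 21% odds
reduction) adjusted for AGE and BMI — the size of association the package's
worked example narrates. Where no public distributional detail exists the
choices are generic (normal/Bernoulli/categorical) and made once. The
ground-truth sheet records every planted parameter and the injected sentinel
count, so downstream expected values never require re-simulation.

What the generator does **not** emulate: real missingness mechanisms
(injection is independent at random), measurement error, correlated
covariates, time-to-event structure, or any omics modality. Passing tests
therefore demonstrate that the machinery — profiling, cleaning accounting,
effect recovery by an ordinary logistic fit, sign-agreement validation — is
correct on data whose generating process is known, not that any scientific
conclusion transfers to a real cohort. Likewise, scripted transcripts verify
the framework's mechanics (ordering, routing, bounds, determinism), not the
scientific quality of any live provider.

Problem sizes used by the test suite and acceptance script, chosen to give
stable statistics at interactive runtimes: 1000 scripted universes for the
oracle sweep; 100 seeded replicates for trend-coverage (planted slope 2,
noise SD 1, 25 scores per round over 4 rounds); 1000 bootstrap replicates
over 100 outcomes; 50 seeds at n = 5000 for planted-effect recovery, with
coverage required in at least 90% of seeds at the nominal 95% level.

## Known limitations

The provider-format re-ask budget is one; persistent malformed output fails
the question rather than looping. Requirement parsing detects registry tools
by word match and trusts the artifact's declared software for external
tools — it is not a static analyzer. The container build side of the install
provider is behind the provider boundary and is not exercised here: offline
runs prove the algorithm, not any real build. Image "compatibility" is name
membership in `installed_software`; no version constraint solving is
attempted, deliberately — the algorithm is attempt-based, not
constraint-based. Execution sandboxing is a fresh working directory per run
with captured, capped streams; it is isolation by convention, not a security
boundary.
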