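# Hand-written universes for the algorithm's canonical paths.
universe <- function(...) structure(list(software = list(...)),
                                    class = "software_universe")
method <- function(outcomes, deps = character(0), description = "m") {
  list(description = description, deps = deps, outcomes = outcomes)
}

run_install <- function(u, root, max_attempts = 5L, registry = NULL) {
  install_software(root, scripted_search_provider(u),
                   scripted_install_provider(u),
                   max_attempts = max_attempts, registry = registry)
}

test_that("single method succeeding on attempt one installs and empties the tree", {
  u <- universe(s1 = list(methods = list(method("success"))))
  res <- run_install(u, "s1")
  expect_identical(res$result, "installed")
  expect_identical(res$install_calls, 1L)
  expect_true(tree_emptied(res$tree))
  kinds <- vapply(res$events, `[[`, "", "kind")
  expect_identical(kinds, c("search", "attempt", "prune-software"))
})

test_that("a missing dependency is installed recursively before the parent retries", {
  u <- universe(
    root = list(methods = list(method("success", deps = "dep"))),
    dep = list(methods = list(method("success"))))
  res <- run_install(u, "root")
  expect_identical(res$result, "installed")
  # install order: dep first, then root (stack depth reached 2)
  expect_identical(res$installed, c("dep", "root"))
  # calls: root md-report, dep success, root success
  expect_identical(res$install_calls, 3L)
  expect_true(tree_emptied(res$tree))
  depnode <- res$tree$methods[[1]]$dependencies[[1]]
  expect_identical(depnode$name, "dep")
  expect_identical(depnode$state, "installed")
})

test_that("code errors are retried only while attempts remain", {
  u <- universe(s1 = list(methods = list(
    method(c("code_error", "code_error")),
    method(c("code_error", "code_error")))))
  res <- run_install(u, "s1", max_attempts = 2L)
  expect_identical(res$result, "failed")
  expect_identical(res$install_calls, 4L)  # both methods exhaust 2 attempts
  expect_false(tree_emptied(res$tree))
  expect_identical(vapply(res$tree$methods, `[[`, "", "state"),
                   c("failed", "failed"))
  # retry succeeds when the budget allows it
  u2 <- universe(s1 = list(methods = list(method(c("code_error", "success")))))
  expect_identical(run_install(u2, "s1", max_attempts = 2L)$result, "installed")
  expect_identical(run_install(u2, "s1", max_attempts = 1L)$result, "failed")
})

test_that("a failed dependency prunes the method regardless of attempts left", {
  u <- universe(
    root = list(methods = list(method(c("success"), deps = "dead"),
                               method("success"))),
    dead = list(methods = list(method("code_error"))))
  res <- run_install(u, "root", max_attempts = 5L)
  expect_identical(res$result, "installed")  # second method rescues the root
  m1 <- res$tree$methods[[1]]
  expect_identical(m1$state, "failed")
  expect_lt(m1$attempts_used, m1$max_attempts)  # pruned early, not exhausted
})

test_that("dependency cycles are cut by the stack guard and both sides fail", {
  u <- universe(
    a = list(methods = list(method("success", deps = "b"))),
    b = list(methods = list(method("success", deps = "a"))))
  res <- run_install(u, "a")
  expect_identical(res$result, "failed")
  kinds <- vapply(res$events, `[[`, "", "kind")
  expect_true("cycle" %in% kinds)
  # self-dependency is the degenerate cycle
  u2 <- universe(s = list(methods = list(method("success", deps = "s"))))
  expect_identical(run_install(u2, "s")$result, "failed")
})

test_that("software with no installation method fails cleanly", {
  u <- universe(s1 = list(methods = list()))
  res <- run_install(u, "s1")
  expect_identical(res$result, "failed")
  expect_identical(res$install_calls, 0L)
})

test_that("successful installs register a new image; registry only grows", {
  reg <- tool_registry()
  u <- universe(
    root = list(methods = list(method("success", deps = "dep"))),
    dep = list(methods = list(method("success"))))
  res <- run_install(u, "root", registry = reg)
  expect_identical(res$result, "installed")
  entries <- registry_entries(reg)
  expect_length(entries, 1)
  expect_setequal(entries[[1]]$installed_software, c("dep", "root"))
  expect_false(is.null(find_compatible_image(reg, "dep")))
  # a second install adds, never replaces
  run_install(universe(x = list(methods = list(method("success")))), "x",
              registry = reg)
  expect_length(registry_entries(reg), 2)
})

test_that("registry lookups resolve tools and tie-break on the freshest image", {
  reg <- tool_registry(list(
    list(image_ref = "img/base:1", installed_software = c("samtools", "bcftools"),
         usage_notes = "call directly"),
    list(image_ref = "img/base:2", installed_software = "samtools",
         usage_notes = "newer build")))
  e <- resolve_registry(reg, "bcftools")
  expect_identical(e$image_ref, "img/base:1")
  # shared image: both tools resolve to the same ref
  expect_identical(resolve_registry(reg, "bcftools")$image_ref, "img/base:1")
  # two candidates: the most recently built wins
  expect_identical(find_compatible_image(reg, "samtools")$image_ref,
                   "img/base:2")
  expect_null(find_compatible_image(reg, "absent"))
  expect_error(resolve_registry(reg, "absent"), class = "adra_not_found")
})

test_that("requirement parsing classifies declared and invoked tools by registry lookup", {
  reg <- tool_registry(list(
    list(image_ref = "img/a:1", installed_software = c("samtools", "bwa", "bedtools"))))
  art <- code_artifact("q", "shell",
                       "samtools view in.bam | mycustomtool > out\nbwa mem ref q",
                       required_software = c("samtools", "bwa", "mycustomtool",
                                             "otherext", "bedtools"))
  req <- parse_requirements(art, reg)
  expect_setequal(req$registry_tools, c("samtools", "bwa", "bedtools"))
  expect_identical(req$external_tools, c("mycustomtool", "otherext"))
  expect_identical(req$language, "shell")

  plain <- code_artifact("q", "r", "cat(1)")
  req2 <- parse_requirements(plain, reg)
  expect_length(req2$registry_tools, 0)
  expect_length(req2$external_tools, 0)
})

test_that("configure_environment resolves, installs, and reports partial failures", {
  reg <- tool_registry(list(
    list(image_ref = "img/a:1", installed_software = "samtools")))
  u <- universe(
    newtool = list(methods = list(method("success"))),
    doomed = list(methods = list(method(rep("code_error", 5)))))
  art <- code_artifact("q", "shell", "samtools sort; newtool run; doomed go",
                       required_software = c("samtools", "newtool", "doomed"))
  manifest <- configure_environment(art, reg,
                                    search = scripted_search_provider(u),
                                    install = scripted_install_provider(u))
  expect_setequal(names(manifest$resolved), c("samtools", "newtool"))
  expect_false(manifest$resolved$newtool$reused)
  expect_identical(manifest$failures, "doomed")
  expect_length(registry_entries(reg), 2)  # grew by exactly one

  # all tools in registry: lookup-only, no installs triggered
  art2 <- code_artifact("q", "shell", "samtools index x",
                        required_software = "samtools")
  m2 <- configure_environment(art2, reg)
  expect_identical(m2$failures, character(0))
  expect_true(m2$resolved$samtools$reused)
})

test_that("install equals the brute-force oracle over 1000 seeded universes", {
  n_universes <- 1000L
  mism <- 0L
  for (s in seq_len(n_universes)) {
    u <- generate_software_universe(
      n_software = 1L + (s %% 6L), max_methods = 3L, max_deps = 3L,
      seed = s, p_success = 0.5 + 0.4 * ((s %% 5) / 4),
      p_dep = 0.15 + 0.3 * ((s %% 3) / 2))
    max_attempts <- 1L + (s %% 5L)
    res <- run_install(u, "s1", max_attempts = max_attempts)
    oracle <- reference_install_outcome(u, "s1", max_attempts = max_attempts)
    if (!identical(res$result, oracle)) mism <- mism + 1L
    expect_lte(res$install_calls, attempt_budget_bound(res$tree))
    expect_identical(tree_emptied(res$tree), res$result == "installed")
    walk <- function(sn) {
      for (m in sn$methods) {
        expect_lte(m$attempts_used, m$max_attempts)
        for (d in m$dependencies) walk(d)
      }
    }
    walk(res$tree)
  }
  expect_identical(mism, 0L)
})

test_that("build recipes list dependency installs before their dependents", {
  u <- universe(
    root = list(methods = list(method("success", deps = "dep"))),
    dep = list(methods = list(method("success"))))
  res <- run_install(u, "root")
  recipe <- build_recipe(res$tree)
  lines <- strsplit(recipe, "\n")[[1]]
  expect_lt(grep("dep:", lines), grep("root:", lines))
})
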