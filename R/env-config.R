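#' Environment configuration via installation-tree backtracking
#'
#' Analysis scripts declare required software. Tools already covered by a
#' registry image are resolved by lookup; anything else is installed by a
#' dynamic installation tree: the tool is the root software node, a
#' SearchMethod provider appends candidate method nodes, and an Install
#' provider attempts each method. An attempt ends in success (the software
#' node is pruned), a code error (retried while attempts remain, then the
#' method node is pruned), or missing dependencies (each dependency is
#' recursively installed as a child software node; if any dependency fails,
#' the method node is pruned regardless of attempts left). A software node
#' fails when all its method nodes have failed; the tree being emptied is
#' exactly a successful installation. Every Install call generates
#' installation code, so every call — whatever its outcome — consumes one of
#' the method's attempts.
#'
#' Providers are pluggable: tests and offline runs use a scripted simulator
#' over a [software universe][generate_software_universe()]; a container
#' runtime can be plugged in behind the same two functions.
#'
#' @name env-config
NULL

# --- image registry ----------------------------------------------------------

#' Tool/image registry
#'
#' Holds image registry entries: `image_ref` (unique), `installed_software`,
#' `usage_notes`. Entries are only ever added within a run, never removed.
#'
#' @param entries optional list of entries to preload.
#' @return object of class `tool_registry` (reference semantics).
#' @export
tool_registry <- function(entries = list()) {
  st <- new.env(parent = emptyenv())
  st$entries <- list()
  reg <- structure(list(state = st), class = "tool_registry")
  for (e in entries)
    registry_add(reg, e$image_ref, e$installed_software,
                 e$usage_notes %||% "")
  reg
}

#' @rdname tool_registry
#' @param registry a `tool_registry`.
#' @param image_ref unique image reference.
#' @param installed_software character vector of tools the image provides.
#' @param usage_notes free-text usage notes.
#' @export
registry_add <- function(registry, image_ref, installed_software,
                         usage_notes = "") {
  st <- registry$state
  refs <- vapply(st$entries, function(e) e$image_ref, character(1))
  if (image_ref %in% refs)
    adra_abort("domain", paste0("image_ref already registered: ", image_ref))
  st$entries[[length(st$entries) + 1L]] <- list(
    image_ref = image_ref,
    installed_software = as.character(installed_software),
    usage_notes = usage_notes, built_at = length(st$entries) + 1L)
  invisible(registry)
}

#' @rdname tool_registry
#' @export
registry_entries <- function(registry) registry$state$entries

#' @rdname tool_registry
#' @export
registry_tools <- function(registry) {
  unique(unlist(lapply(registry$state$entries,
                       function(e) e$installed_software))) %||% character(0)
}

#' Load or save a registry as JSON
#' @param path JSON file of entries.
#' @return a [tool_registry()].
#' @export
read_registry <- function(path) {
  entries <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tool_registry(entries)
}

#' @rdname read_registry
#' @param registry a [tool_registry()].
#' @export
write_registry <- function(registry, path) {
  entries <- lapply(registry_entries(registry), function(e)
    e[c("image_ref", "installed_software", "usage_notes")])
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Resolve a registry tool to its image entry
#' @param registry a [tool_registry()].
#' @param tool tool name.
#' @return the entry (resolve errors when absent; find returns `NULL`).
#' @export
resolve_registry <- function(registry, tool) {
  hit <- find_compatible_image(registry, tool)
  if (is.null(hit))
    adra_abort("not_found", paste0("tool not in registry: ", tool))
  hit
}

#' @rdname resolve_registry
#' @details `find_compatible_image()` returns the most recently built image
#'   listing the tool, or `NULL`; the deterministic most-recent tie-break
#'   means reuse always prefers the freshest build.
#' @export
find_compatible_image <- function(registry, tool) {
  hits <- Filter(function(e) tool %in% e$installed_software,
                 registry$state$entries)
  if (length(hits) == 0) return(NULL)
  hits[[which.max(vapply(hits, function(e) e$built_at, numeric(1)))]]
}

# --- requirement parsing -----------------------------------------------------

#' Parse a code artifact's software requirements
#'
#' Classification is by registry lookup: the declared `required_software`
#' plus any registry tool invoked by name in the source are split into
#' registry tools and external tools (unknown means external).
#'
#' @param artifact a [code_artifact()].
#' @param registry a [tool_registry()].
#' @return list of `language`, `registry_tools`, `external_tools`.
#' @export
parse_requirements <- function(artifact, registry) {
  known <- registry_tools(registry)
  scan_hits <- known[vapply(known, function(t)
    grepl(paste0("\\b", t, "\\b"), artifact$source), logical(1))]
  declared <- artifact$required_software
  list(language = artifact$language,
       registry_tools = unique(c(intersect(declared, known), scan_hits)),
       external_tools = setdiff(declared, known))
}

# --- scripted install universe -----------------------------------------------

#' Scripted providers over a software universe
#'
#' A software universe scripts, for every software, its installation methods:
#' each method has a dependency list and a finite outcome sequence
#' (`"success"` / `"code_error"`), consumed one entry per actual install
#' execution; an exhausted sequence keeps yielding code errors. An Install
#' call made while any dependency is uninstalled reports those dependencies
#' missing instead of consuming an outcome.
#'
#' @param universe a universe as built by [generate_software_universe()] or
#'   read from JSON (`list(software = list(<name> = list(methods = ...)))`).
#' @return `scripted_search_provider()`: a `function(name)` returning method
#'   descriptors; `scripted_install_provider()`: a
#'   `function(software, method, installed)` returning an install outcome
#'   `list(kind, missing, log)`.
#' @export
scripted_search_provider <- function(universe) {
  function(name) {
    sw <- universe$software[[name]]
    if (is.null(sw)) return(list())
    ms <- sw$methods
    lapply(seq_along(ms), function(i) {
      list(method_id = paste0(name, "#", i),
           description = ms[[i]]$description %||% paste0("method ", i, " for ", name),
           deps = as.character(ms[[i]]$deps %||% character(0)),
           outcomes = as.character(ms[[i]]$outcomes %||% character(0)))
    })
  }
}

#' @rdname scripted_search_provider
#' @export
scripted_install_provider <- function(universe) {
  cursors <- new.env(parent = emptyenv())
  function(software, method, installed) {
    missing <- setdiff(method$deps, installed)
    if (length(missing))
      return(list(kind = "missing_dependency", missing = missing,
                  log = paste0("missing: ", paste(missing, collapse = ", "))))
    key <- method$method_id
    n <- (cursors[[key]] %||% 0L) + 1L
    cursors[[key]] <- n
    kind <- if (n <= length(method$outcomes)) method$outcomes[[n]] else "code_error"
    list(kind = kind, missing = character(0),
         log = paste0(key, " attempt ", n, ": ", kind))
  }
}

# --- the backtracking algorithm ----------------------------------------------

#' Install software via the installation-tree backtracking algorithm
#'
#' See the module description under [env-config]. The returned tree is the
#' final annotated node structure (states: `installed`/`failed` for software
#' nodes, `succeeded`/`failed` for method nodes, with `attempts_used` per
#' method); the event log records every search, attempt, outcome, prune and
#' cycle detection in order.
#'
#' @param root name of the software to install.
#' @param search SearchMethod provider: `function(name)` returning a list of
#'   method descriptors (each at least `method_id`, `description`).
#' @param install Install provider:
#'   `function(software, method, installed)` returning
#'   `list(kind = "success"|"code_error"|"missing_dependency",
#'   missing = character, log = character)`.
#' @param max_attempts attempt budget per method node (default 5). Every
#'   Install call consumes one attempt.
#' @param registry optional [tool_registry()]; on success a new image entry
#'   covering everything installed in this run is stored for future reuse.
#' @return list with `result` (`"installed"` or `"failed"`), `tree` (root
#'   software node), `events` (list of event records), `install_calls`
#'   (total Install invocations), `installed` (software installed in this
#'   run).
#' @export
install_software <- function(root, search, install, max_attempts = 5L,
                             registry = NULL) {
  run <- new.env(parent = emptyenv())
  run$installed <- character(0)
  run$failed <- character(0)
  run$events <- list()
  run$calls <- 0L
  ev <- function(kind, software = NULL, method = NULL, detail = NULL) {
    run$events[[length(run$events) + 1L]] <- list(
      kind = kind, software = software, method = method, detail = detail)
  }

  install_node <- function(name, stack) {
    if (name %in% run$installed) {
      ev("reuse", software = name)
      return(list(name = name, state = "installed", reused = TRUE,
                  methods = list()))
    }
    if (name %in% run$failed) {
      ev("reuse-failed", software = name)
      return(list(name = name, state = "failed", reused = TRUE,
                  methods = list()))
    }
    ev("search", software = name)
    methods <- tryCatch(search(name), error = function(e) {
      ev("search-error", software = name, detail = conditionMessage(e))
      list()
    })
    node <- list(name = name, state = "pending", reused = FALSE,
                 methods = list())
    for (m in methods) {
      mnode <- list(method_id = m$method_id,
                    description = m$description %||% m$method_id,
                    attempts_used = 0L, max_attempts = as.integer(max_attempts),
                    state = "active", dependencies = list())
      repeat {
        if (mnode$attempts_used >= max_attempts) {
          mnode$state <- "failed"
          ev("prune-method", software = name, method = m$method_id,
             detail = "attempt budget exhausted")
          break
        }
        out <- install(name, m, run$installed)
        run$calls <- run$calls + 1L
        mnode$attempts_used <- mnode$attempts_used + 1L
        ev("attempt", software = name, method = m$method_id,
           detail = out$kind)
        if (identical(out$kind, "success")) {
          mnode$state <- "succeeded"
          node$state <- "installed"
          run$installed <- c(run$installed, name)
          ev("prune-software", software = name, method = m$method_id)
        } else if (identical(out$kind, "code_error")) {
          next
        } else if (identical(out$kind, "missing_dependency")) {
          dep_failed <- FALSE
          for (d in out$missing) {
            if (d %in% c(stack, name)) {
              ev("cycle", software = name, method = m$method_id,
                 detail = paste0("dependency already on stack: ", d))
              dep_failed <- TRUE
              break
            }
            child <- install_node(d, c(stack, name))
            mnode$dependencies[[length(mnode$dependencies) + 1L]] <- child
            if (!identical(child$state, "installed")) {
              dep_failed <- TRUE
              break
            }
          }
          if (dep_failed) {
            mnode$state <- "failed"
            ev("prune-method", software = name, method = m$method_id,
               detail = "dependency failed")
            break
          }
          next
        } else {
          mnode$state <- "failed"
          ev("prune-method", software = name, method = m$method_id,
             detail = paste0("unknown outcome kind: ", out$kind))
          break
        }
        break
      }
      node$methods[[length(node$methods) + 1L]] <- mnode
      if (identical(node$state, "installed")) break
    }
    if (!identical(node$state, "installed")) {
      node$state <- "failed"
      run$failed <- c(run$failed, name)
      ev("software-failed", software = name,
         detail = if (length(methods)) "all methods failed" else "no method found")
    }
    node
  }

  tree <- install_node(root, character(0))
  result <- if (identical(tree$state, "installed")) "installed" else "failed"
  if (result == "installed" && !is.null(registry)) {
    ref <- paste0("img/", root, ":", length(registry_entries(registry)) + 1L)
    registry_add(registry, ref, run$installed,
                 usage_notes = paste0("auto-built for ", root))
    ev("register-image", software = root, detail = ref)
  }
  list(result = result, tree = tree, events = run$events,
       install_calls = run$calls, installed = run$installed)
}

#' Is the installation tree emptied?
#'
#' Successful installs prune software nodes (with their method subtrees);
#' failed method nodes are pruned but leave their failed software node in
#' place. The tree is therefore emptied exactly when the root software node
#' was pruned by success.
#'
#' @param tree root software node from [install_software()].
#' @return logical scalar.
#' @export
tree_emptied <- function(tree) {
  count_unpruned <- function(s_node) {
    if (identical(s_node$state, "installed")) return(0L)
    1L + sum(vapply(s_node$methods, function(m)
      sum(vapply(m$dependencies, count_unpruned, integer(1)), 0L),
      integer(1)))
  }
  count_unpruned(tree) == 0L
}

#' Sum of attempt budgets over visited method nodes
#'
#' The upper bound on total Install calls: every call consumes one attempt
#' of some visited method node.
#'
#' @param tree root software node from [install_software()].
#' @return integer bound.
#' @export
attempt_budget_bound <- function(tree) {
  walk <- function(s_node) {
    sum(vapply(s_node$methods, function(m)
      m$max_attempts + sum(vapply(m$dependencies, walk, integer(1)), 0L),
      integer(1)), 0L)
  }
  walk(tree)
}

#' Emit a Dockerfile-style build recipe for an installed tree
#'
#' One RUN line per successful method, dependencies first — a readable record
#' of how the environment was produced.
#'
#' @param tree root software node of a successful [install_software()] run.
#' @return character scalar Dockerfile text.
#' @export
build_recipe <- function(tree) {
  lines <- character(0)
  walk <- function(s_node) {
    for (m in s_node$methods) {
      for (d in m$dependencies) walk(d)
      if (identical(m$state, "succeeded"))
        lines <<- c(lines, paste0("RUN # ", s_node$name, ": ", m$description))
    }
  }
  walk(tree)
  paste(c("FROM ubuntu:latest", lines), collapse = "\n")
}

#' Configure the runtime environment for a code artifact
#'
#' Requirements are parsed, registry tools resolved by lookup, compatible
#' images reused, and remaining external tools installed via
#' [install_software()] when search/install providers are supplied. Failures
#' never raise: the manifest lists them.
#'
#' @param artifact a [code_artifact()].
#' @param registry a [tool_registry()].
#' @param search,install optional providers for external installs.
#' @param max_attempts per-method attempt budget for installs.
#' @return list of class `environment_manifest`: `language`, `resolved`
#'   (named list tool -> list(image_ref, usage_notes, reused)), `failures`
#'   (character), `events`.
#' @export
configure_environment <- function(artifact, registry, search = NULL,
                                  install = NULL, max_attempts = 5L) {
  req <- parse_requirements(artifact, registry)
  resolved <- list()
  failures <- character(0)
  events <- list()
  for (tool in req$registry_tools) {
    e <- resolve_registry(registry, tool)
    resolved[[tool]] <- list(image_ref = e$image_ref,
                             usage_notes = e$usage_notes, reused = TRUE)
  }
  for (tool in req$external_tools) {
    hit <- find_compatible_image(registry, tool)
    if (!is.null(hit)) {
      resolved[[tool]] <- list(image_ref = hit$image_ref,
                               usage_notes = hit$usage_notes, reused = TRUE)
      events[[length(events) + 1L]] <- list(kind = "reuse-image", software = tool,
                                            detail = hit$image_ref)
      next
    }
    if (is.null(search) || is.null(install)) {
      failures <- c(failures, tool)
      next
    }
    res <- install_software(tool, search, install,
                            max_attempts = max_attempts, registry = registry)
    events <- c(events, res$events)
    if (res$result == "installed") {
      e <- find_compatible_image(registry, tool)
      resolved[[tool]] <- list(image_ref = e$image_ref,
                               usage_notes = e$usage_notes, reused = FALSE)
    } else {
      failures <- c(failures, tool)
    }
  }
  structure(list(language = req$language, resolved = resolved,
                 failures = failures, events = events),
            class = "environment_manifest")
}
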