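#' Prompt templates
#'
#' Prompts are plain-text bodies with `{name}` placeholders. Each template
#' exists in two modes: `full` (the engineered prompt) and `basic` (a minimal
#' task description used to measure how much the prompt engineering itself
#' contributes). The packaged store keeps one file per template id under
#' `templates/full/` and `templates/basic/`.
#'
#' @param template_id identifier, conventionally the operation name.
#' @param body template text with `{name}` placeholders.
#' @param mode `"full"` or `"basic"`.
#' @return object of class `prompt_template`.
#' @export
prompt_template <- function(template_id, body, mode = c("full", "basic")) {
  mode <- match.arg(mode)
  structure(list(template_id = template_id, body = body, mode = mode),
            class = "prompt_template")
}

template_placeholders <- function(body) {
  m <- gregexpr("\\{([a-zA-Z0-9_]+)\\}", body)[[1]]
  if (m[1] == -1) return(character(0))
  unique(substring(body, m + 1L, m + attr(m, "match.length") - 2L))
}

#' Render a template against a binding map
#'
#' @param template a [prompt_template()].
#' @param bindings named list or character vector covering every placeholder.
#' @return rendered text containing no unresolved placeholder.
#' @export
render_template <- function(template, bindings = list()) {
  body <- template$body
  ph <- template_placeholders(body)
  missing <- setdiff(ph, names(bindings))
  if (length(missing))
    adra_abort("missing_binding",
               paste0("no binding for placeholder '", missing[1], "' in template '",
                      template$template_id, "'"),
               data = list(placeholder = missing[1]))
  for (name in ph) {
    body <- gsub(paste0("{", name, "}"),
                 as.character(bindings[[name]]), body, fixed = TRUE)
  }
  body
}

#' Load a template store from disk
#'
#' @param dir directory holding `full/` and `basic/` subdirectories of
#'   `<template_id>.txt` files. Defaults to the store shipped with the
#'   package.
#' @param mode which mode renders are served from; every full template has a
#'   basic counterpart.
#' @return object of class `template_store`.
#' @export
template_store <- function(dir = system.file("templates", package = "adra"),
                           mode = c("full", "basic")) {
  mode <- match.arg(mode)
  store <- list(dir = dir, mode = mode, templates = list())
  for (m in c("full", "basic")) {
    files <- list.files(file.path(dir, m), pattern = "\\.txt$", full.names = TRUE)
    for (f in files) {
      id <- tools::file_path_sans_ext(basename(f))
      body <- paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
      store$templates[[m]][[id]] <- prompt_template(id, body, m)
    }
  }
  full_ids <- names(store$templates[["full"]])
  basic_ids <- names(store$templates[["basic"]])
  orphans <- setdiff(full_ids, basic_ids)
  if (length(orphans))
    adra_abort("parse", paste0("full template without basic counterpart: ",
                               paste(orphans, collapse = ", ")))
  structure(store, class = "template_store")
}

#' Fetch a template from a store
#' @param store a [template_store()].
#' @param template_id template name.
#' @return a [prompt_template()] in the store's mode.
#' @export
get_template <- function(store, template_id) {
  tpl <- store$templates[[store$mode]][[template_id]]
  if (is.null(tpl))
    adra_abort("not_found", paste0("no template '", template_id, "' in mode '",
                                   store$mode, "'"))
  tpl
}

# Render a store template and complete it in one step.
render_and_ask <- function(config, store, template_id, bindings,
                           check = function(parsed) NULL, provider = NULL) {
  prompt <- render_template(get_template(store, template_id), bindings)
  ask_structured(config, prompt, check = check, provider = provider)
}
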