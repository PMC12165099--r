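# Internal helpers shared across modules.

#' Round half away from zero at integer precision
#'
#' Reported percentages and efficiency multiples use commercial (half-up)
#' rounding, not banker's rounding: 87.5 reports as 88.
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @export
round_half_up <- function(x) {
  stopifnot(is.numeric(x))
  sign(x) * floor(abs(x) + 0.5)
}

# Polynomial rolling hash over UTF-8 bytes, mod the Mersenne prime 2^31-1,
# in double arithmetic (exact: intermediate values stay below 2^53). Used for
# stable content-derived identifiers; not cryptographic.
content_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x1f")))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read a JSON Lines file
#' @param path file path.
#' @return list with one element per non-empty line.
#' @export
read_jsonl <- function(path) {
  if (!file.exists(path)) adra_abort("io", paste0("no such file: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
}

#' Write a list of records as JSON Lines
#' @param records list of named lists.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(records, path) {
  lines <- vapply(
    records,
    function(r) jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null"),
    character(1)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Parse a provider response expected to be JSON. Tolerates code fences.
parse_provider_json <- function(text) {
  txt <- sub("^\\s*```[a-zA-Z]*\\s*", "", text)
  txt <- sub("\\s*```\\s*$", "", txt)
  tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
           error = function(e) NULL)
}

# Ask the provider, parse JSON, re-ask once with the parse error prepended,
# then raise a provider-format error. `check` returns a character string
# describing the defect, or NULL when the parsed value is acceptable.
ask_structured <- function(config, prompt, check = function(parsed) NULL,
                           provider = NULL) {
  for (attempt in 1:2) {
    p <- if (attempt == 1) prompt else paste0(
      "Your previous reply could not be used (", bad,
      "). Reply with valid JSON only.\n\n", prompt)
    resp <- complete(config, p, provider = provider)
    parsed <- parse_provider_json(resp)
    bad <- if (is.null(parsed)) "not valid JSON" else check(parsed)
    if (is.null(bad)) return(parsed)
  }
  adra_abort("provider_format",
             paste0("provider output unusable after one re-ask: ", bad))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
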