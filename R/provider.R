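#' Provider gateway
#'
#' Every text generation in the framework flows through a single contract:
#' a [provider_config()] names a registered provider, [complete()] sends a
#' rendered prompt to it, and the provider returns text. Providers are
#' pluggable; the two shipped with the package are a scripted transcript
#' player (deterministic replay for tests and reproducible runs) and a
#' recording wrapper that captures any provider's traffic as a transcript.
#' No other module may reach a network or process boundary to obtain text.
#'
#' @name provider-gateway
NULL

the_providers <- new.env(parent = emptyenv())

#' Provider configuration
#'
#' @param provider_id name under which the provider is registered (see
#'   [register_provider()]).
#' @param model_name model identifier passed through to the provider.
#' @param temperature non-negative sampling temperature. The framework default
#'   is 0 for every module except question raising, which uses the provider's
#'   own default (`NA`): deterministic adjudication, diverse ideation.
#' @param max_retries non-negative number of retries on transient provider
#'   failure. Retries use exponential backoff and never consume a transcript
#'   entry in replay mode.
#' @return an object of class `provider_config`.
#' @export
provider_config <- function(provider_id, model_name = "default",
                            temperature = 0, max_retries = 2L) {
  if (!is.na(temperature) && temperature < 0)
    adra_abort("domain", "temperature must be non-negative")
  if (max_retries < 0)
    adra_abort("domain", "max_retries must be non-negative")
  structure(
    list(provider_id = provider_id, model_name = model_name,
         temperature = temperature, max_retries = as.integer(max_retries)),
    class = "provider_config"
  )
}

#' Register a provider implementation
#'
#' A provider is any object with a `generate(provider, prompt, config)` method
#' (S3 generic [provider_generate()]). Registration makes it addressable from
#' a [provider_config()] by id.
#'
#' @param provider_id registration name.
#' @param provider provider object.
#' @return the provider, invisibly.
#' @export
register_provider <- function(provider_id, provider) {
  assign(provider_id, provider, envir = the_providers)
  invisible(provider)
}

#' @rdname register_provider
#' @export
unregister_provider <- function(provider_id) {
  if (exists(provider_id, envir = the_providers))
    rm(list = provider_id, envir = the_providers)
  invisible(NULL)
}

get_provider <- function(provider_id) {
  if (!exists(provider_id, envir = the_providers))
    adra_abort("provider_unavailable",
               paste0("no provider registered as '", provider_id, "'"))
  get(provider_id, envir = the_providers)
}

#' Low-level provider generation generic
#'
#' @param provider a provider object.
#' @param prompt character scalar.
#' @param config the [provider_config()] in effect.
#' @return character scalar response.
#' @export
provider_generate <- function(provider, prompt, config) {
  UseMethod("provider_generate")
}

#' Request a completion from a configured provider
#'
#' Transient provider failures (condition class `adra_provider_transient`)
#' are retried up to `config$max_retries` times with exponential backoff;
#' replay-exhaustion and format errors are not retried.
#'
#' @param config a [provider_config()]; `config$provider_id` must be
#'   registered, or `provider` must be supplied directly.
#' @param prompt rendered prompt text.
#' @param provider optional provider object, bypassing the registry.
#' @return non-empty character scalar.
#' @export
complete <- function(config, prompt, provider = NULL) {
  prov <- provider %||% get_provider(config$provider_id)
  attempt <- 0L
  repeat {
    resp <- tryCatch(provider_generate(prov, prompt, config),
                     adra_provider_transient = function(e) e)
    if (!inherits(resp, "condition")) {
      if (!is.character(resp) || length(resp) != 1L || !nzchar(resp))
        adra_abort("provider_unavailable", "provider returned empty response")
      return(resp)
    }
    attempt <- attempt + 1L
    if (attempt > config$max_retries)
      adra_abort("provider_unavailable",
                 paste0("provider failed after ", config$max_retries,
                        " retries: ", conditionMessage(resp)))
    Sys.sleep(min(2^(attempt - 1L) * 0.01, 1))
  }
}

# --- scripted (replay) provider ---------------------------------------------

#' Scripted transcript provider
#'
#' Replays recorded responses strictly in request order, which makes every
#' provider-dependent module deterministic under test. Requesting more
#' completions than the transcript holds raises a replay-exhausted error.
#'
#' @param responses character vector of responses, or a list of transcript
#'   entries as produced by [read_transcript()].
#' @return a provider object of class `scripted_provider`.
#' @export
scripted_provider <- function(responses) {
  if (is.list(responses))
    responses <- vapply(responses, function(e)
      if (is.list(e)) e$response else e, character(1))
  state <- new.env(parent = emptyenv())
  state$responses <- as.character(responses)
  state$cursor <- 0L
  structure(list(state = state), class = c("scripted_provider", "adra_provider"))
}

#' @export
provider_generate.scripted_provider <- function(provider, prompt, config) {
  st <- provider$state
  if (st$cursor >= length(st$responses))
    adra_abort("replay_exhausted",
               paste0("transcript exhausted after ", st$cursor, " responses"))
  st$cursor <- st$cursor + 1L
  st$responses[[st$cursor]]
}

#' Number of transcript entries consumed so far
#' @param provider a [scripted_provider()].
#' @return integer count of responses served.
#' @export
replay_position <- function(provider) provider$state$cursor

# --- function-backed provider (the seam for real backends) ------------------

#' Wrap a function as a provider
#'
#' The adapter for real backends: `fn(prompt, config)` must return a character
#' scalar. Real providers must honor `temperature = 0` as their most
#' deterministic mode.
#'
#' @param fn function of `(prompt, config)`.
#' @return a provider object.
#' @export
function_provider <- function(fn) {
  stopifnot(is.function(fn))
  structure(list(fn = fn), class = c("function_provider", "adra_provider"))
}

#' @export
provider_generate.function_provider <- function(provider, prompt, config) {
  provider$fn(prompt, config)
}

# --- recording wrapper -------------------------------------------------------

#' Record a provider's traffic as a transcript
#'
#' Wraps any provider; every completion is appended to an in-memory
#' transcript of `(request_hash, rendered_prompt, response, ordinal)`
#' entries. Replaying the written transcript through [scripted_provider()]
#' reproduces all responses byte-identically in request order.
#'
#' @param inner the provider to wrap.
#' @return a provider object of class `recording_provider`.
#' @export
recording_provider <- function(inner) {
  state <- new.env(parent = emptyenv())
  state$entries <- list()
  structure(list(inner = inner, state = state),
            class = c("recording_provider", "adra_provider"))
}

#' @export
provider_generate.recording_provider <- function(provider, prompt, config) {
  resp <- provider_generate(provider$inner, prompt, config)
  st <- provider$state
  ord <- length(st$entries) + 1L
  st$entries[[ord]] <- list(
    request_hash = content_hash(prompt),
    rendered_prompt = prompt,
    response = resp,
    ordinal = ord
  )
  resp
}

#' Retrieve or persist a recorded transcript
#'
#' Transcripts are JSON Lines, one entry per line, UTF-8, with strictly
#' increasing ordinals.
#'
#' @param provider a [recording_provider()].
#' @return for `recorded_transcript()`, the list of entries.
#' @export
recorded_transcript <- function(provider) provider$state$entries

#' @rdname recorded_transcript
#' @param path file path.
#' @export
write_transcript <- function(provider, path) {
  entries <- if (inherits(provider, "recording_provider"))
    recorded_transcript(provider) else provider
  write_jsonl(entries, path)
}

#' Read a transcript file
#' @param path JSON Lines transcript path.
#' @return list of transcript entries, validated for strictly increasing
#'   ordinals.
#' @export
read_transcript <- function(path) {
  entries <- read_jsonl(path)
  ords <- vapply(entries, function(e) as.integer(e$ordinal), integer(1))
  if (length(ords) && any(diff(ords) <= 0))
    adra_abort("parse", "transcript ordinals must strictly increase")
  entries
}
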