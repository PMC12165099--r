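#' Signal a classed framework error
#'
#' All errors raised by the package carry a subclass of `adra_error`, so
#' callers (and the orchestrator's per-question error containment) can route
#' on the error kind rather than match message text.
#'
#' @param class character; error subclass, e.g. `"provider_format"`. The
#'   condition signalled has classes `c(paste0("adra_", class), "adra_error",
#'   "error", "condition")`.
#' @param message human-readable message.
#' @param data optional named list attached to the condition.
#' @return does not return; signals the condition.
#' @keywords internal
adra_abort <- function(class, message, data = list()) {
  cond <- structure(
    class = c(paste0("adra_", class), "adra_error", "error", "condition"),
    c(list(message = message, call = sys.call(-1)), data)
  )
  stop(cond)
}

#' Test whether a condition is a given framework error
#' @param cond a condition object.
#' @param class error subclass without the `adra_` prefix.
#' @return logical scalar.
#' @export
is_adra_error <- function(cond, class = NULL) {
  if (!inherits(cond, "adra_error")) return(FALSE)
  if (is.null(class)) return(TRUE)
  inherits(cond, paste0("adra_", class))
}
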