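#' @keywords internal
"_PACKAGE"

# Classed error helper: every package error carries "rhizogeo_error" plus a
# specific subclass so callers (and tests) can distinguish contract violations.
rg_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "rhizogeo_error", "error")))
}

rg_check <- function(cond, message, class) {
  if (!isTRUE(cond)) rg_abort(message, class)
  invisible(TRUE)
}
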