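# internal helpers shared across modules

#' @keywords internal
snm_error <- function(subclass, message, call = sys.call(-1)) {
  stop(structure(
    class = c(subclass, "subnetmark_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' Derive a stage-specific child seed from a global seed
#'
#' Fans a single pipeline seed out to per-stage seeds so each stage is
#' independently reproducible. The rule is `(|seed| mod 1e5) * 10007 +
#' (sum of the stage name's UTF-8 code points mod 10007)`, which stays
#' below 2^31.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage)) %% 10007L
  as.integer((abs(as.integer(seed)) %% 100000L) * 10007L + h)
}

# format a numeric for deterministic text output: 10 significant digits
snm_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 10L, format = "g"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
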