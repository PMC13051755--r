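#' Derive a stage-specific seed from a master seed
#'
#' All stochastic stages of the pipeline draw their seed deterministically
#' from one master seed plus a stage label, so a single integer reproduces
#' the whole analysis bit-for-bit while stages stay independent.
#'
#' @param master integer master seed.
#' @param stage character stage label (e.g. "rarefy", "bnti").
#' @return an integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483629
  s <- ((abs(master) %% 2147483629) * 48271) %% 2147483629  # < 2^53, exact
  as.integer((s + h) %% 2147483629) + 1L
}

# internal: stop with a formatted message
abort <- function(...) stop(sprintf(...), call. = FALSE)

# internal: consistent informational logging to stderr
log_msg <- function(...) message(sprintf(...))
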