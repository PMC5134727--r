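#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a run-level seed
#'
#' All stochastic stages (simulation, splits, permutations) draw their seeds
#' from one run-level seed through named substreams, so that e.g. two GRM
#' weighting schemes evaluated under the same run seed see identical
#' train/test splits.  The derived seed is kept below 2^31 - 1.
#'
#' @param seed integer run-level seed.
#' @param label character substream name.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 1000003L
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

stop_wgp <- function(..., class = "wgpred_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
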