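#' @useDynLib gapnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed
#'
#' Mixes a master seed with any number of extra components (integers or
#' strings, e.g. a region id or a grid-cell index) into a single integer
#' seed in `[1, 2^31 - 2]`. The same inputs always give the same seed, so
#' per-region / per-cell work is reproducible and independent of execution
#' order.
#'
#' @param master integer master seed.
#' @param ... extra components: numbers or character scalars.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  M <- 2147483647 # 2^31 - 1, prime
  h <- abs(master) %% M
  for (part in list(...)) {
    codes <- if (is.character(part)) utf8ToInt(part) else as.numeric(part)
    for (v in codes) {
      # exact in doubles: h < 2^31, multiplier small
      h <- (h * 69069 + (abs(v) %% M) + 1) %% M
      h <- (h * 31 + 7) %% M
    }
  }
  as.integer(h %% (M - 2) + 1)
}

stop_input <- function(...) stop(..., call. = FALSE)
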