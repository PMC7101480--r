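## Internal helpers: condition classes, link functions, seed substreams.

ec_abort_validation <- function(message, ...) {
  abort(message, class = "effcov_validation_error", ...)
}

ec_abort_io <- function(message, ...) {
  abort(message, class = "effcov_io_error", ...)
}

#' Logit and antilogit maps
#'
#' `antilogit()` is the inverse-logit map \eqn{x \mapsto e^x/(1+e^x)}, used to
#' carry logit-scale interval endpoints back to the probability scale. Thin
#' wrappers over [stats::plogis()] / [stats::qlogis()] exported for use in
#' downstream code and oracles.
#'
#' @param x Numeric vector (any real for `antilogit`, in (0,1) for `logit`).
#' @return Numeric vector of the same length.
#' @examples
#' antilogit(0)        # 0.5
#' logit(antilogit(2)) # 2
#' @export
antilogit <- function(x) plogis(x)

#' @rdname antilogit
#' @export
logit <- function(x) qlogis(x)

## z quantile for a two-sided interval. The conventional 1.96 is used verbatim
## at the default 95% level (not qnorm(0.975) = 1.959964) so that intervals
## match the hard-coded 1.96 of the source formulas bit-for-bit.
ec_zvalue <- function(conf_level = 0.95) {
  stopifnot(is.numeric(conf_level), length(conf_level) == 1L,
            conf_level > 0, conf_level < 1)
  if (isTRUE(all.equal(conf_level, 0.95))) 1.96 else qnorm(1 - (1 - conf_level) / 2)
}

## Deterministic 31-bit integer substream seed from a master seed plus a
## character key (FNV-1a style). Keeps every derived seed in [0, 2^31 - 2] so
## grid subsets reproduce the corresponding cells of a full run.
ec_substream_seed <- function(master_seed, key) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed))
  bytes <- utf8ToInt(paste0(format(master_seed, scientific = FALSE), "|", key))
  ## xor on 16-bit halves keeps everything inside integer range; the state h
  ## lives in doubles mod 2^32 (exact: well below 2^53)
  xor32 <- function(a, b) {
    bitwXor(a %% 65536, b %% 65536) +
      65536 * bitwXor(a %/% 65536, b %/% 65536)
  }
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    ## 32-bit multiply by the FNV prime 16777619 = 2^24 + 403; only the low
    ## 8 bits of h survive the 2^24 shift mod 2^32, so every term is exact
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

ec_check_prop <- function(x, name) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) {
    ec_abort_validation(sprintf("`%s` must lie in [0, 1]; got %s",
                                name, paste(format(x[bad][1]), collapse = ", ")))
  }
  invisible(x)
}

ec_check_count <- function(x, name, min = 1) {
  bad <- !is.na(x) & (x < min | x != floor(x))
  if (any(bad)) {
    ec_abort_validation(sprintf("`%s` must be an integer >= %s; got %s",
                                name, min, format(x[bad][1])))
  }
  invisible(x)
}

ec_status_levels <- c("valid", "invalid_bounds", "degenerate", "undefined")
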