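#' @keywords internal
"_PACKAGE"

#' @importFrom stats qnorm pnorm rnorm runif rpois rbinom median sd var cor
#'   cor.test predict complete.cases p.adjust
#' @importFrom utils head modifyList packageVersion
#' @importFrom data.table data.table as.data.table rbindlist setattr setorder
#'   fread fwrite
NULL

# Stop with a classed condition so callers/tests can match on error class.
sf_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "splicefve_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

sf_assert <- function(cond, class, msg, ...) {
  if (!isTRUE(cond)) sf_stop(class, msg, ...)
  invisible(TRUE)
}

#' Clip values into the open unit interval
#'
#' @param x numeric vector.
#' @param eps clipping bound in (0, 0.5); values are forced into
#'   `[eps, 1 - eps]`.
#' @return clipped numeric vector (NAs preserved).
#' @keywords internal
clip_unit <- function(x, eps = 1e-6) {
  sf_assert(is.numeric(eps) && length(eps) == 1 && eps > 0 && eps < 0.5,
            "invalid_input", "eps must be a single number in (0, 0.5)")
  pmin(pmax(x, eps), 1 - eps)
}

# Deterministic per-stage seed derived from a global seed and a stage label.
# Polynomial string hash folded into [0, 2^31 - 2]; stable across platforms.
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1, is.character(stage), length(stage) == 1)
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# Standardize a vector to mean 0, sd 1 (sample sd).
standardize <- function(x, what = "input") {
  s <- stats::sd(x)
  sf_assert(is.finite(s) && s > 0, "degenerate_input",
            "%s has zero variance and cannot be standardized", what)
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
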