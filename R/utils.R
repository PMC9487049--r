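# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Geometric mean
#'
#' @param x positive numeric vector.
#' @return `exp(mean(log(x)))`.
#' @keywords internal
geomean <- function(x) {
  if (any(x <= 0)) stop("geometric mean requires strictly positive values", call. = FALSE)
  exp(mean(log(x)))
}

#' Derive reproducible child seeds from a single master seed
#'
#' A single pipeline seed fans out into independent per-stage seeds so that
#' each stage (spatial generation, expression, survival, ...) can be re-run in
#' isolation and still reproduce the full-run output.
#'
#' @param seed integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  if (length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

# consistent error with no call clutter
.err <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# significance stars at the figure-legend levels
.stars <- function(p) {
  ifelse(is.na(p), "",
    ifelse(p < 1e-4, "****",
      ifelse(p < 1e-3, "***",
        ifelse(p < 0.01, "**",
          ifelse(p < 0.05, "*", "ns")))))
}
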