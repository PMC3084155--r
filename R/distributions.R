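#' Sampling distribution attached to a model parameter
#'
#' Every scalar input of the model carries both a base-case value (used for
#' deterministic runs) and a sampling law (used by the probabilistic
#' sensitivity analysis). Four laws are supported: `uniform(p1, p2)` with
#' lower/upper bounds, `lognormal(p1, p2)` where `p1`/`p2` are the mean and
#' standard deviation of the natural log, `normal(p1, p2)` with mean and
#' standard deviation, and `fixed` (never redrawn).
#'
#' @param kind one of `"uniform"`, `"lognormal"`, `"normal"`, `"fixed"`.
#' @param p1,p2 distribution parameters (see Details); ignored for `"fixed"`.
#' @param base base-case value. Defaults: uniform midpoint, normal mean,
#'   lognormal median `exp(p1)`; required for `"fixed"`.
#' @return an object of class `dist_spec`.
#' @examples
#' dist_spec("uniform", 10.26, 19.06)      # base = midpoint 14.66
#' dist_spec("lognormal", 4.36, 1.39, base = 206.43)
#' dist_spec("fixed", base = 0)
#' @export
dist_spec <- function(kind = c("uniform", "lognormal", "normal", "fixed"),
                      p1 = NA_real_, p2 = NA_real_, base = NULL) {
  kind <- match.arg(kind)
  if (is.null(base)) {
    base <- switch(kind,
      uniform   = (p1 + p2) / 2,
      lognormal = exp(p1),
      normal    = p1,
      fixed     = stop("a fixed dist_spec needs an explicit `base`",
                       call. = FALSE))
  }
  spec <- structure(list(kind = kind, p1 = as.numeric(p1), p2 = as.numeric(p2),
                         base = as.numeric(base)),
                    class = "dist_spec")
  validate_dist_spec(spec)
  spec
}

validate_dist_spec <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  with(spec, {
    if (!is.finite(base)) stop("dist_spec base must be finite", call. = FALSE)
    switch(kind,
      uniform = {
        if (!is.finite(p1) || !is.finite(p2) || p1 > p2)
          stop("uniform dist_spec needs p1 <= p2", call. = FALSE)
        if (base < p1 || base > p2)
          stop("uniform base ", base, " outside [", p1, ", ", p2, "]",
               call. = FALSE)
      },
      lognormal = {
        if (!is.finite(p2) || p2 <= 0)
          stop("lognormal dist_spec needs sigma > 0", call. = FALSE)
      },
      normal = {
        if (!is.finite(p2) || p2 < 0)
          stop("normal dist_spec needs sd >= 0", call. = FALSE)
      },
      fixed = NULL)
  })
  invisible(spec)
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec> %s(%s) base %.4g\n", x$kind,
              if (x$kind == "fixed") "" else sprintf("%.4g, %.4g", x$p1, x$p2),
              x$base))
  invisible(x)
}

#' Draw from a parameter's sampling distribution
#'
#' Normal draws can be truncated to a support interval by resampling; this is
#' used for probabilities (support `[0, 1]`) and hazard ratios (support
#' `(0, 1.5]`), where at the printed standard deviations truncation is
#' vanishingly rare but keeps the contract total.
#'
#' @param spec a [dist_spec()].
#' @param n number of draws.
#' @param support optional length-2 numeric: truncation interval for normal
#'   draws.
#' @return numeric vector of length `n`.
#' @export
draw_dist <- function(spec, n = 1L, support = NULL) {
  validate_dist_spec(spec)
  out <- switch(spec$kind,
    uniform   = stats::runif(n, spec$p1, spec$p2),
    lognormal = stats::rlnorm(n, spec$p1, spec$p2),
    normal    = stats::rnorm(n, spec$p1, spec$p2),
    fixed     = rep(spec$base, n))
  if (!is.null(support) && spec$kind == "normal") {
    bad <- which(out <= support[1] | out > support[2])
    while (length(bad)) {
      out[bad] <- stats::rnorm(length(bad), spec$p1, spec$p2)
      bad <- bad[out[bad] <= support[1] | out[bad] > support[2]]
    }
  }
  out
}

#' Central 95% interval of a dist_spec (used for tornado bounds)
#' @param spec a [dist_spec()].
#' @return numeric length 2 (`NA` for fixed parameters).
#' @keywords internal
dist_bounds <- function(spec) {
  switch(spec$kind,
    uniform   = c(spec$p1, spec$p2),
    lognormal = exp(spec$p1 + c(-1, 1) * stats::qnorm(0.975) * spec$p2),
    normal    = spec$p1 + c(-1, 1) * stats::qnorm(0.975) * spec$p2,
    fixed     = c(NA_real_, NA_real_))
}

#' Theoretical mean implied by a dist_spec
#' @keywords internal
dist_mean <- function(spec) {
  switch(spec$kind,
    uniform   = (spec$p1 + spec$p2) / 2,
    lognormal = exp(spec$p1 + spec$p2^2 / 2),
    normal    = spec$p1,
    fixed     = spec$base)
}
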