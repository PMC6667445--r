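#' Prepare a trait vector for log-scale analysis
#'
#' Traits that are negative by sign convention (water potentials, osmotic
#' potentials) are multiplied by -1 before log transformation so power-law
#' relationships can be fitted on magnitudes.
#'
#' @param x Numeric trait vector.
#' @return List with `value` (possibly negated), `negated` flag, and
#'   `loggable` (TRUE when all non-missing values are positive after the sign
#'   rule).
#' @export
sign_rule <- function(x) {
  ok <- !is.na(x)
  negated <- FALSE
  if (any(ok) && all(x[ok] < 0)) {
    x <- -x
    negated <- TRUE
  }
  list(value = x, negated = negated, loggable = all(x[ok] > 0))
}

#' Pearson correlation on raw and log scales
#'
#' Computes the Pearson coefficient for untransformed and log-transformed
#' data (modelling the relationship as linear or approximately power-law) and
#' marks the stronger fit (larger |r|) as selected. Negative-valued traits
#' are negated before logging per [sign_rule()].
#'
#' @param x,y Numeric trait vectors (pairwise complete cases used).
#' @return data.frame with one row per scale: `scale`, `r`, `p`, `n`,
#'   `selected`, `x_negated`, `y_negated`.
#' @export
pearson_both_scales <- function(x, y) {
  cc <- stats::complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  raw <- stats::cor.test(x, y)
  sx <- sign_rule(x); sy <- sign_rule(y)
  out <- data.frame(
    scale = "raw", r = unname(raw$estimate), p = raw$p.value, n = n,
    selected = NA, x_negated = FALSE, y_negated = FALSE,
    stringsAsFactors = FALSE)
  if (sx$loggable && sy$loggable) {
    lg <- stats::cor.test(log(sx$value), log(sy$value))
    out <- rbind(out, data.frame(
      scale = "log", r = unname(lg$estimate), p = lg$p.value, n = n,
      selected = NA, x_negated = sx$negated, y_negated = sy$negated,
      stringsAsFactors = FALSE))
  }
  out$selected <- abs(out$r) == max(abs(out$r))
  out
}

#' Standard major axis fit
#'
#' Symmetric line fit for structural trait-trait relationships:
#' slope \eqn{= sign(r)\,sd(y)/sd(x)}, line through the means.
#'
#' @param x,y Numeric vectors (complete pairs used).
#' @param scale `"raw"` or `"log"` (applies [sign_rule()] then logs).
#' @param group Optional label carried through.
#' @return An `sma_fit` list: `slope`, `intercept`, `r`, `n`, `scale`,
#'   `group`.
#' @examples
#' sma_fit(c(1, 2, 3), c(2, 4, 7))$slope  # ~2.517
#' @export
sma_fit <- function(x, y, scale = c("raw", "log"), group = NA_character_) {
  scale <- match.arg(scale)
  cc <- stats::complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (scale == "log") {
    sx <- sign_rule(x); sy <- sign_rule(y)
    if (!sx$loggable || !sy$loggable) {
      stop("non-positive values after sign rule; cannot log-transform",
           call. = FALSE)
    }
    x <- log(sx$value); y <- log(sy$value)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: SMA fit is degenerate", call. = FALSE)
  }
  r <- stats::cor(x, y)
  slope <- sign(r) * stats::sd(y) / stats::sd(x)
  if (r == 0) slope <- stats::sd(y) / stats::sd(x)  # sign convention for r = 0
  structure(list(slope = slope, intercept = mean(y) - slope * mean(x),
                 r = r, n = length(x), scale = scale, group = group),
            class = "sma_fit")
}

# Correlation between SMA residual and fitted axis scores for candidate
# slope b: zero exactly at the group's own SMA slope.
.sma_resid_fitted_cor <- function(x, y, b) {
  u <- y - b * x
  v <- y + b * x
  if (stats::sd(u) == 0 || stats::sd(v) == 0) return(0)
  stats::cor(u, v)
}

#' Heterogeneity of SMA slopes (and elevations) across groups
#'
#' Likelihood-ratio test for a common SMA slope across groups, using the
#' residual-versus-fitted-axis correlation formulation: at a candidate common
#' slope \eqn{b}, each group contributes \eqn{-n_i \log(1 - r_{uv,i}^2(b))};
#' the statistic minimized over \eqn{b} is compared to \eqn{\chi^2_{g-1}}.
#' When the common slope is not rejected, a Wald elevation test compares the
#' group intercepts at the common slope.
#'
#' @param groups List of lists/data.frames each with elements `x` and `y`
#'   (already on the analysis scale, typically log).
#' @param min_n Groups with fewer pairs are dropped with a warning.
#' @param alpha Significance level gating the elevation test.
#' @return List: `slope_stat`, `slope_df`, `slope_p`, `common_slope`,
#'   `elevation_stat`, `elevation_df`, `elevation_p` (NA when slopes differ),
#'   `n_groups`.
#' @export
sma_heterogeneity_test <- function(groups, min_n = 3, alpha = 0.05) {
  keep <- vapply(groups, function(g) {
    sum(stats::complete.cases(g$x, g$y)) >= min_n
  }, logical(1))
  if (any(!keep)) {
    warning(sum(!keep), " group(s) dropped (fewer than ", min_n, " pairs)")
  }
  groups <- groups[keep]
  if (length(groups) < 2) stop("need at least 2 usable groups", call. = FALSE)
  xs <- lapply(groups, function(g) {
    cc <- stats::complete.cases(g$x, g$y)
    list(x = g$x[cc], y = g$y[cc])
  })
  # work on the positive-slope orientation: flip y when the prevailing
  # correlation is negative, and restore the sign at the end
  rs <- vapply(xs, function(g) stats::cor(g$x, g$y), numeric(1))
  flipped <- sum(sign(rs)) < 0
  if (flipped) xs <- lapply(xs, function(g) list(x = g$x, y = -g$y))
  lr <- function(logb) {
    b <- exp(logb)
    sum(vapply(xs, function(g) {
      -length(g$x) * log(1 - .sma_resid_fitted_cor(g$x, g$y, b)^2)
    }, numeric(1)))
  }
  own <- vapply(xs, function(g) abs(sma_fit(g$x, g$y)$slope), numeric(1))
  opt <- stats::optimize(lr, interval = log(range(own)) + c(-2, 2),
                         tol = 1e-10)
  common_slope <- exp(opt$minimum)
  stat <- opt$objective
  df <- length(xs) - 1L
  slope_p <- stats::pchisq(stat, df, lower.tail = FALSE)

  elevation_stat <- elevation_p <- NA_real_
  if (slope_p > alpha) {
    ints <- vapply(xs, function(g) mean(g$y) - common_slope * mean(g$x),
                   numeric(1))
    vars <- vapply(xs, function(g) {
      res <- g$y - common_slope * g$x
      stats::var(res) / length(g$x)
    }, numeric(1))
    w <- 1 / vars
    grand <- sum(w * ints) / sum(w)
    elevation_stat <- sum(w * (ints - grand)^2)
    elevation_p <- stats::pchisq(elevation_stat, df, lower.tail = FALSE)
  }
  list(slope_stat = stat, slope_df = df, slope_p = slope_p,
       common_slope = if (flipped) -common_slope else common_slope,
       elevation_stat = elevation_stat,
       elevation_df = df, elevation_p = elevation_p, n_groups = length(xs))
}
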