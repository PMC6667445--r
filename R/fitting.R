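#' @keywords internal
#' AICc for a Gaussian least-squares fit.
#' With i.i.d. Gaussian errors of unknown sigma, maximum likelihood is least
#' squares with sigma^2 = RSS/n, and (dropping the additive constant)
#' AICc = n log(RSS/n) + 2k + 2k(k+1)/(n - k - 1), k counting sigma.
.aicc <- function(rss, n, k) {
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Profiled residual sum of squares: the families are linear in their
# amplitude parameters given the nonlinear ones, so those are concentrated
# out with a linear solve and the optimizer only sees 1-2 dimensions.
.profile_rss <- function(g, basis) {
  qr_b <- qr(basis)
  if (qr_b$rank < ncol(basis)) return(list(rss = Inf, coef = NULL))
  co <- qr.coef(qr_b, g)
  res <- g - basis %*% co
  list(rss = sum(res^2), coef = co)
}

#' Fit one response family to a species dataset
#'
#' Gaussian maximum-likelihood (equivalently least-squares) fit of a single
#' candidate family, using deterministic multistart optimization: the
#' amplitude parameters are profiled out analytically and the remaining one or
#' two nonlinear parameters are optimized from a grid of data-driven starts
#' (quantiles of the observed potentials for midpoints, log-spaced shape
#' values). The fit is a pure function of the data: no random number use.
#'
#' @param dataset A `species_response` with `gs_adj` populated (typically
#'   after [refine_dataset()]).
#' @param family_name One of [family_names()].
#' @return A `fitted_response` with elements `family`, `rss`, `sigma_hat`,
#'   `n`, `k`, `aicc`, `converged`, and the observed psi range (used later to
#'   bracket root-finding). Derived quantities are `NA` until
#'   [derive_parameters()].
#' @export
fit_family <- function(dataset, family_name) {
  stopifnot(inherits(dataset, "species_response"), dataset$gmin_subtracted)
  family_name <- match.arg(family_name, family_names())
  psi <- dataset$points$psi_leaf
  g <- dataset$points$gs_adj
  n <- length(g)
  n_par <- length(.family_registry[[family_name]]$pars)
  if (n < n_par + 2) {
    stop("need at least ", n_par + 2, " points to fit the ", family_name,
         " family (got ", n, ")", call. = FALSE)
  }
  if (length(unique(psi)) < 2) {
    stop("degenerate dataset: all psi_leaf identical", call. = FALSE)
  }

  fit <- switch(family_name,
    linear = .fit_linear(psi, g),
    exponential = .fit_exponential(psi, g),
    sigmoidal = .fit_sigmoidal(psi, g),
    logistic = .fit_logistic(psi, g)
  )

  k <- n_par + 1  # + error SD
  structure(
    list(
      species_id = dataset$species_id,
      family = if (fit$converged) response_family(family_name, fit$pars) else NULL,
      family_name = family_name,
      rss = fit$rss,
      sigma_hat = sqrt(fit$rss / n),
      n = n,
      k = k,
      aicc = if (fit$converged) .aicc(fit$rss, n, k) else Inf,
      converged = fit$converged,
      psi_range = range(psi),
      gmax = NA_real_, psi_gs20 = NA_real_, psi_gs50 = NA_real_,
      psi_gs80 = NA_real_, fit_pvalue = NA_real_, reference_psi = NA_real_,
      derived_warning = FALSE
    ),
    class = "fitted_response"
  )
}

.fit_linear <- function(psi, g) {
  co <- stats::lm.fit(cbind(1, psi), g)$coefficients
  pars <- c(a = unname(co[2]), g0 = unname(co[1]))
  rss <- sum((g - (pars["g0"] + pars["a"] * psi))^2)
  list(pars = pars, rss = rss, converged = TRUE)
}

.fit_exponential <- function(psi, g) {
  # g = g0 + a exp(-b psi); on psi <= 0, b < 0 gives decline with dehydration.
  # Profile (g0, a) by linear solve; scan b deterministically, refine by Brent.
  obj <- function(b) .profile_rss(g, cbind(1, exp(-b * psi)))$rss
  b_grid <- -exp(seq(log(0.01), log(30), length.out = 40))
  vals <- vapply(b_grid, obj, numeric(1))
  i <- which.min(vals)
  lo <- b_grid[min(length(b_grid), i + 1L)]
  hi <- b_grid[max(1L, i - 1L)]
  opt <- stats::optimize(obj, lower = lo, upper = hi, tol = 1e-10)
  b <- opt$minimum
  pr <- .profile_rss(g, cbind(1, exp(-b * psi)))
  if (!is.finite(pr$rss)) return(list(pars = NULL, rss = Inf, converged = FALSE))
  list(pars = c(g0 = unname(pr$coef[1]), a = unname(pr$coef[2]), b = b),
       rss = pr$rss, converged = TRUE)
}

.fit_sigmoidal <- function(psi, g) {
  shape <- function(th) 1 / (1 + exp(-(psi - th[1]) / exp(th[2])))
  obj <- function(th) {
    s <- shape(th)
    ss <- sum(s^2)
    if (!is.finite(ss) || ss == 0) return(Inf)
    a <- sum(g * s) / ss
    sum((g - a * s)^2)
  }
  span <- diff(range(psi))
  x0_starts <- stats::quantile(psi, c(0.2, 0.35, 0.5, 0.65, 0.8), names = FALSE)
  b_starts <- span * c(0.03, 0.08, 0.2, 0.5)
  best <- list(value = Inf)
  for (x0s in x0_starts) for (bs in b_starts) {
    o <- tryCatch(
      stats::optim(c(x0s, log(bs)), obj, method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(o) && o$value < best$value) best <- o
  }
  if (!is.finite(best$value)) return(list(pars = NULL, rss = Inf, converged = FALSE))
  th <- best$par
  s <- shape(th)
  a <- sum(g * s) / sum(s^2)
  list(pars = c(a = a, b = exp(th[2]), x0 = th[1]), rss = best$value,
       converged = TRUE)
}

.fit_logistic <- function(psi, g) {
  # a / (1 + (psi/x0)^b): enforce x0 < 0, b > 0 via log parameterization
  shape <- function(th) {
    x0 <- -exp(th[1]); b <- exp(th[2])
    1 / (1 + (psi / x0)^b)
  }
  obj <- function(th) {
    s <- shape(th)
    ss <- sum(s^2)
    if (!is.finite(ss) || ss == 0) return(Inf)
    a <- sum(g * s) / ss
    sum((g - a * s)^2)
  }
  x0_starts <- stats::quantile(psi[psi < 0], c(0.2, 0.35, 0.5, 0.65, 0.8),
                               names = FALSE)
  x0_starts <- x0_starts[x0_starts < 0]
  b_starts <- c(1, 2, 4, 8)
  best <- list(value = Inf)
  for (x0s in x0_starts) for (bs in b_starts) {
    o <- tryCatch(
      stats::optim(c(log(-x0s), log(bs)), obj, method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(o) && o$value < best$value) best <- o
  }
  if (!is.finite(best$value)) return(list(pars = NULL, rss = Inf, converged = FALSE))
  th <- best$par
  s <- shape(th)
  a <- sum(g * s) / sum(s^2)
  list(pars = c(a = a, b = exp(th[2]), x0 = -exp(th[1])), rss = best$value,
       converged = TRUE)
}

#' Select the best family by AICc
#'
#' Returns the converged fit with the lowest AICc. Differences below 2 are not
#' considered meaningful: among all candidates within 2 AICc units of the
#' best, the one with fewest parameters wins, remaining ties broken by the
#' fixed family order of [family_names()].
#'
#' @param fits List of `fitted_response` objects (one per family).
#' @return The selected `fitted_response`, with an `aicc_table` attribute
#'   (data.frame of family, k, rss, aicc, delta_aicc, converged).
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 1)
  tab <- data.frame(
    family = vapply(fits, function(f) f$family_name, character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    rss = vapply(fits, function(f) f$rss, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1)),
    stringsAsFactors = FALSE
  )
  ok <- tab$converged & is.finite(tab$aicc)
  if (!any(ok)) stop("no converged fit to select from", call. = FALSE)
  best_aicc <- min(tab$aicc[ok])
  tab$delta_aicc <- tab$aicc - best_aicc
  cand <- which(ok & tab$delta_aicc < 2)
  cand <- cand[order(tab$k[cand],
                     match(tab$family[cand], family_names()))]
  sel <- fits[[cand[1]]]
  attr(sel, "aicc_table") <- tab
  sel
}

#' Derive g_max and closure-threshold water potentials
#'
#' Evaluates the selected curve at `reference_psi` (0 MPa by default, or -0.1
#' for the sensitivity re-analysis) to obtain \eqn{g_{max}}, then finds the
#' water potentials at 20, 50 and 80 percent decline from \eqn{g_{max}} by
#' bracketed bisection on \eqn{[1.5\,\Psi_{min,obs},\ reference]} (tolerance
#' 1e-6 MPa), taking the most-hydrated root when several exist. For the
#' logistic family with `reference_psi = 0`, \eqn{\Psi_{gs50} = x_0} exactly.
#' Thresholds the curve never reaches inside the bracket are returned as `NA`
#' with the `derived_warning` flag set.
#'
#' @param fit A converged `fitted_response` (from [select_model()]).
#' @param reference_psi Water potential (MPa) defining \eqn{g_{max}}.
#' @return The fit with `gmax`, `psi_gs20`, `psi_gs50`, `psi_gs80` filled in.
#' @export
derive_parameters <- function(fit, reference_psi = 0) {
  stopifnot(inherits(fit, "fitted_response"), isTRUE(fit$converged))
  fam <- fit$family
  fit$reference_psi <- reference_psi
  fit$gmax <- evaluate_family(fam, reference_psi)
  lo <- 1.5 * min(fit$psi_range)
  for (x in c(20, 50, 80)) {
    slot <- paste0("psi_gs", x)
    if (fam$name == "logistic" && x == 50 && reference_psi == 0) {
      fit[[slot]] <- fam$parameters[["x0"]]
      next
    }
    target <- (1 - x / 100) * fit$gmax
    fit[[slot]] <- .most_hydrated_root(fam, target, lo, reference_psi)
    if (is.na(fit[[slot]])) fit$derived_warning <- TRUE
  }
  fit
}

# Most-hydrated psi in [lo, hi] with curve(psi) == target; NA when the curve
# never crosses the target inside the bracket.
.most_hydrated_root <- function(fam, target, lo, hi) {
  f <- function(p) evaluate_family(fam, p) - target
  grid <- seq(hi, lo, length.out = 257L)
  fv <- f(grid)
  if (abs(fv[1]) < 1e-12) return(grid[1])
  cross <- which(fv[-1] * fv[-length(fv)] <= 0)
  if (!length(cross)) return(NA_real_)
  i <- cross[1]
  a <- grid[i + 1]; b <- grid[i]  # a more negative than b
  # bisection to 1e-6 MPa
  fa <- f(a); fb <- f(b)
  if (fa == 0) return(a)
  for (iter in 1:80) {
    mid <- (a + b) / 2
    fm <- f(mid)
    if (abs(b - a) < 1e-7 || fm == 0) return(mid)
    if (sign(fm) == sign(fb)) { b <- mid; fb <- fm } else { a <- mid; fa <- fm }
  }
  (a + b) / 2
}

#' Likelihood-ratio significance of a fitted response
#'
#' Tests the selected model against the constant-\eqn{g_s} null by a
#' likelihood-ratio test: \eqn{LR = n \log(RSS_0/RSS_1)} compared to
#' \eqn{\chi^2} with `n_params - 1` degrees of freedom.
#'
#' @param dataset The `species_response` the fit used (after any refinement).
#' @param fit The selected `fitted_response`.
#' @return The fit with `fit_pvalue` set.
#' @export
fit_significance <- function(dataset, fit) {
  stopifnot(inherits(dataset, "species_response"),
            inherits(fit, "fitted_response"), isTRUE(fit$converged))
  g <- dataset$points$gs_adj
  n <- length(g)
  rss0 <- sum((g - mean(g))^2)
  df <- fit$family$n_params - 1L
  if (fit$rss <= 0) {
    fit$fit_pvalue <- 0
    return(fit)
  }
  lr <- n * log(rss0 / fit$rss)
  fit$fit_pvalue <- stats::pchisq(max(0, lr), df = max(1L, df),
                                  lower.tail = FALSE)
  fit
}

#' Full per-species fitting path
#'
#' Convenience wrapper chaining the per-species stages: g_min subtraction
#' (done at construction), optional refinement filtering, fitting of all four
#' families, AICc selection, derivation of \eqn{g_{max}} and
#' \eqn{\Psi_{gs20/50/80}}, and the likelihood-ratio significance test.
#'
#' @param dataset A `species_response`.
#' @param mode `"refined"` (apply [refine_dataset()]) or `"all"`.
#' @param reference_psi Reference potential for \eqn{g_{max}} (0 or -0.1 MPa).
#' @param families Families to try, default all four.
#' @param ... Threshold overrides passed to [refine_dataset()].
#' @return List with `fit` (selected, derived, tested), `report` (refinement
#'   report or `NULL` in `"all"` mode), `aicc_table`, and the `dataset`
#'   actually fitted.
#' @export
fit_response <- function(dataset, mode = c("refined", "all"),
                         reference_psi = 0, families = family_names(), ...) {
  mode <- match.arg(mode)
  report <- NULL
  if (mode == "refined") {
    r <- refine_dataset(dataset, ...)
    dataset <- r$dataset
    report <- r$report
  }
  if (nrow(dataset$points) < 6) {
    stop("species '", dataset$species_id, "': fewer than 6 points ",
         if (mode == "refined") "after refinement" else "", call. = FALSE)
  }
  fits <- lapply(families, function(fn) {
    tryCatch(fit_family(dataset, fn), error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("all family fits failed for species '",
                          dataset$species_id, "'", call. = FALSE)
  sel <- select_model(fits)
  tab <- attr(sel, "aicc_table")
  sel <- derive_parameters(sel, reference_psi = reference_psi)
  sel <- fit_significance(dataset, sel)
  list(fit = sel, report = report, aicc_table = tab, dataset = dataset)
}

#' @export
print.fitted_response <- function(x, ...) {
  cat("<fitted_response>", x$species_id, "family:", x$family_name,
      sprintf("(AICc %.2f, n %d)\n", x$aicc, x$n))
  if (!is.na(x$gmax)) {
    cat(sprintf("  gmax %.1f at psi = %g; psi_gs20/50/80 = %.3f / %.3f / %.3f; p = %.3g\n",
                x$gmax, x$reference_psi, x$psi_gs20, x$psi_gs50, x$psi_gs80,
                x$fit_pvalue))
  }
  invisible(x)
}
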