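#' Phylogenetic covariance matrix under an evolutionary model
#'
#' Builds the among-species trait covariance implied by the tree:
#' \describe{
#'   \item{BM}{Brownian motion: shared branch-length matrix `ape::vcv`.}
#'   \item{lambda}{Pagel's lambda: off-diagonal entries of the BM matrix
#'     multiplied by \eqn{\lambda \in [0, 1]} (0 = star/independence,
#'     1 = BM).}
#'   \item{OU}{Ornstein-Uhlenbeck with strength \eqn{\alpha}, conditioned on
#'     the root: \eqn{V_{ij} = e^{-2\alpha T}(e^{2\alpha s_{ij}} - 1)/(2\alpha)}
#'     where \eqn{s_{ij}} is the shared path length and \eqn{T} the tree
#'     height; recovers BM as \eqn{\alpha \to 0}. Non-ultrametric trees are
#'     height-normalized with a warning (OU is ill-posed on them otherwise).}
#' }
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param model `"BM"`, `"lambda"`, or `"OU"`.
#' @param parameter lambda (for `"lambda"`) or alpha (for `"OU"`); ignored
#'   for `"BM"`.
#' @return Covariance matrix with tip labels as dimnames.
#' @export
phylo_vcv <- function(tree, model = c("BM", "lambda", "OU"), parameter = NULL) {
  model <- match.arg(model)
  V <- ape::vcv(tree)
  if (model == "BM") return(V)
  if (model == "lambda") {
    lam <- parameter
    stopifnot(is.numeric(lam), lam >= 0, lam <= 1)
    Vl <- V * lam
    diag(Vl) <- diag(V)
    return(Vl)
  }
  alpha <- parameter
  stopifnot(is.numeric(alpha), alpha >= 0)
  if (!ape::is.ultrametric(tree, tol = 1e-6)) {
    warning("OU covariance on a non-ultrametric tree: height-normalizing")
    d <- diag(V)
    V <- V / sqrt(outer(d, d)) * max(d)
  }
  if (alpha < 1e-10) return(V)
  TT <- max(diag(V))
  exp(-2 * alpha * TT) * (exp(2 * alpha * V) - 1) / (2 * alpha)
}

# GLS fit of y ~ x with covariance V (profiled sigma^2).
# Returns coefficients, loglik, SEs, GLS-weighted R^2.
.gls_core <- function(x, y, V) {
  n <- length(y)
  X <- cbind(1, x)
  L <- chol(V)  # V = t(L) %*% L
  Xs <- backsolve(L, X, transpose = TRUE)
  ys <- backsolve(L, y, transpose = TRUE)
  fit <- stats::lm.fit(Xs, ys)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n  # ML estimate
  logdetV <- 2 * sum(log(diag(L)))
  loglik <- -0.5 * (n * log(2 * pi * sigma2) + logdetV + n)
  XtX_inv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(diag(XtX_inv) * rss / (n - 2))
  # phylogenetically weighted mean of y for the GLS R^2
  ones <- backsolve(L, rep(1, n), transpose = TRUE)
  mu_y <- sum(ones * ys) / sum(ones^2)
  tss <- sum((ys - ones * mu_y)^2)
  r2 <- 1 - rss / tss
  list(beta = beta, se = se, rss = rss, sigma2 = sigma2, loglik = loglik,
       r2 = r2, n = n)
}

#' Phylogenetic generalized least squares regression
#'
#' GLS regression of `y` on `x` with residual covariance from shared
#' phylogenetic branch lengths, under Brownian motion, Pagel's lambda
#' (\eqn{\hat\lambda} by ML on [0, 1]) or Ornstein-Uhlenbeck
#' (\eqn{\hat\alpha} by ML, log-grid plus bounded refinement). The tree is
#' pruned to the complete-case species; a name mismatch is an error listing
#' the offenders.
#'
#' The reported correlation-like `r` is a convention, not a sample
#' statistic: \eqn{r = sign(slope)\sqrt{R^2_{GLS}}} with the GLS
#' \eqn{R^2} computed about the phylogenetically weighted mean. The raw
#' slope and its SE are always reported alongside.
#'
#' @param x,y Named numeric vectors (names = species ids) or unnamed vectors
#'   ordered as `tree$tip.label`.
#' @param tree An `ape::phylo`.
#' @param model `"BM"`, `"lambda"`, or `"OU"`.
#' @return A `pgls_result` list: `method`, `slope`, `slope_se`, `intercept`,
#'   `r`, `p` (t-test on the slope), `n`, `loglik`, `aic`, `k`,
#'   `lambda_or_alpha`.
#' @export
pgls_fit <- function(x, y, tree, model = c("BM", "lambda", "OU")) {
  model <- match.arg(model)
  d <- .align_to_tree(x, y, tree)
  tree <- d$tree; x <- d$x; y <- d$y
  n <- length(y)
  if (n < 3) stop("need at least 3 complete-case species", call. = FALSE)

  fit_at <- function(par) {
    V <- phylo_vcv(tree, model, parameter = par)
    .gls_core(x, y, V)
  }
  par_hat <- NA_real_
  if (model == "BM") {
    core <- fit_at(NULL)
    k <- 3L  # intercept, slope, sigma^2
  } else if (model == "lambda") {
    opt <- stats::optimize(function(l) -fit_at(l)$loglik, c(0, 1), tol = 1e-8)
    # compare against the boundary values: optimize can miss edge optima
    cand <- c(opt$minimum, 0, 1)
    lls <- vapply(cand, function(l) fit_at(l)$loglik, numeric(1))
    par_hat <- cand[which.max(lls)]
    core <- fit_at(par_hat)
    k <- 4L
  } else {
    TT <- max(diag(ape::vcv(tree)))
    agrid <- c(1e-8, 10^seq(-3, 1.3, length.out = 12) / TT)
    lls <- vapply(agrid, function(a) fit_at(a)$loglik, numeric(1))
    i <- which.max(lls)
    lo <- agrid[max(1, i - 1)]; hi <- agrid[min(length(agrid), i + 1)]
    opt <- stats::optimize(function(a) -fit_at(a)$loglik, c(lo, hi),
                           tol = 1e-9)
    par_hat <- if (-opt$objective > lls[i]) opt$minimum else agrid[i]
    core <- fit_at(par_hat)
    k <- 4L
  }
  slope <- unname(core$beta[2])
  tstat <- slope / core$se[2]
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  structure(
    list(method = paste0("pgls-", model), slope = slope,
         slope_se = core$se[2], intercept = unname(core$beta[1]),
         r = sign(slope) * sqrt(max(0, core$r2)), p = p, n = n,
         loglik = core$loglik, aic = -2 * core$loglik + 2 * k, k = k,
         lambda_or_alpha = par_hat),
    class = "pgls_result")
}

.align_to_tree <- function(x, y, tree) {
  if (is.null(names(x)) && is.null(names(y))) {
    stopifnot(length(x) == ape::Ntip(tree), length(y) == ape::Ntip(tree))
    names(x) <- names(y) <- tree$tip.label
  }
  ids <- intersect(names(x), names(y))
  cc <- ids[stats::complete.cases(x[ids], y[ids])]
  missing_tips <- setdiff(cc, tree$tip.label)
  if (length(missing_tips)) {
    stop("species absent from the tree: ",
         paste(missing_tips, collapse = ", "), call. = FALSE)
  }
  drop <- setdiff(tree$tip.label, cc)
  if (length(drop)) tree <- ape::drop.tip(tree, drop)
  list(tree = tree, x = x[tree$tip.label], y = y[tree$tip.label])
}

#' PGLS with evolutionary-model selection by AIC
#'
#' Fits BM, Pagel's lambda, and OU, and returns the lowest-AIC model, with
#' the stated preference for the lambda model when lambda and OU are equally
#' good fits (AIC difference < 2).
#'
#' @inheritParams pgls_fit
#' @return The selected `pgls_result`, with an `aic_table` attribute.
#' @export
pgls_model_select <- function(x, y, tree) {
  fits <- list()
  for (m in c("BM", "lambda", "OU")) {
    fits[[m]] <- tryCatch(pgls_fit(x, y, tree, model = m),
                          warning = function(w) {
                            suppressWarnings(pgls_fit(x, y, tree, model = m))
                          },
                          error = function(e) NULL)
  }
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("all PGLS models failed", call. = FALSE)
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  sel <- names(which.min(aics))
  if (!is.null(fits$lambda) && !is.null(fits$OU) && sel == "OU" &&
      abs(fits$lambda$aic - fits$OU$aic) < 2) {
    sel <- "lambda"
  }
  out <- fits[[sel]]
  attr(out, "aic_table") <- data.frame(model = names(aics), aic = unname(aics))
  out
}

#' @export
print.pgls_result <- function(x, ...) {
  cat(sprintf(
    "<pgls_result> %s: slope %.4f (SE %.4f), r = %.3f, p = %.3g, n = %d, AIC = %.2f",
    x$method, x$slope, x$slope_se, x$r, x$p, x$n, x$aic))
  if (!is.na(x$lambda_or_alpha)) cat(sprintf(", par = %.3f", x$lambda_or_alpha))
  cat("\n")
  invisible(x)
}
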