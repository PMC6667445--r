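#' Candidate response families for gs(Psi_leaf)
#'
#' Four function families describe the decline of stomatal conductance
#' \eqn{g_s} with leaf water potential \eqn{\Psi_{leaf}} (MPa, non-positive):
#'
#' \describe{
#'   \item{linear}{\eqn{g_s = g_0 + a\Psi}}
#'   \item{sigmoidal}{\eqn{g_s = a / (1 + e^{-(\Psi - x_0)/b})}}
#'   \item{logistic}{\eqn{g_s = a / (1 + (\Psi/x_0)^b)}}
#'   \item{exponential}{\eqn{g_s = g_0 + a e^{-b\Psi}}}
#' }
#'
#' The parameter printed as a "maximum" inside the linear and exponential
#' formulas is stored as `g0`: the reported maximum conductance is always the
#' fitted curve evaluated at the reference potential (see
#' [derive_parameters()]), never a raw parameter.
#'
#' @param name One of `"linear"`, `"sigmoidal"`, `"logistic"`, `"exponential"`.
#' @param parameters Named numeric vector of the family's parameters.
#' @return An object of class `response_family`.
#' @seealso [evaluate_family()], [fit_family()]
#' @export
response_family <- function(name, parameters) {
  name <- match.arg(name, names(.family_registry))
  spec <- .family_registry[[name]]
  parameters <- unlist(parameters)
  missing <- setdiff(spec$pars, names(parameters))
  if (length(missing)) {
    stop("family '", name, "' needs parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (name == "logistic" && parameters[["x0"]] == 0) {
    stop("logistic family requires x0 != 0", call. = FALSE)
  }
  structure(
    list(name = name, parameters = parameters[spec$pars],
         n_params = length(spec$pars)),
    class = "response_family"
  )
}

# Registry: parameter names, curve function, and data-driven multistart
# heuristics for each family. `fun` takes (psi, p) with p a named vector.
.family_registry <- list(
  linear = list(
    pars = c("a", "g0"),
    fun = function(psi, p) p[["g0"]] + p[["a"]] * psi
  ),
  exponential = list(
    pars = c("g0", "a", "b"),
    fun = function(psi, p) p[["g0"]] + p[["a"]] * exp(-p[["b"]] * psi)
  ),
  sigmoidal = list(
    pars = c("a", "b", "x0"),
    fun = function(psi, p) p[["a"]] / (1 + exp(-(psi - p[["x0"]]) / p[["b"]]))
  ),
  logistic = list(
    pars = c("a", "b", "x0"),
    # psi <= 0 and x0 < 0 keep psi/x0 >= 0 so the power is well defined
    fun = function(psi, p) p[["a"]] / (1 + (psi / p[["x0"]])^p[["b"]])
  )
)

#' Family names in canonical order
#'
#' Order also serves as the deterministic tie-break in [select_model()]:
#' linear, exponential, sigmoidal, logistic.
#' @return Character vector of the four family names.
#' @export
family_names <- function() c("linear", "exponential", "sigmoidal", "logistic")

#' Evaluate a response family at given water potentials
#'
#' @param family A `response_family` object (or family name, with `parameters`
#'   supplied).
#' @param psi Numeric vector of leaf water potentials (MPa, \eqn{\le 0}).
#' @param parameters Optional named parameter vector when `family` is a name.
#' @return Numeric vector of conductances (same units as the fitted data).
#' @examples
#' evaluate_family(response_family("linear", c(a = 100, g0 = 300)), -1)  # 200
#' @export
evaluate_family <- function(family, psi, parameters = NULL) {
  if (is.character(family)) family <- response_family(family, parameters)
  stopifnot(inherits(family, "response_family"))
  .family_registry[[family$name]]$fun(psi, family$parameters)
}

#' @export
print.response_family <- function(x, ...) {
  cat("<response_family>", x$name, "\n")
  print(x$parameters)
  invisible(x)
}
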