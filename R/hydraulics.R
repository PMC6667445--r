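#' Organ hydraulic vulnerability curve
#'
#' Sigmoidal dependence of hydraulic conductance on water potential:
#' \deqn{K(\Psi) = K_{max} / (1 + e^{\alpha(\Psi - \Psi_{50})})}
#' with \eqn{K(\Psi_{50}) = K_{max}/2} exactly.
#'
#' @details With the conventional \eqn{\alpha > 0} this form saturates at
#' \eqn{K_{max}} for strongly negative \eqn{\Psi} and falls below
#' \eqn{K_{max}/2} at potentials above \eqn{\Psi_{50}}; e.g. with
#' `Kmax = 10, psi50 = -1, alpha = 3`, \eqn{K(0) \approx 0.474}. The shape
#' parameter \eqn{\alpha} (MPa^-1) is a free default (3 for every organ)
#' since organ-level steepness is rarely reported; it can be overridden per
#' curve for sensitivity sweeps.
#'
#' @param Kmax Maximum conductance, mmol m^-2 s^-1 MPa^-1 (leaf-area basis).
#' @param psi50 Water potential at 50 percent conductance loss, MPa.
#' @param alpha Shape, MPa^-1 (> 0).
#' @return A `vulnerability_curve` object.
#' @export
vulnerability_curve <- function(Kmax, psi50, alpha = 3) {
  stopifnot(Kmax > 0, alpha > 0, is.finite(psi50))
  structure(list(Kmax = Kmax, psi50 = psi50, alpha = alpha),
            class = "vulnerability_curve")
}

#' Hydraulic conductance at a water potential
#'
#' @param curve A [vulnerability_curve()].
#' @param psi Water potential(s), MPa.
#' @return K(psi), mmol m^-2 s^-1 MPa^-1.
#' @examples
#' conductance_at(vulnerability_curve(10, -1, 3), -1)  # Kmax/2 = 5
#' @export
conductance_at <- function(curve, psi) {
  stopifnot(inherits(curve, "vulnerability_curve"), all(is.finite(psi)))
  curve$Kmax / (1 + exp(curve$alpha * (psi - curve$psi50)))
}

# Overflow-safe log(1 + exp(x))
.log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Kirchhoff flux capacity between two potentials
#'
#' The Kirchhoff transform linearizes potential-dependent conductance: the
#' steady flux sustainable between potentials is
#' \eqn{\int_{lo}^{hi} K(\Psi)\,d\Psi}. For the sigmoidal vulnerability curve
#' this has the closed form
#' \deqn{K_{max}\left[\Psi - \tfrac{1}{\alpha}\log(1 + e^{\alpha(\Psi-\Psi_{50})})\right]_{lo}^{hi}}
#' evaluated with an overflow-safe log-sum-exp.
#'
#' @param curve A [vulnerability_curve()].
#' @param psi_lo,psi_hi Integration bounds, MPa, `psi_lo <= psi_hi`.
#' @param allow_reversed If `TRUE`, reversed bounds return the sign-correct
#'   value instead of erroring.
#' @return Flux capacity, mmol m^-2 s^-1.
#' @export
kirchhoff_capacity <- function(curve, psi_lo, psi_hi, allow_reversed = FALSE) {
  stopifnot(inherits(curve, "vulnerability_curve"))
  if (psi_lo > psi_hi) {
    if (!allow_reversed) stop("psi_lo > psi_hi", call. = FALSE)
    return(-kirchhoff_capacity(curve, psi_hi, psi_lo))
  }
  antideriv <- function(p) {
    curve$Kmax * (p - .log1pexp(curve$alpha * (p - curve$psi50)) / curve$alpha)
  }
  antideriv(psi_hi) - antideriv(psi_lo)
}

#' Stomatal closure response to leaf water potential
#'
#' Exponential decline anchored at both ends of its definition:
#' \deqn{g_s(\Psi) = g_{max}\, 2^{\Psi/|\Psi_{gs50}|}}
#' so \eqn{g_s(0) = g_{max}} and \eqn{g_s(\Psi_{gs50}) = g_{max}/2} hold by
#' construction (each MPa of dehydration beyond \eqn{\Psi_{gs50}} halves
#' conductance again).
#'
#' @param gmax Conductance at full hydration, mmol m^-2 s^-1.
#' @param psi_gs50 Water potential at 50 percent closure, MPa (< 0).
#' @return A `stomatal_closure` object.
#' @export
stomatal_closure <- function(gmax, psi_gs50) {
  stopifnot(gmax > 0)
  if (!is.finite(psi_gs50) || psi_gs50 >= 0) {
    stop("psi_gs50 must be finite and < 0", call. = FALSE)
  }
  structure(list(gmax = gmax, psi_gs50 = psi_gs50), class = "stomatal_closure")
}

#' Stomatal conductance at a leaf water potential
#'
#' @param response A [stomatal_closure()].
#' @param psi_leaf Leaf water potential(s), MPa (<= 0).
#' @return g_s, mmol m^-2 s^-1.
#' @examples
#' stomatal_conductance_at(stomatal_closure(300, -1), -2)  # 75
#' @export
stomatal_conductance_at <- function(response, psi_leaf) {
  stopifnot(inherits(response, "stomatal_closure"), all(psi_leaf <= 0))
  response$gmax * 2^(psi_leaf / abs(response$psi_gs50))
}

#' Photosynthesis parameters (carboxylation-limited, light-saturated)
#'
#' Defaults are literature values for a typical Mediterranean evergreen oak:
#' Vcmax 29.1 umol m^-2 s^-1, Km 550 ppm, Gamma* 40 ppm, dark respiration R
#' 1 umol m^-2 s^-1, atmospheric CO2 400 ppm.
#'
#' @param Vcmax,Km,gamma_star,R,ca See description; all positive and
#'   `gamma_star < ca`.
#' @return A `photo_params` object.
#' @export
photo_params <- function(Vcmax = 29.1, Km = 550, gamma_star = 40, R = 1,
                         ca = 400) {
  stopifnot(Vcmax > 0, Km > 0, gamma_star > 0, R > 0, ca > 0, gamma_star < ca)
  structure(list(Vcmax = Vcmax, Km = Km, gamma_star = gamma_star, R = R,
                 ca = ca), class = "photo_params")
}

#' Net assimilation as a function of stomatal conductance
#'
#' Closed-form solution of Fick's law \eqn{A = u(c_a - c_i)} combined with
#' carboxylation-limited net photosynthesis
#' \eqn{A = V_{cmax}(c_i - \Gamma^*)/(c_i + K_m) - R}:
#' \deqn{A = a + b u - \sqrt{b^2 u^2 + c u + a^2}}
#' with \eqn{a = 0.5(V_{cmax} - R)}, \eqn{b = 0.5(c_a + K_m)},
#' \eqn{c = 0.5[R(c_a + K_m) + V_{cmax}(K_m - c_a + 2\Gamma^*)]}, and
#' \eqn{u = g_s/1600} the CO2 conductance in mol m^-2 s^-1 (the 1600 combines
#' the mmol-to-mol conversion with the 1.6 H2O/CO2 diffusivity ratio).
#'
#' @param gs Stomatal conductance to water vapor, mmol m^-2 s^-1 (>= 0);
#'   vectorized.
#' @param params A [photo_params()].
#' @return Net assimilation A, umol m^-2 s^-1. `A(0) = 0` exactly.
#' @examples
#' photosynthesis(200)  # ~8.614
#' @export
photosynthesis <- function(gs, params = photo_params()) {
  if (any(gs < 0)) stop("gs must be >= 0", call. = FALSE)
  u <- gs / 1600
  a <- 0.5 * (params$Vcmax - params$R)
  b <- 0.5 * (params$ca + params$Km)
  cc <- 0.5 * (params$R * (params$ca + params$Km) +
                 params$Vcmax * (params$Km - params$ca + 2 * params$gamma_star))
  a + b * u - sqrt(b^2 * u^2 + cc * u + a^2)
}

#' Whole-plant system for the steady-state model
#'
#' Three organ vulnerability curves in series (root, stem, leaf), the stomatal
#' closure response, and photosynthesis parameters. Defaults follow the
#' typical-parameter design: Kmax (leaf, stem, root) = (10, 20, 10)
#' mmol m^-2 s^-1 MPa^-1, Psi50 = (-1, -2, -1) MPa, shared shape alpha = 3.
#'
#' @param leaf,stem,root [vulnerability_curve()] objects.
#' @param stomata A [stomatal_closure()].
#' @param photo A [photo_params()].
#' @return A `plant_system` object.
#' @export
plant_system <- function(leaf = vulnerability_curve(10, -1),
                         stem = vulnerability_curve(20, -2),
                         root = vulnerability_curve(10, -1),
                         stomata = stomatal_closure(300, -1),
                         photo = photo_params()) {
  stopifnot(inherits(leaf, "vulnerability_curve"),
            inherits(stem, "vulnerability_curve"),
            inherits(root, "vulnerability_curve"),
            inherits(stomata, "stomatal_closure"),
            inherits(photo, "photo_params"))
  structure(list(leaf = leaf, stem = stem, root = root, stomata = stomata,
                 photo = photo), class = "plant_system")
}

#' Environmental forcing
#'
#' @param psi_soil Soil water potential, MPa (default 0; -1.2 for drought).
#' @param vpd Vapor pressure deficit as a mole fraction (default 0.01, i.e.,
#'   about 1 kPa).
#' @return An `environment_state` object.
#' @export
environment_state <- function(psi_soil = 0, vpd = 0.01) {
  stopifnot(is.finite(psi_soil), psi_soil <= 0, vpd >= 0)
  structure(list(psi_soil = psi_soil, vpd = vpd), class = "environment_state")
}

# Net fluxes into leaf, stem, root (all zero at steady state).
.fluxes <- function(plant, env, psi) {
  # psi = c(leaf, stem, root)
  E <- stomatal_conductance_at(plant$stomata, min(psi[1], 0)) * env$vpd
  f_leaf <- kirchhoff_capacity(plant$leaf, psi[1], psi[2],
                               allow_reversed = TRUE) - E
  f_stem <- kirchhoff_capacity(plant$stem, psi[2], psi[3],
                               allow_reversed = TRUE) -
    kirchhoff_capacity(plant$leaf, psi[1], psi[2], allow_reversed = TRUE)
  f_root <- kirchhoff_capacity(plant$root, psi[3], env$psi_soil,
                               allow_reversed = TRUE) -
    kirchhoff_capacity(plant$stem, psi[2], psi[3], allow_reversed = TRUE)
  c(f_leaf, f_stem, f_root)
}

#' Steady-state solution of the hydraulic-stomatal-photosynthetic model
#'
#' Solves for the organ water potentials at which the net volumetric flux
#' into leaf, stem and root is zero, i.e., the transpiration demand
#' \eqn{E = g_s(\Psi_{leaf})\,VPD} equals the Kirchhoff flux capacity of each
#' series element. A damped Newton iteration on
#' \eqn{(\Psi_{leaf}, \Psi_{stem}, \Psi_{root})} (finite-difference Jacobian,
#' step halving) is tried first; if it fails to reach tolerance, a robust
#' nested-bisection fallback exploits series continuity: given
#' \eqn{\Psi_{leaf}}, E is known, \eqn{\Psi_{root}} and \eqn{\Psi_{stem}}
#' follow from 1-D root finding, and the leaf flux residual is driven to zero
#' in \eqn{\Psi_{leaf}} alone.
#'
#' @param plant A [plant_system()].
#' @param env An [environment_state()].
#' @param tol Residual flux tolerance (mmol m^-2 s^-1), default 1e-10.
#' @return A `steady_state` list: `psi_leaf`, `psi_stem`, `psi_root`, `gs`,
#'   `E`, `A`, `residuals` (length-3), `converged`.
#' @export
solve_steady_state <- function(plant, env, tol = 1e-10) {
  stopifnot(inherits(plant, "plant_system"), inherits(env, "environment_state"))
  if (env$vpd == 0) {
    p <- rep(env$psi_soil, 3)
    return(.pack_solution(plant, env, p, .fluxes(plant, env, p), TRUE))
  }
  sol <- .newton_solve(plant, env, tol)
  if (!sol$converged) sol <- .nested_solve(plant, env, tol)
  sol
}

.pack_solution <- function(plant, env, psi, res, converged) {
  gs <- stomatal_conductance_at(plant$stomata, min(psi[1], 0))
  structure(
    list(psi_leaf = psi[1], psi_stem = psi[2], psi_root = psi[3],
         gs = gs, E = gs * env$vpd, A = photosynthesis(gs, plant$photo),
         residuals = res, converged = converged),
    class = "steady_state")
}

.newton_solve <- function(plant, env, tol, maxit = 60) {
  psi <- rep(env$psi_soil, 3) - c(3e-2, 2e-2, 1e-2)
  f <- .fluxes(plant, env, psi)
  for (it in seq_len(maxit)) {
    if (max(abs(f)) < tol) return(.pack_solution(plant, env, psi, f, TRUE))
    J <- matrix(0, 3, 3)
    hstep <- 1e-7 * pmax(1, abs(psi))
    for (j in 1:3) {
      pj <- psi; pj[j] <- pj[j] + hstep[j]
      J[, j] <- (.fluxes(plant, env, pj) - f) / hstep[j]
    }
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lambda <- 1
    improved <- FALSE
    for (half in 1:25) {
      cand <- psi + lambda * step
      cand <- pmin(cand, env$psi_soil)  # potentials cannot exceed the soil
      fc <- .fluxes(plant, env, cand)
      if (all(is.finite(fc)) && max(abs(fc)) < max(abs(f))) {
        psi <- cand; f <- fc; improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  if (max(abs(f)) < tol) return(.pack_solution(plant, env, psi, f, TRUE))
  .pack_solution(plant, env, psi, f, FALSE)
}

# Nested bisection using series continuity: E(psi_leaf) fixes the flux that
# the root and stem segments must carry, each solvable by monotone 1-D root
# finding in the upstream potential.
.nested_solve <- function(plant, env, tol) {
  solve_upstream <- function(curve, E, psi_up_hi) {
    # find psi (<= psi_up_hi) with capacity(psi, psi_up_hi) == E
    f <- function(p) kirchhoff_capacity(curve, p, psi_up_hi) - E
    lo <- psi_up_hi - 1
    while (f(lo) < 0 && lo > -200) lo <- lo - 1
    if (f(lo) < 0) return(NA_real_)  # supply cannot meet demand
    stats::uniroot(f, c(lo, psi_up_hi), tol = 1e-12)$root
  }
  leaf_residual <- function(psi_leaf) {
    E <- stomatal_conductance_at(plant$stomata, psi_leaf) * env$vpd
    psi_root <- solve_upstream(plant$root, E, env$psi_soil)
    if (is.na(psi_root)) return(NA_real_)
    psi_stem <- solve_upstream(plant$stem, E, psi_root)
    if (is.na(psi_stem)) return(NA_real_)
    kirchhoff_capacity(plant$leaf, psi_leaf, psi_stem,
                       allow_reversed = TRUE) - E
  }
  lo <- env$psi_soil - 1
  r_lo <- leaf_residual(lo)
  tries <- 0
  while (!is.na(r_lo) && r_lo < 0 && tries < 200) {
    lo <- lo - 1; r_lo <- leaf_residual(lo); tries <- tries + 1
  }
  hi <- env$psi_soil
  r_hi <- leaf_residual(hi)
  if (is.na(r_lo) || is.na(r_hi) || r_lo < 0 || r_hi > 0) {
    return(.pack_solution(plant, env, rep(env$psi_soil, 3),
                          rep(Inf, 3), FALSE))
  }
  psi_leaf <- stats::uniroot(leaf_residual, c(lo, hi), tol = 1e-13)$root
  E <- stomatal_conductance_at(plant$stomata, psi_leaf) * env$vpd
  psi_root <- solve_upstream(plant$root, E, env$psi_soil)
  psi_stem <- solve_upstream(plant$stem, E, psi_root)
  psi <- c(psi_leaf, psi_stem, psi_root)
  res <- .fluxes(plant, env, psi)
  .pack_solution(plant, env, psi, res, max(abs(res)) < max(tol, 1e-8))
}

#' Simulate a g_max x Psi_gs50 grid
#'
#' Runs [solve_steady_state()] for every combination of `gmax`, `psi_gs50`
#' and environment, holding all other plant parameters fixed. The default
#' grid spans gmax 100 to 400 mmol m^-2 s^-1 in steps of 10 and Psi_gs50 -0.2
#' to -3 MPa in steps of 0.2, under well-watered (0 MPa) and drought (-1.2
#' MPa) soil at VPD 0.01 mol mol^-1.
#'
#' @param plant_template A [plant_system()] supplying everything except the
#'   stomatal response.
#' @param environments List of [environment_state()] objects.
#' @param gmax_grid,psi_gs50_grid Numeric grids.
#' @return Tidy data.frame: `gmax`, `psi_gs50`, `psi_soil`, `vpd`, `gs`, `E`,
#'   `A`, `psi_leaf`, `psi_stem`, `psi_root`, `max_residual`, `converged`.
#' @export
run_grid <- function(plant_template = plant_system(),
                     environments = list(environment_state(0, 0.01),
                                         environment_state(-1.2, 0.01)),
                     gmax_grid = seq(100, 400, by = 10),
                     psi_gs50_grid = seq(-3, -0.2, by = 0.2)) {
  stopifnot(length(gmax_grid) >= 1, length(psi_gs50_grid) >= 1)
  rows <- vector("list", length(gmax_grid) * length(psi_gs50_grid) *
                   length(environments))
  i <- 0L
  for (env in environments) {
    for (p50 in psi_gs50_grid) {
      for (gm in gmax_grid) {
        plant <- plant_template
        plant$stomata <- stomatal_closure(gm, p50)
        s <- solve_steady_state(plant, env)
        i <- i + 1L
        rows[[i]] <- data.frame(
          gmax = gm, psi_gs50 = p50, psi_soil = env$psi_soil, vpd = env$vpd,
          gs = s$gs, E = s$E, A = s$A, psi_leaf = s$psi_leaf,
          psi_stem = s$psi_stem, psi_root = s$psi_root,
          max_residual = max(abs(s$residuals)), converged = s$converged)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf(
    "<steady_state> psi(leaf,stem,root) = (%.4f, %.4f, %.4f) MPa; gs = %.2f; E = %.4f; A = %.3f%s\n",
    x$psi_leaf, x$psi_stem, x$psi_root, x$gs, x$E, x$A,
    if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}
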