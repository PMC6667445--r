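#' Biophysical constants for anatomical conductance
#'
#' Diffusivity of water vapor in air `D` (m^2 s^-1), molar volume of air `v`
#' (m^3 mol^-1), and the derived constant `b = D/v` (mol m^-1 s^-1).
#'
#' @param D Diffusivity of water in air, default 2.82e-5 m^2 s^-1.
#' @param v Molar volume of air, default 2.24e-2 m^3 mol^-1.
#' @return List with `D`, `v`, `b`.
#' @export
anatomy_constants <- function(D = 2.82e-5, v = 2.24e-2) {
  stopifnot(D > 0, v > 0)
  list(D = D, v = v, b = D / v)
}

#' Theoretical anatomical maximum stomatal conductance
#'
#' Computes \deqn{g_{max,anatomy} = b\, m\, d\, s / \sqrt{s}}{g = b m d s / sqrt(s)}
#' with the geometry factor \eqn{m = \pi c^2 / (\sqrt{j}\,(4 h j + \pi))},
#' \eqn{c = p/L}, \eqn{j = W/L}. The pore-depth-to-width ratio `h` defaults to
#' 0.5 (pore depth is rarely measured). The formula is evaluated in SI units;
#' because unit confusion is the classic failure mode here, inputs must be
#' tagged with their units and are converted explicitly.
#'
#' @param d Stomatal density (both surfaces summed).
#' @param s Mean stomatal areal size (single stoma, abaxial surface).
#' @param W Stomatal width.
#' @param L Guard cell length.
#' @param p Stomatal pore length.
#' @param h Pore depth / pore width ratio, default 0.5.
#' @param units Units of the inputs: `"field"` (d in mm^-2, s in um^2, lengths
#'   in um -- the customary microscopy units) or `"SI"` (m^-2, m^2, m).
#' @param constants From [anatomy_constants()].
#' @return g_max,anatomy in mol m^-2 s^-1 (vectorized over rows).
#' @examples
#' gmax_anatomy(d = 3e8, s = 2e-10, W = 10e-6, L = 20e-6, p = 10e-6,
#'              units = "SI")  # ~1.43 mol m-2 s-1
#' @export
gmax_anatomy <- function(d, s, W, L, p, h = 0.5, units = c("field", "SI"),
                         constants = anatomy_constants()) {
  units <- match.arg(units)
  if (units == "field") {
    d <- d * 1e6        # mm^-2 -> m^-2
    s <- s * 1e-12      # um^2  -> m^2
    W <- W * 1e-6; L <- L * 1e-6; p <- p * 1e-6
  }
  if (any(L <= 0)) stop("guard cell length L must be > 0", call. = FALSE)
  if (any(c(s, W, p) <= 0) || any(d < 0)) {
    stop("anatomy dimensions must be positive (d >= 0)", call. = FALSE)
  }
  if (any(p > L) || any(W > L)) {
    stop("pore length p and width W cannot exceed guard cell length L",
         call. = FALSE)
  }
  cc <- p / L
  j <- W / L
  m <- pi * cc^2 / (sqrt(j) * (4 * h * j + pi))
  constants$b * m * d * s / sqrt(s)
}

#' Stomatal opening ratio
#'
#' Ratio of the fitted operational maximum conductance to the anatomical
#' maximum, \eqn{g_{max}/g_{max,anatomy}}: the fraction of the theoretical
#' diffusive capacity realized by open stomata (typically < 1).
#'
#' @param gmax_fitted Fitted g_max.
#' @param gmax_anat Anatomical g_max.
#' @param units_fitted,units_anat Units of each input (`"mmol"` or `"mol"`
#'   m^-2 s^-1); conversion is explicit because the two quantities customarily
#'   arrive on different scales.
#' @return Dimensionless ratio.
#' @examples
#' gmax_ratio(400, 1.43, units_fitted = "mmol", units_anat = "mol")  # ~0.28
#' @export
gmax_ratio <- function(gmax_fitted, gmax_anat,
                       units_fitted = c("mmol", "mol"),
                       units_anat = c("mol", "mmol")) {
  units_fitted <- match.arg(units_fitted)
  units_anat <- match.arg(units_anat)
  if (any(gmax_fitted <= 0)) stop("fitted gmax must be > 0", call. = FALSE)
  if (any(gmax_anat <= 0)) stop("anatomical gmax must be > 0", call. = FALSE)
  f <- if (units_fitted == "mmol") gmax_fitted / 1000 else gmax_fitted
  a <- if (units_anat == "mmol") gmax_anat / 1000 else gmax_anat
  f / a
}

#' Anatomy table computation
#'
#' Applies [gmax_anatomy()] row-wise to a species anatomy table and, when a
#' fitted-gmax column is supplied, adds the opening ratio.
#'
#' @param anatomy data.frame with columns `species_id`, `d`, `s`, `W`, `L`,
#'   `p` and optionally `h`.
#' @param fits Optional data.frame with `species_id` and `gmax` (mmol m^-2
#'   s^-1) from the curve-fitting stage.
#' @param units Units of the anatomy columns, see [gmax_anatomy()].
#' @return The anatomy table with `gmax_anatomy` (mol m^-2 s^-1) and, if
#'   `fits` given, `gmax_ratio` columns added.
#' @export
anatomy_table <- function(anatomy, fits = NULL, units = c("field", "SI")) {
  units <- match.arg(units)
  need <- c("species_id", "d", "s", "W", "L", "p")
  if (!all(need %in% names(anatomy))) {
    stop("anatomy table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  h <- if ("h" %in% names(anatomy)) anatomy$h else 0.5
  anatomy$gmax_anatomy <- gmax_anatomy(anatomy$d, anatomy$s, anatomy$W,
                                       anatomy$L, anatomy$p, h = h,
                                       units = units)
  if (!is.null(fits)) {
    idx <- match(anatomy$species_id, fits$species_id)
    ratio <- rep(NA_real_, nrow(anatomy))
    ok <- !is.na(idx) & !is.na(fits$gmax[pmax(idx, 1L)])
    if (any(ok)) {
      ratio[ok] <- gmax_ratio(fits$gmax[idx[ok]], anatomy$gmax_anatomy[ok],
                              units_fitted = "mmol", units_anat = "mol")
    }
    anatomy$gmax_ratio <- ratio
  }
  anatomy
}
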