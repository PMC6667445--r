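#' Per-species stomatal response dataset
#'
#' Bundles the paired (\eqn{\Psi_{leaf}}, \eqn{g_s}) measurements of one
#' species with its mean minimum epidermal conductance \eqn{g_{min}}, the
#' fitting substrate for [fit_response()].
#'
#' @param species_id Species label.
#' @param psi_leaf Numeric vector of leaf water potentials, MPa. Must be
#'   finite and non-positive unless `psi_as_magnitude = TRUE`, in which case
#'   positive magnitudes are negated on construction.
#' @param gs Numeric vector of stomatal conductances, mmol m-2 s-1 (>= 0).
#' @param gmin Minimum epidermal conductance, mmol m-2 s-1 (>= 0). May be `NA`
#'   when `subtract_gmin = FALSE` (the literature-compilation path).
#' @param subtract_gmin Should `gmin` be subtracted before fitting?
#' @param artifact_label Optional character vector labelling each point
#'   (`"clean"`, `"squeeze"`, `"reopen"`); used by the synthetic generator to
#'   validate the refinement filters.
#' @param psi_as_magnitude Set `TRUE` if `psi_leaf` holds positive magnitudes.
#' @return An object of class `species_response`, a list with a `points`
#'   data.frame (`psi_leaf`, `gs_raw`, `gs_adj`, `artifact_label`), `gmin`,
#'   and flags.
#' @export
species_response <- function(species_id, psi_leaf, gs, gmin = NA_real_,
                             subtract_gmin = TRUE, artifact_label = NULL,
                             psi_as_magnitude = FALSE) {
  psi_leaf <- as.numeric(psi_leaf)
  gs <- as.numeric(gs)
  stopifnot(length(psi_leaf) == length(gs))
  if (psi_as_magnitude) psi_leaf <- -abs(psi_leaf)
  if (any(!is.finite(psi_leaf)) || any(psi_leaf > 0)) {
    stop("psi_leaf must be finite and <= 0 (or set psi_as_magnitude = TRUE)",
         call. = FALSE)
  }
  if (any(!is.finite(gs)) || any(gs < 0)) {
    stop("gs must be finite and >= 0", call. = FALSE)
  }
  if (!is.na(gmin) && gmin < 0) stop("gmin must be >= 0", call. = FALSE)
  if (is.null(artifact_label)) artifact_label <- rep("clean", length(gs))
  x <- structure(
    list(
      species_id = as.character(species_id),
      points = data.frame(psi_leaf = psi_leaf, gs_raw = gs, gs_adj = NA_real_,
                          artifact_label = artifact_label,
                          stringsAsFactors = FALSE),
      gmin = gmin,
      subtract_gmin = isTRUE(subtract_gmin),
      gmin_subtracted = FALSE
    ),
    class = "species_response"
  )
  subtract_gmin(x)
}

#' Subtract the minimum epidermal conductance
#'
#' Populates `gs_adj = gs_raw - gmin` when the dataset's `subtract_gmin` flag
#' is set, the identity `gs_adj = gs_raw` otherwise (the literature path fits
#' raw conductances). Negative adjusted values are kept: clamping would bias
#' the Gaussian error model.
#'
#' @param dataset A `species_response`.
#' @return The dataset with `gs_adj` filled in.
#' @export
subtract_gmin <- function(dataset) {
  stopifnot(inherits(dataset, "species_response"))
  if (dataset$subtract_gmin) {
    if (is.na(dataset$gmin)) {
      stop("subtract_gmin = TRUE but gmin is missing for species '",
           dataset$species_id, "'", call. = FALSE)
    }
    dataset$points$gs_adj <- dataset$points$gs_raw - dataset$gmin
  } else {
    dataset$points$gs_adj <- dataset$points$gs_raw
  }
  dataset$gmin_subtracted <- TRUE
  dataset
}

#' Refinement filters for artifact points
#'
#' Removes the two artifact classes seen in shoot-dehydration experiments:
#' \describe{
#'   \item{squeeze points}{well-hydrated leaves with closed stomata, caused by
#'     the mechanical advantage of epidermal cells in turgid leaves:
#'     `gs_adj < squeeze_gs` at `psi_leaf > squeeze_psi`;}
#'   \item{re-opening points}{stomata open in strongly dehydrated leaves that
#'     have lost stomatal control: `gs_adj > reopen_gs` at
#'     `psi_leaf < reopen_psi`.}
#' }
#' Thresholds default to 50 mmol m-2 s-1 and -0.5 / -2.0 MPa. Applying the
#' filter twice equals applying it once (idempotent).
#'
#' @param dataset A `species_response` with `gs_adj` populated.
#' @param squeeze_gs,squeeze_psi Squeeze rule thresholds.
#' @param reopen_gs,reopen_psi Re-opening rule thresholds.
#' @return A list with `dataset` (filtered) and `report`, a one-row data.frame
#'   (`n_total`, `n_squeeze`, `n_reopen`, `fraction_excluded`) plus the
#'   excluded point indices as an attribute `excluded_ids`.
#' @export
refine_dataset <- function(dataset, squeeze_gs = 50, squeeze_psi = -0.5,
                           reopen_gs = 50, reopen_psi = -2.0) {
  stopifnot(inherits(dataset, "species_response"), dataset$gmin_subtracted)
  pts <- dataset$points
  squeeze <- pts$gs_adj < squeeze_gs & pts$psi_leaf > squeeze_psi
  reopen <- pts$gs_adj > reopen_gs & pts$psi_leaf < reopen_psi
  drop <- squeeze | reopen
  report <- data.frame(
    n_total = nrow(pts),
    n_squeeze = sum(squeeze),
    n_reopen = sum(reopen & !squeeze),
    fraction_excluded = sum(drop) / max(1L, nrow(pts))
  )
  attr(report, "excluded_ids") <- which(drop)
  dataset$points <- pts[!drop, , drop = FALSE]
  rownames(dataset$points) <- NULL
  list(dataset = dataset, report = report)
}

#' @export
print.species_response <- function(x, ...) {
  cat("<species_response>", x$species_id, "-", nrow(x$points), "points; gmin =",
      x$gmin, if (x$subtract_gmin) "(subtracted)" else "(not subtracted)", "\n")
  invisible(x)
}
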