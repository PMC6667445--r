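#' Write a synthetic bundle to plain-text files
#'
#' Emits the round-trippable file set: `points.csv` (species, psi_leaf_MPa,
#' gs_mmol_m2_s, artifact_label), `gmin.csv`, `traits.csv`, `anatomy.csv`,
#' `truth.csv`, `tree.nwk`, and `config.json`.
#'
#' @param bundle A `synth_bundle` from [generate_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synth_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pts <- do.call(rbind, lapply(bundle$response_datasets, function(d) {
    data.frame(species = d$species_id,
               psi_leaf_MPa = d$points$psi_leaf,
               gs_mmol_m2_s = d$points$gs_raw,
               artifact_label = d$points$artifact_label,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(pts, file.path(dir, "points.csv"), row.names = FALSE)
  gmin <- data.frame(species = bundle$truth$species_id,
                     gmin_mmol_m2_s = bundle$truth$gmin)
  utils::write.csv(gmin, file.path(dir, "gmin.csv"), row.names = FALSE)
  utils::write.csv(bundle$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$anatomy, file.path(dir, "anatomy.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  cfg <- bundle$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a bundle back from disk
#'
#' Inverse of [write_bundle()]: reconstructs the response datasets (with
#' artifact labels), trait and anatomy tables, tree and config.
#'
#' @param dir Directory written by [write_bundle()].
#' @return A `synth_bundle` (without the `truth` element if `truth.csv` is
#'   absent).
#' @export
read_bundle <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  config <- do.call(synth_config, cfg[setdiff(names(cfg), character(0))])
  pts <- utils::read.csv(file.path(dir, "points.csv"),
                         stringsAsFactors = FALSE)
  gmin <- utils::read.csv(file.path(dir, "gmin.csv"),
                          stringsAsFactors = FALSE)
  datasets <- lapply(split(pts, pts$species), function(p) {
    gm <- gmin$gmin_mmol_m2_s[match(p$species[1], gmin$species)]
    species_response(p$species[1], p$psi_leaf_MPa, p$gs_mmol_m2_s, gmin = gm,
                     subtract_gmin = TRUE,
                     artifact_label = p$artifact_label)
  })
  truth_path <- file.path(dir, "truth.csv")
  structure(
    list(config = config,
         tree = ape::read.tree(file.path(dir, "tree.nwk")),
         truth = if (file.exists(truth_path)) {
           utils::read.csv(truth_path, stringsAsFactors = FALSE)
         },
         response_datasets = datasets[order(names(datasets))],
         anatomy = utils::read.csv(file.path(dir, "anatomy.csv"),
                                   stringsAsFactors = FALSE),
         traits = utils::read.csv(file.path(dir, "traits.csv"),
                                  stringsAsFactors = FALSE)),
    class = "synth_bundle")
}

#' Read user response-point tables
#'
#' Reads a delimited points file (columns `species`, `psi_leaf_MPa`,
#' `gs_mmol_m2_s`, optional `artifact_label`) and an optional g_min file
#' (`species`, `gmin_mmol_m2_s`) into a list of `species_response` objects.
#'
#' @param points_path Path to the points file.
#' @param gmin_path Optional path to the g_min file; when `NULL` the
#'   literature path is assumed (`subtract_gmin = FALSE`).
#' @param psi_as_magnitude Declare positive psi magnitudes (negated on read).
#' @return Named list of `species_response`.
#' @export
read_response_points <- function(points_path, gmin_path = NULL,
                                 psi_as_magnitude = FALSE) {
  pts <- utils::read.csv(points_path, stringsAsFactors = FALSE)
  need <- c("species", "psi_leaf_MPa", "gs_mmol_m2_s")
  if (!all(need %in% names(pts))) {
    stop("points file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(pts) == 0) stop("points file is empty", call. = FALSE)
  gmin <- if (!is.null(gmin_path)) {
    utils::read.csv(gmin_path, stringsAsFactors = FALSE)
  }
  datasets <- lapply(split(pts, pts$species), function(p) {
    gm <- if (is.null(gmin)) NA_real_ else {
      gmin$gmin_mmol_m2_s[match(p$species[1], gmin$species)]
    }
    species_response(
      p$species[1], p$psi_leaf_MPa, p$gs_mmol_m2_s, gmin = gm,
      subtract_gmin = !is.null(gmin),
      artifact_label = if ("artifact_label" %in% names(p)) p$artifact_label,
      psi_as_magnitude = psi_as_magnitude)
  })
  datasets[order(names(datasets))]
}
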