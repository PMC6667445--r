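#' Fit every species in a collection
#'
#' Runs the per-species path ([fit_response()]) over a list of datasets,
#' collecting fits, refinement reports and failures.
#'
#' @param datasets Named list of `species_response`.
#' @param mode `"refined"` or `"all"`.
#' @param reference_psi Reference potential for g_max.
#' @param ... Passed to [fit_response()].
#' @return List: `fits_table` (one row per fitted species), `refinement`
#'   (per-species report), `failures` (named character of error messages),
#'   `fits` (the fitted objects).
#' @export
fit_all_species <- function(datasets, mode = "refined", reference_psi = 0,
                            ...) {
  fits <- list(); reports <- list(); failures <- character(0)
  for (nm in names(datasets)) {
    res <- tryCatch(
      fit_response(datasets[[nm]], mode = mode,
                   reference_psi = reference_psi, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[nm] <- conditionMessage(res)
      next
    }
    fits[[nm]] <- res
    if (!is.null(res$report)) {
      reports[[nm]] <- cbind(species_id = nm, res$report)
    }
  }
  fits_table <- do.call(rbind, lapply(fits, function(r) {
    f <- r$fit
    data.frame(species_id = f$species_id, family = f$family_name, n = f$n,
               aicc = f$aicc, gmax = f$gmax, psi_gs20 = f$psi_gs20,
               psi_gs50 = f$psi_gs50, psi_gs80 = f$psi_gs80,
               p_value = f$fit_pvalue, sigma_hat = f$sigma_hat,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(fits_table)) rownames(fits_table) <- NULL
  refinement <- if (length(reports)) {
    out <- do.call(rbind, reports)
    rownames(out) <- NULL
    out
  }
  list(fits_table = fits_table, refinement = refinement, failures = failures,
       fits = fits)
}

#' Cross-species summary of fitted parameters
#'
#' @param fits_table From [fit_all_species()].
#' @param refinement Optional refinement table (adds the mean excluded
#'   fraction).
#' @return One-row data.frame: spans (max - min) of `psi_gs20/50/80`, the
#'   g_max fold range (max/min), species count, and `mean_fraction_excluded`.
#' @export
summarize_fits <- function(fits_table, refinement = NULL) {
  data.frame(
    n_species = nrow(fits_table),
    psi_gs20_span = diff(range(fits_table$psi_gs20, na.rm = TRUE)),
    psi_gs50_span = diff(range(fits_table$psi_gs50, na.rm = TRUE)),
    psi_gs80_span = diff(range(fits_table$psi_gs80, na.rm = TRUE)),
    gmax_fold_range = max(fits_table$gmax, na.rm = TRUE) /
      min(fits_table$gmax, na.rm = TRUE),
    mean_fraction_excluded = if (!is.null(refinement)) {
      mean(refinement$fraction_excluded)
    } else NA_real_)
}

#' Trait-pair correlation battery
#'
#' For each requested trait pair runs the ahistorical analyses (Pearson on
#' raw and log scales, SMA on the stronger scale) and the evolutionary
#' analysis (PGLS with AIC model selection), pruning the tree to
#' complete-case species per pair.
#'
#' @param traits data.frame with `species_id` and trait columns.
#' @param tree `ape::phylo` whose tips cover the species.
#' @param pairs List of `c(x, y)` character pairs of column names.
#' @return Long data.frame: one row per pair x method.
#' @export
correlation_battery <- function(traits, tree, pairs) {
  rows <- list()
  for (pr in pairs) {
    x <- stats::setNames(traits[[pr[1]]], traits$species_id)
    y <- stats::setNames(traits[[pr[2]]], traits$species_id)
    cc <- sum(stats::complete.cases(x, y))
    if (cc < 3) next
    pe <- pearson_both_scales(x, y)
    for (i in seq_len(nrow(pe))) {
      rows[[length(rows) + 1]] <- data.frame(
        x = pr[1], y = pr[2], method = paste0("pearson-", pe$scale[i]),
        r = pe$r[i], p = pe$p[i], n = pe$n[i], slope = NA_real_,
        model_par = NA_real_, selected = pe$selected[i],
        stringsAsFactors = FALSE)
    }
    scale_sel <- pe$scale[pe$selected][1]
    sm <- tryCatch(sma_fit(x, y, scale = scale_sel), error = function(e) NULL)
    if (!is.null(sm)) {
      rows[[length(rows) + 1]] <- data.frame(
        x = pr[1], y = pr[2], method = paste0("sma-", sm$scale), r = sm$r,
        p = NA_real_, n = sm$n, slope = sm$slope, model_par = NA_real_,
        selected = NA, stringsAsFactors = FALSE)
    }
    pg <- tryCatch(pgls_model_select(x, y, tree), error = function(e) NULL)
    if (!is.null(pg)) {
      rows[[length(rows) + 1]] <- data.frame(
        x = pr[1], y = pr[2], method = pg$method, r = pg$r, p = pg$p,
        n = pg$n, slope = pg$slope, model_par = pg$lambda_or_alpha,
        selected = NA, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.default_pairs <- list(
  c("gmax", "psi_gs50"), c("s", "gmax"), c("s", "psi_gs50"),
  c("pi_o", "gmax"), c("pi_o", "psi_gs50"),
  c("LMA", "gmax"), c("LMA", "psi_gs50"))

#' Run the full experimental analysis pipeline
#'
#' Orchestrates the dehydration-experiment analysis end to end: g_min
#' subtraction, optional refinement, four-family fitting with AICc
#' selection, derived g_max and closure thresholds, anatomical conductance
#' merge, cross-species summaries, and the trait-correlation battery
#' (Pearson, SMA, PGLS). When `outdir` is given, all tables are written as
#' CSV together with a JSON run manifest echoing the resolved configuration.
#'
#' @param bundle A `synth_bundle` (or object with the same elements built
#'   from user data).
#' @param mode `"refined"` or `"all"`.
#' @param reference_psi 0 (default) or -0.1 for the sensitivity re-analysis.
#' @param pairs Trait pairs for [correlation_battery()]; defaults to the
#'   trade-off and mechanism pairs.
#' @param outdir Optional output directory.
#' @return List: `fits_table`, `refinement`, `summary`, `anatomy`,
#'   `correlations`, `failures`, `manifest`.
#' @export
run_experiment_pipeline <- function(bundle, mode = "refined",
                                    reference_psi = 0, pairs = NULL,
                                    outdir = NULL) {
  stopifnot(!is.null(bundle$response_datasets), !is.null(bundle$tree))
  if (is.null(pairs)) pairs <- .default_pairs
  fitres <- fit_all_species(bundle$response_datasets, mode = mode,
                            reference_psi = reference_psi)
  if (is.null(fitres$fits_table)) {
    stop("no species could be fitted", call. = FALSE)
  }
  anat <- if (!is.null(bundle$anatomy)) {
    anatomy_table(bundle$anatomy, fits = fitres$fits_table)
  }
  traits <- merge(fitres$fits_table[, c("species_id", "gmax", "psi_gs20",
                                        "psi_gs50", "psi_gs80")],
                  bundle$traits, by = "species_id", all = TRUE)
  if (!is.null(anat)) {
    traits <- merge(traits,
                    anat[, c("species_id", "gmax_anatomy",
                             intersect("gmax_ratio", names(anat)))],
                    by = "species_id", all = TRUE)
  }
  corr <- correlation_battery(traits, bundle$tree, pairs)
  summ <- summarize_fits(fitres$fits_table, fitres$refinement)
  manifest <- list(
    mode = mode, reference_psi = reference_psi,
    n_species_fit = nrow(fitres$fits_table),
    failures = as.list(fitres$failures),
    config = if (!is.null(bundle$config)) unclass(bundle$config),
    timestamp = NULL)  # timestamps omitted: outputs must be reproducible
  out <- list(fits_table = fitres$fits_table, refinement = fitres$refinement,
              summary = summ, anatomy = anat, correlations = corr,
              traits = traits, failures = fitres$failures,
              manifest = manifest)
  if (!is.null(outdir)) .write_run(out, outdir)
  out
}

#' Run the literature-compilation pipeline
#'
#' Per-study curve fitting without g_min subtraction, per-study SMA lines for
#' log g_max versus log |Psi_gs50|, and the cross-study common-slope test for
#' studies with at least `min_species_slope` species.
#'
#' @param studies Named list; each element a named list of
#'   `species_response` objects (built with `subtract_gmin = FALSE`), or a
#'   data.frame with `species`, `psi_leaf_MPa`, `gs_mmol_m2_s` columns.
#' @param mode,reference_psi As in [run_experiment_pipeline()].
#' @param min_species_slope Minimum species per study for the slope test.
#' @param outdir Optional output directory.
#' @return List: `fits_by_study`, `sma_by_study`, `heterogeneity` (or `NULL`
#'   when fewer than two studies qualify), `skipped`.
#' @export
run_literature_pipeline <- function(studies, mode = "all", reference_psi = 0,
                                    min_species_slope = 6, outdir = NULL) {
  fits_by_study <- list(); sma_by_study <- list(); skipped <- character(0)
  groups <- list()
  for (nm in names(studies)) {
    st <- studies[[nm]]
    if (is.data.frame(st)) {
      st <- lapply(split(st, st$species), function(p) {
        species_response(p$species[1], p$psi_leaf_MPa, p$gs_mmol_m2_s,
                         subtract_gmin = FALSE)
      })
    }
    if (length(st) < 2) {
      warning("study '", nm, "' skipped: fewer than 2 entities")
      skipped <- c(skipped, nm)
      next
    }
    fr <- fit_all_species(st, mode = mode, reference_psi = reference_psi)
    fits_by_study[[nm]] <- fr$fits_table
    tb <- fr$fits_table
    if (!is.null(tb) && nrow(tb) >= 3) {
      sma_by_study[[nm]] <- sma_fit(tb$gmax, tb$psi_gs50, scale = "log",
                                    group = nm)
    }
    if (!is.null(tb) && nrow(tb) >= min_species_slope) {
      groups[[nm]] <- list(x = log(tb$gmax), y = log(-tb$psi_gs50))
    }
  }
  het <- if (length(groups) >= 2) sma_heterogeneity_test(groups)
  out <- list(fits_by_study = fits_by_study, sma_by_study = sma_by_study,
              heterogeneity = het, skipped = skipped)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    all_fits <- do.call(rbind, lapply(names(fits_by_study), function(nm) {
      cbind(study = nm, fits_by_study[[nm]])
    }))
    utils::write.csv(all_fits, file.path(outdir, "literature_fits.csv"),
                     row.names = FALSE)
  }
  out
}

.write_run <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) {
    if (!is.null(x)) utils::write.csv(x, file.path(outdir, f),
                                      row.names = FALSE)
  }
  wr(out$fits_table, "fits.csv")
  wr(out$refinement, "refinement.csv")
  wr(out$summary, "summary.csv")
  wr(out$anatomy, "anatomy.csv")
  wr(out$correlations, "correlations.csv")
  wr(out$traits, "traits_merged.csv")
  jsonlite::write_json(out$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}
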