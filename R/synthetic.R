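#' Configuration of the synthetic world
#'
#' Defaults describe a dehydration experiment on woody species: 15 species,
#' 40 points per species, additive Gaussian conductance noise of 10
#' mmol m^-2 s^-1, 4 percent squeeze plus 4 percent re-opening artifacts
#' (8 percent on average excluded, matching typical refined fractions),
#' g_max between 150 and 450 mmol m^-2 s^-1, Psi_gs50 between -1.2 and -0.4
#' MPa (sensitive closure, so that bulk closure precedes the -2 MPa
#' re-opening filter threshold the refinement stage assumes), g_min between
#' 2 and 15 mmol m^-2 s^-1, and an evolutionary correlation of 0.7 between
#' log g_max and Psi_gs50 (the built-in safety-efficiency trade-off).
#'
#' @param n_species,points_per_species Counts.
#' @param true_family One of [family_names()] or `"mixed"`.
#' @param noise_sd Conductance noise SD, mmol m^-2 s^-1 (>= 0).
#' @param squeeze_rate,reopen_rate Artifact fractions in [0, 0.3].
#' @param gmin_range,gmax_range Positive conductance intervals.
#' @param psi_gs50_range Strictly negative MPa interval.
#' @param tradeoff_correlation Target correlation between log g_max and
#'   Psi_gs50, in [-1, 1].
#' @param seed Integer seed; every generator is a pure function of
#'   (inputs, seed).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_species = 15, points_per_species = 40,
                         true_family = "mixed", noise_sd = 10,
                         squeeze_rate = 0.04, reopen_rate = 0.04,
                         gmin_range = c(2, 15), gmax_range = c(150, 450),
                         psi_gs50_range = c(-1.2, -0.4),
                         tradeoff_correlation = 0.7, seed = 1L) {
  stopifnot(n_species >= 2, points_per_species >= 6, noise_sd >= 0,
            squeeze_rate >= 0, squeeze_rate <= 0.3,
            reopen_rate >= 0, reopen_rate <= 0.3,
            all(gmin_range >= 0), all(gmax_range > 0),
            all(psi_gs50_range < 0),
            abs(tradeoff_correlation) <= 1)
  if (!identical(true_family, "mixed")) {
    true_family <- match.arg(true_family, family_names())
  }
  structure(as.list(environment()), class = "synth_config")
}

# Stable 31-bit hash of a species id, used to sub-stream the RNG so that
# adding a species never perturbs the draws of the others.
.stable_hash <- function(id) {
  h <- 0
  for (b in utf8ToInt(id)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a random ultrametric phylogeny
#'
#' Pure-birth (Yule) tree with `n_species` uniquely labelled tips
#' (`sp01`, `sp02`, ...), scaled to unit height. Stands in for a pruned
#' community phylogeny.
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Integer seed.
#' @return An `ape::phylo`, ultrametric and binary.
#' @export
generate_phylogeny <- function(n_species, seed = 1L) {
  if (n_species < 2) stop("n_species must be >= 2", call. = FALSE)
  .with_seed(seed, {
    tree <- ape::rphylo(n_species, birth = 1, death = 0)
    tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
    tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
    tree
  })
}

#' Evolve species traits on the tree
#'
#' Simulates correlated bivariate Brownian evolution of (log g_max,
#' Psi_gs50) with evolutionary correlation `tradeoff_correlation`, maps the
#' standardized tip states into the configured ranges (affine maps preserve
#' the correlation), and adds auxiliary traits with the expected sign
#' structure: stomatal size `s` (um^2) decreasing with g_max, osmotic
#' potentials `pi_o >= pi_tlp` (both negative, tracking Psi_gs50), and `LMA`
#' (g m^-2) decreasing with g_max. True response-family assignments and
#' parameters are included so downstream recovery can be validated.
#'
#' @param tree An `ape::phylo` from [generate_phylogeny()].
#' @param config A [synth_config()].
#' @return data.frame (one row per tip): `species_id`, `gmax`, `psi_gs50`,
#'   `family`, curve parameters `par_a`, `par_b`, `par_x0`, `par_g0`,
#'   `psi_gs80`, `gmin`, `s`, `pi_o`, `pi_tlp`, `LMA`.
#' @export
generate_traits <- function(tree, config = synth_config()) {
  stopifnot(inherits(tree, "phylo"))
  if (any(!is.finite(tree$edge.length))) {
    stop("tree has non-finite branch lengths", call. = FALSE)
  }
  n <- ape::Ntip(tree)
  rho <- config$tradeoff_correlation
  .with_seed(config$seed + 1L, {
    V <- ape::vcv(tree)
    # matrix-normal BM: rows correlated by the tree, columns by rho
    Lv <- chol(V + diag(1e-12, n))
    R <- matrix(c(1, rho, rho, 1), 2)
    Z <- matrix(stats::rnorm(2 * n), n, 2) %*% chol(R)
    tips <- t(Lv) %*% Z
    scale_to <- function(z, range) {
      zs <- z / sqrt(max(diag(V)))  # standardize by expected BM variance
      mean(range) + diff(range) / 4 * zs
    }
    log_gmax <- scale_to(tips[, 1], log(config$gmax_range))
    psi50 <- pmin(scale_to(tips[, 2], config$psi_gs50_range), -0.05)
    gmax <- exp(log_gmax)
    fams <- if (identical(config$true_family, "mixed")) {
      sample(family_names(), n, replace = TRUE)
    } else rep(config$true_family, n)
    out <- data.frame(
      species_id = rownames(V), gmax = gmax, psi_gs50 = psi50,
      family = fams, stringsAsFactors = FALSE)
    pars <- t(mapply(.true_curve_params, fams, gmax, psi50))
    out$par_a <- pars[, "a"]; out$par_b <- pars[, "b"]
    out$par_x0 <- pars[, "x0"]; out$par_g0 <- pars[, "g0"]
    out$psi_gs80 <- vapply(seq_len(n), function(i) {
      .true_psi_gsX(out[i, ], 80)
    }, numeric(1))
    out$gmin <- stats::runif(n, config$gmin_range[1], config$gmin_range[2])
    out$s <- exp(5.8 - 0.7 * (log_gmax - mean(log(config$gmax_range))) +
                   stats::rnorm(n, 0, 0.25))
    out$pi_o <- pmin(1.3 * psi50 - 0.3 + stats::rnorm(n, 0, 0.15), -0.3)
    out$pi_tlp <- out$pi_o - abs(stats::rnorm(n, 0.45, 0.1))
    out$LMA <- exp(5.0 - 0.5 * (log_gmax - mean(log(config$gmax_range))) +
                     stats::rnorm(n, 0, 0.2))
    rownames(out) <- NULL
    out
  })
}

# True curve parameters for a species with given family, gmax = curve(0) and
# psi_gs50 = half-decline potential (both exact by construction).
.true_curve_params <- function(family, gmax, psi50) {
  switch(family,
    linear = c(a = -gmax / (2 * psi50), b = NA_real_, x0 = NA_real_,
               g0 = gmax),
    exponential = c(a = gmax, b = log(2) / psi50, x0 = NA_real_, g0 = 0),
    sigmoidal = .calibrate_sigmoid(gmax, psi50),
    logistic = c(a = gmax, b = 4, x0 = psi50, g0 = NA_real_))
}

# Sigmoid with gs(0) = gmax and gs(psi50) = gmax/2 exactly:
# gs = a / (1 + e^{-(psi - x0)/b}). Two anchors, free b = |psi50|/5.
# gs(psi50)/gs(0) = (1 + e^{x0/b}) / (1 + e^{-(psi50 - x0)/b}) = 1/2.
# Solve for x0 by 1-D root finding.
.calibrate_sigmoid <- function(gmax, psi50) {
  b <- abs(psi50) / 5
  f <- function(x0) {
    (1 + exp(x0 / b)) / (1 + exp(-(psi50 - x0) / b)) - 0.5
  }
  x0 <- stats::uniroot(f, c(psi50 * 3, -1e-9), tol = 1e-12)$root
  a <- gmax * (1 + exp(x0 / b))
  c(a = a, b = b, x0 = x0, g0 = NA_real_)
}

# True psi at X percent decline from gmax (analytic where possible).
.true_psi_gsX <- function(row, X) {
  frac <- 1 - X / 100
  fam <- row$family
  if (fam == "linear") return(-row$gmax * (X / 100) / row$par_a)
  if (fam == "exponential") return(-row$psi_gs50 * log(frac) / log(2))
  if (fam == "logistic") {
    return(row$par_x0 * ((row$par_a / (frac * row$gmax) - 1))^(1 / row$par_b))
  }
  # sigmoidal: invert a/(1+e^{-(psi-x0)/b}) = frac * gmax
  arg <- row$par_a / (frac * row$gmax) - 1
  row$par_x0 - row$par_b * log(arg)
}

# Evaluate a truth-table row's curve at psi (vectorized over psi).
.true_curve <- function(row, psi) {
  pars <- switch(row$family,
    linear = c(a = row$par_a, g0 = row$par_g0),
    exponential = c(g0 = row$par_g0, a = row$par_a, b = row$par_b),
    sigmoidal = c(a = row$par_a, b = row$par_b, x0 = row$par_x0),
    logistic = c(a = row$par_a, b = row$par_b, x0 = row$par_x0))
  evaluate_family(row$family, psi, pars)
}

#' Generate one species' response dataset from its true curve
#'
#' Samples water potentials stratified-uniformly over
#' \eqn{[1.5\,\Psi_{gs80,true},\ 0]} (one uniform draw per equal-width
#' stratum, so every curve region is represented), evaluates the true curve,
#' adds g_min and Gaussian noise (floored at zero), then replaces a
#' binomially chosen subset of points with artifacts: squeeze points
#' (\eqn{\Psi > -0.5} MPa, adjusted g_s uniform in [0, 40]) and re-opening
#' points (beyond both the species' deep-closure potential and -2 MPa,
#' adjusted g_s uniform in [60, 150] -- magnitudes chosen to straddle the 50
#' mmol m^-2 s^-1 filter threshold). Artifact provenance labels are kept.
#'
#' @param truth One row of the [generate_traits()] table.
#' @param config A [synth_config()].
#' @return A `species_response` with `artifact_label` set.
#' @export
generate_response_dataset <- function(truth, config = synth_config()) {
  stopifnot(nrow(truth) == 1)
  if (config$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  n <- config$points_per_species
  sub_seed <- (config$seed + .stable_hash(truth$species_id)) %% 2147483647
  .with_seed(as.integer(sub_seed), {
    lo <- 1.5 * truth$psi_gs80
    breaks <- seq(lo, 0, length.out = n + 1)
    psi <- stats::runif(n, breaks[-(n + 1)], breaks[-1])
    gs <- .true_curve(truth, psi) + truth$gmin +
      stats::rnorm(n, 0, config$noise_sd)
    gs <- pmax(gs, 0)
    label <- rep("clean", n)
    n_squeeze <- stats::rbinom(1, n, config$squeeze_rate)
    n_reopen <- stats::rbinom(1, n, config$reopen_rate)
    idx <- sample.int(n, min(n, n_squeeze + n_reopen))
    sq <- idx[seq_len(min(n_squeeze, length(idx)))]
    ro <- setdiff(idx, sq)
    if (length(sq)) {
      psi[sq] <- stats::runif(length(sq), -0.45, -0.05)
      gs[sq] <- truth$gmin + stats::runif(length(sq), 0, 40)
      label[sq] <- "squeeze"
    }
    if (length(ro)) {
      deep <- min(1.5 * truth$psi_gs80, -2) - 0.1
      psi[ro] <- stats::runif(length(ro), deep - 0.8, deep)
      gs[ro] <- truth$gmin + stats::runif(length(ro), 60, 150)
      label[ro] <- "reopen"
    }
    species_response(truth$species_id, psi, gs, gmin = truth$gmin,
                     subtract_gmin = TRUE, artifact_label = label)
  })
}

#' Generate a stomatal anatomy table
#'
#' Emulates the size-density packing trade-off: density `d` (mm^-2) declines
#' with stomatal size `s` (um^2); guard cell length `L`, width `W` and pore
#' length `p` (um) are derived from `s` with jittered shape ratios kept
#' inside (0, 1), so `p < L` and `W < L` always hold.
#'
#' @param truth_table Output of [generate_traits()] (uses `species_id`, `s`).
#' @param seed Integer seed.
#' @return data.frame: `species_id`, `d` (mm^-2), `s` (um^2), `W`, `L`, `p`
#'   (um), `h`.
#' @export
generate_anatomy <- function(truth_table, seed = 1L) {
  stopifnot(nrow(truth_table) >= 1)
  .with_seed(seed + 2L, {
    n <- nrow(truth_table)
    s <- truth_table$s
    d <- exp(9.8 - 0.85 * log(s) + stats::rnorm(n, 0, 0.15))
    L <- 2 * sqrt(s) * exp(stats::rnorm(n, 0, 0.05))
    W <- L * stats::runif(n, 0.35, 0.55)
    p <- L * stats::runif(n, 0.4, 0.6)
    data.frame(species_id = truth_table$species_id, d = d, s = s, W = W,
               L = L, p = p, h = 0.5, stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic bundle
#'
#' Tree, trait truth table, per-species response datasets, anatomy table, and
#' the analysis-facing trait table, all from one seed. Species labels are
#' consistent across every component.
#'
#' @param config A [synth_config()].
#' @return A `synth_bundle` list: `config`, `tree`, `truth`,
#'   `response_datasets` (named list of `species_response`), `anatomy`,
#'   `traits` (analysis trait table: `species_id`, `s`, `pi_o`, `pi_tlp`,
#'   `LMA` -- measured-trait stand-ins without the fitted quantities).
#' @export
generate_bundle <- function(config = synth_config()) {
  tree <- generate_phylogeny(config$n_species, seed = config$seed)
  truth <- generate_traits(tree, config)
  datasets <- lapply(seq_len(nrow(truth)), function(i) {
    generate_response_dataset(truth[i, , drop = FALSE], config)
  })
  names(datasets) <- truth$species_id
  anatomy <- generate_anatomy(truth, seed = config$seed)
  traits <- truth[, c("species_id", "s", "pi_o", "pi_tlp", "LMA")]
  structure(
    list(config = config, tree = tree, truth = truth,
         response_datasets = datasets, anatomy = anatomy, traits = traits),
    class = "synth_bundle")
}
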