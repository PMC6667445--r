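# Shared fixtures: noiseless datasets built directly from a family's curve.
make_noiseless_dataset <- function(family_name, parameters, psi,
                                   gmin = 0, species_id = "test_sp") {
  fam <- response_family(family_name, parameters)
  gs <- evaluate_family(fam, psi) + gmin
  species_response(species_id, psi, pmax(gs, 0), gmin = gmin,
                   subtract_gmin = gmin > 0)
}

# Dense psi grid over [lo, 0] for fitting fixtures.
psi_grid <- function(n = 40, lo = -3) seq(lo, 0, length.out = n)

# Independent bisection oracle for curve(psi) == target (most-hydrated root),
# deliberately separate from the package's root finder.
bisect_oracle <- function(f, lo, hi, tol = 1e-9) {
  flo <- f(lo); fhi <- f(hi)
  stopifnot(sign(flo) != sign(fhi))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) break
    if (sign(fm) == sign(fhi)) { hi <- mid; fhi <- fm } else { lo <- mid }
  }
  (lo + hi) / 2
}

# Numeric two-equation photosynthesis oracle: solve Fick + Farquhar for ci.
photosynthesis_oracle <- function(gs, params = photo_params()) {
  u <- gs / 1600
  if (u == 0) return(0)
  f <- function(ci) {
    u * (params$ca - ci) -
      (params$Vcmax * (ci - params$gamma_star) / (ci + params$Km) - params$R)
  }
  ci <- stats::uniroot(f, c(-params$Km + 1e-6, params$ca + 200),
                       tol = 1e-14)$root
  u * (params$ca - ci)
}
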