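test_that("phylogeny generator yields labelled ultrametric Yule trees", {
  tr <- generate_phylogeny(8, seed = 1)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 8)
  expect_equal(tr$Nnode, 7)  # binary rooted: n - 1 internal nodes
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_true(all(tr$edge.length > 0))
  expect_equal(anyDuplicated(tr$tip.label), 0)

  tr2 <- generate_phylogeny(2, seed = 5)
  depths <- ape::node.depth.edgelength(tr2)[1:2]
  expect_equal(depths[1], depths[2])

  expect_identical(ape::write.tree(generate_phylogeny(12, seed = 3)),
                   ape::write.tree(generate_phylogeny(12, seed = 3)))
  expect_error(generate_phylogeny(1), "n_species")
})

test_that("generators are pure functions of (inputs, seed)", {
  cfg <- synth_config(n_species = 10, seed = 99)
  b1 <- generate_bundle(cfg)
  b2 <- generate_bundle(cfg)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$anatomy, b2$anatomy)
  expect_identical(lapply(b1$response_datasets, function(d) d$points),
                   lapply(b2$response_datasets, function(d) d$points))
  # generators leave the global RNG state alone
  set.seed(1); before <- .Random.seed
  invisible(generate_bundle(cfg))
  expect_identical(.Random.seed, before)
})

test_that("adding a species does not perturb the draws of the others", {
  cfg10 <- synth_config(n_species = 10, seed = 4)
  cfg11 <- synth_config(n_species = 11, seed = 4)
  t10 <- generate_traits(generate_phylogeny(10, 4), cfg10)
  d_a <- generate_response_dataset(t10[3, ], cfg10)
  d_b <- generate_response_dataset(t10[3, ], cfg11)
  expect_identical(d_a$points, d_b$points)
})

test_that("species labels are consistent across every bundle component", {
  b <- generate_bundle(synth_config(n_species = 12, seed = 8))
  ids <- b$truth$species_id
  expect_equal(anyDuplicated(ids), 0)
  expect_setequal(ids, b$tree$tip.label)
  expect_setequal(ids, b$anatomy$species_id)
  expect_setequal(ids, b$traits$species_id)
  expect_setequal(ids, names(b$response_datasets))
})

test_that("trait evolution hits the target trade-off correlation", {
  tr <- generate_phylogeny(200, seed = 9)
  tt <- generate_traits(tr, synth_config(n_species = 200,
                                         tradeoff_correlation = 0.99,
                                         seed = 9))
  expect_gt(cor(log(tt$gmax), tt$psi_gs50), 0.9)
  # sign conventions of auxiliary traits
  expect_true(all(tt$psi_gs50 < 0))
  expect_true(all(tt$pi_o < 0))
  expect_true(all(tt$pi_tlp <= tt$pi_o))
  expect_true(all(tt$gmax > 0 & tt$s > 0 & tt$LMA > 0))
})

test_that("uncorrelated evolution yields near-zero evolutionary correlation", {
  # the raw cross-species correlation converges slowly under shared
  # phylogeny (effective n << tips), so the evolutionary correlation is the
  # sharper check; the raw value gets a loose bound
  tr <- generate_phylogeny(300, seed = 14)
  tt <- generate_traits(tr, synth_config(n_species = 300,
                                         tradeoff_correlation = 0,
                                         seed = 14))
  expect_lt(abs(cor(log(tt$gmax), tt$psi_gs50)), 0.4)
  x <- stats::setNames(log(tt$gmax), tt$species_id)
  y <- stats::setNames(tt$psi_gs50, tt$species_id)
  expect_lt(abs(pgls_fit(x, y, tr, "BM")$r), 0.25)  # > 4 sampling SDs
})

test_that("true curves honor their anchors for every family", {
  for (fam in family_names()) {
    cfg <- synth_config(n_species = 5, true_family = fam, seed = 31)
    tt <- generate_traits(generate_phylogeny(5, 31), cfg)
    for (i in seq_len(nrow(tt))) {
      row <- tt[i, ]
      expect_equal(stomsafe:::.true_curve(row, 0), row$gmax,
                   tolerance = 1e-8, info = fam)
      expect_equal(stomsafe:::.true_curve(row, row$psi_gs50), row$gmax / 2,
                   tolerance = 1e-8, info = fam)
      expect_equal(stomsafe:::.true_curve(row, row$psi_gs80), row$gmax / 5,
                   tolerance = 1e-8, info = fam)
    }
  }
})

test_that("response generator respects artifact rates and labels", {
  cfg0 <- synth_config(squeeze_rate = 0, reopen_rate = 0, seed = 2)
  tt <- generate_traits(generate_phylogeny(6, 2), cfg0)
  d <- generate_response_dataset(tt[1, ], cfg0)
  expect_true(all(d$points$artifact_label == "clean"))

  # binomial expectation: 0.08 on 50 points ~ 4 per species on average
  cfg8 <- synth_config(n_species = 40, points_per_species = 50,
                       squeeze_rate = 0.08, reopen_rate = 0, seed = 6)
  tt8 <- generate_traits(generate_phylogeny(40, 6), cfg8)
  counts <- vapply(seq_len(40), function(i) {
    sum(generate_response_dataset(tt8[i, ], cfg8)$points$artifact_label ==
          "squeeze")
  }, numeric(1))
  expect_equal(mean(counts), 4, tolerance = 0.3)

  # squeeze points sit in the hydrated/closed corner, re-opening beyond -2
  cfg <- synth_config(squeeze_rate = 0.15, reopen_rate = 0.15, seed = 13)
  ttx <- generate_traits(generate_phylogeny(10, 13), cfg)
  for (i in 1:10) {
    dd <- generate_response_dataset(ttx[i, ], cfg)
    p <- dd$points
    expect_true(all(p$psi_leaf[p$artifact_label == "squeeze"] > -0.5))
    expect_true(all(p$gs_adj[p$artifact_label == "squeeze"] < 50))
    expect_true(all(p$psi_leaf[p$artifact_label == "reopen"] < -2))
    expect_true(all(p$gs_adj[p$artifact_label == "reopen"] > 50))
  }
  expect_error(
    synth_config(noise_sd = -1), "noise_sd")
})

test_that("noiseless generation round-trips through the fitting path", {
  cfg <- synth_config(n_species = 8, points_per_species = 50, noise_sd = 0,
                      squeeze_rate = 0, reopen_rate = 0, gmin_range = c(0, 0),
                      true_family = "exponential", seed = 17)
  tt <- generate_traits(generate_phylogeny(8, 17), cfg)
  for (i in c(1, 4, 8)) {
    d <- generate_response_dataset(tt[i, ], cfg)
    f <- derive_parameters(fit_family(d, "exponential"))
    expect_equal(f$gmax, tt$gmax[i], tolerance = 1e-6)
    expect_equal(f$psi_gs50, tt$psi_gs50[i], tolerance = 1e-6)
  }
})

test_that("anatomy generator satisfies geometric and packing invariants", {
  b <- generate_bundle(synth_config(n_species = 25, seed = 5))
  a <- b$anatomy
  expect_true(all(a$d > 0 & a$s > 0 & a$W > 0 & a$L > 0 & a$p > 0))
  expect_true(all(a$p / a$L > 0 & a$p / a$L < 1))
  expect_true(all(a$W / a$L > 0 & a$W / a$L < 1))
  expect_lt(cor(a$d, a$s, method = "spearman"), 0)
  expect_identical(generate_anatomy(b$truth, seed = 5),
                   generate_anatomy(b$truth, seed = 5))
})
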