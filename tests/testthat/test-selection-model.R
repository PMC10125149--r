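test_that("degenerate RSA weights pin the first pick", {
  p <- gen_toy_protein(5, codes = rep("GLY", 5),
                       rsa = c(0, 0, 1, 0, 0), geometry = "line")
  nb <- neighbors(p)
  set.seed(1)
  firsts <- replicate(200, sample_patch(p, nb)[1])
  expect_true(all(firsts == 3))
})

test_that("patches are distinct indices drawn from the seed's neighbor pool", {
  p <- hetero_protein(8)
  nb <- neighbors(p, L = 5)
  pools <- split(nb$neighbor, nb$residue)
  set.seed(2)
  for (i in 1:100) {
    patch <- sample_patch(p, nb)
    expect_length(patch, 4)
    expect_false(anyDuplicated(patch) > 0)
    expect_true(all(patch[-1] %in% pools[[as.character(patch[1])]]))
  }
})

test_that("first-pick frequencies follow the RSA weights", {
  p <- gen_toy_protein(6, codes = rep("GLY", 6),
                       rsa = c(0.05, 0.1, 0.2, 0.25, 0.15, 0.25),
                       geometry = "ring")
  nb <- neighbors(p)
  set.seed(99)
  n_draw <- 20000
  firsts <- replicate(n_draw, sample_patch(p, nb)[1])
  w <- p$rsa / sum(p$rsa)
  for (i in 1:6) {
    phat <- mean(firsts == i)
    se <- sqrt(w[i] * (1 - w[i]) / n_draw)
    expect_lt(abs(phat - w[i]), 3 * se)
  }
})

test_that("N = 1 collapses to a pure RSA-weighted draw", {
  p <- gen_toy_protein(6, codes = rep("GLY", 6),
                       rsa = c(0.4, 0.3, 0.1, 0.1, 0.05, 0.05),
                       geometry = "ring")
  nb <- neighbors(p)
  cfg <- selection_config(N = 1, reps = 50000, seed = 4)
  d <- sample_energy_distribution(p, nb, aa_energy_table(), cfg)
  expect_length(d$samples, 50000)
  expect_true(all(d$samples == aa_energy(aa_energy_table(), "GLY")))
  set.seed(5)
  patch <- sample_patch(p, nb, selection_config(N = 1))
  expect_length(patch, 1)
})

test_that("a homopolymer gives a single-point distribution at N * dE", {
  p <- homopolymer_cys()
  d <- sample_energy_distribution(p, neighbors(p), aa_energy_table(),
                                  selection_config(reps = 5000, seed = 1))
  expect_true(all(d$samples == -4 * 1.4944))
  expect_equal(d$mean, -5.9776)
  expect_equal(d$std, 0)
  expect_identical(d$gamma_method, "skipped")
})

test_that("all-zero RSA falls back to uniform with a warning", {
  p <- gen_toy_protein(6, codes = rep("CYS", 6), rsa = rep(0, 6),
                       geometry = "ring")
  expect_warning(
    d <- sample_energy_distribution(p, neighbors(p), aa_energy_table(),
                                    selection_config(reps = 10, seed = 1)),
    class = "porepass_uniform_fallback_warning")
  expect_length(d$samples, 10)
})

test_that("a single rep yields a one-sample distribution with the fit skipped", {
  p <- hetero_protein(6)
  d <- sample_energy_distribution(p, neighbors(p), toy_table(),
                                  selection_config(reps = 1, seed = 1))
  expect_length(d$samples, 1)
  expect_identical(d$gamma_method, "skipped")
})

test_that("table lookups name the unresolvable residue", {
  p <- gen_toy_protein(6, codes = c(rep("CYS", 5), "MET"), rsa = rep(0.5, 6),
                       geometry = "ring")
  expect_error(
    sample_energy_distribution(p, neighbors(p), aa_energy_table(),
                               selection_config(reps = 10, seed = 1)),
    regexp = "MET", class = "porepass_lookup_error")
})

test_that("fixed seeds reproduce the sample stream bit for bit", {
  p <- hetero_protein(8)
  nb <- neighbors(p)
  cfg <- selection_config(reps = 2000, seed = 77)
  d1 <- sample_energy_distribution(p, nb, toy_table(), cfg)
  d2 <- sample_energy_distribution(p, nb, toy_table(), cfg)
  expect_identical(d1$samples, d2$samples)
  d3 <- sample_energy_distribution(p, nb, toy_table(),
                                   selection_config(reps = 2000, seed = 78))
  expect_false(identical(d1$samples, d3$samples))
})

test_that("exact enumeration matches an independent brute-force law", {
  for (n in c(6, 8)) {
    p <- hetero_protein(n)
    nb <- neighbors(p, L = 5)
    tab <- toy_table()
    ex <- enumerate_exact(p, nb, tab, N = 4, L = 5)
    bf <- brute_force_patch_law(p, nb, tab, N = 4, L = 5)
    expect_equal(ex$mean, bf$mean, tolerance = 1e-12)
    expect_equal(ex$std, bf$std, tolerance = 1e-12)
    expect_equal(sum(ex$support$probability), 1, tolerance = 1e-12)
  }
})

test_that("enumeration restricts support to positively weighted seeds", {
  p <- gen_toy_protein(6, codes = c("CYS", "GLY", "ALA", "SER", "THR", "VAL"),
                       rsa = c(0.5, 0.5, 0, 0, 0, 0), geometry = "ring")
  nb <- neighbors(p)
  tab <- toy_table()
  ex <- enumerate_exact(p, nb, tab)
  bf <- brute_force_patch_law(p, nb, tab, N = 4, L = 5)
  expect_equal(sum(ex$support$probability), 1, tolerance = 1e-12)
  expect_equal(ex$mean, bf$mean, tolerance = 1e-12)
  # every support energy must be attainable from a patch seeded at 1 or 2
  seeded <- unique(unlist(lapply(1:2, function(i) {
    pool <- nb$neighbor[nb$residue == i]
    e <- aa_energy(tab, p$code)
    apply(utils::combn(pool, 3), 2, function(s) e[i] + sum(e[s]))
  })))
  expect_true(all(sapply(ex$support$energy,
                         function(x) any(abs(x - seeded) < 1e-12))))
})

test_that("homopolymer enumeration is a unit mass at -N |dE|", {
  p <- homopolymer_cys()
  ex <- enumerate_exact(p, neighbors(p), aa_energy_table())
  expect_identical(nrow(ex$support), 1L)
  expect_equal(ex$support$energy, -4 * 1.4944)
  expect_equal(ex$support$probability, 1)
  expect_equal(ex$std, 0)
})

test_that("Monte-Carlo means converge to the exact law", {
  p <- hetero_protein(6)
  nb <- neighbors(p)
  tab <- toy_table()
  ex <- enumerate_exact(p, nb, tab)
  reps <- 100000
  d <- sample_energy_distribution(p, nb, tab,
                                  selection_config(reps = reps, seed = 10))
  expect_lt(abs(d$mean - ex$mean), 3 * ex$std / sqrt(reps))
  expect_true(all(d$samples < 0))
})

test_that("gamma moments track the sample moments", {
  p <- hetero_protein(8)
  d <- sample_energy_distribution(p, neighbors(p), toy_table(),
                                  selection_config(reps = 50000, seed = 21))
  expect_identical(d$gamma_method, "mle")
  expect_equal(d$gamma_shape * d$gamma_scale, abs(d$mean), tolerance = 0.02)
  expect_equal(sqrt(d$gamma_shape) * d$gamma_scale, d$std, tolerance = 0.1)
})

test_that("homopolymer N-sweep means are exactly linear in N", {
  p <- homopolymer_cys()
  nb <- neighbors(p)
  sw <- sensitivity_sweep(p, nb, aa_energy_table(), sweep = "N",
                          values = 1:4,
                          cfg = selection_config(reps = 2000, seed = 3))
  expect_equal(sw$mean, -(1:4) * 1.4944)
  expect_equal(sw$std, rep(0, 4))
})

test_that("heteropolymer mean energy grows linearly with patch size", {
  p <- hetero_protein(8)
  nb <- neighbors(p, L = 5)
  tab <- toy_table()
  means <- sapply(1:6, function(N) enumerate_exact(p, nb, tab, N = N)$mean)
  expect_gt(stats::cor(seq_along(means), means)^2, 0.99)
  expect_true(all(diff(means) < 0))  # more residues, more attraction
})

test_that("Monte-Carlo scatter shrinks as one over root reps", {
  p <- hetero_protein(6)
  nb <- neighbors(p)
  tab <- toy_table()
  sds <- sapply(c(1000, 10000), function(reps) {
    means <- sapply(1:100, function(s) {
      cfg <- selection_config(reps = reps, seed = 1000 + s)
      mean(sample_energy_distribution(p, nb, tab, cfg,
                                      fit_gamma = FALSE)$samples)
    })
    sd(means)
  })
  expect_equal(sds[1] / sds[2], sqrt(10), tolerance = 0.2)
})

test_that("sweep rejects values violating the config invariants", {
  p <- hetero_protein(6)
  nb <- neighbors(p)
  expect_error(
    sensitivity_sweep(p, nb, toy_table(), sweep = "N", values = c(2, 9),
                      cfg = selection_config(reps = 10, seed = 1)),
    class = "porepass_input_error")
})
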