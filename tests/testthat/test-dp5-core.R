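# Boltzmann combination, molecular probability, calibration and the
# end-to-end pipeline.

test_that("Boltzmann weights follow closed forms", {
  expect_identical(boltzmann_weights(0)$weights, 1)
  expect_equal(boltzmann_weights(c(0, 0))$weights, c(0.5, 0.5))
  RT <- 8.31446e-3 * 298.15
  expect_equal(boltzmann_weights(c(0, RT * log(2)))$weights, c(2/3, 1/3),
               tolerance = 1e-10)
  expect_error(boltzmann_weights(numeric(0)), class = "dp5_value_error")
  expect_error(boltzmann_weights(0, temperature = 0),
               class = "dp5_parameter_error")
})

test_that("conformer combination is the weighted average with bound preservation", {
  w <- boltzmann_weights(c(0, 0))
  expect_equal(combine_conformers(rbind(c(0.2, 0.9), c(0.8, 0.1)), w),
               c(0.5, 0.5))
  w1 <- boltzmann_weights(0)
  expect_equal(combine_conformers(matrix(c(0.3, 0.7), 1), w1), c(0.3, 0.7))
  wfirst <- structure(list(weights = c(1, 0), temperature = 298.15),
                      class = "dp5_boltzmann")
  expect_equal(combine_conformers(rbind(c(0.2, 0.9), c(0.8, 0.1)), wfirst),
               c(0.2, 0.9))
  expect_error(combine_conformers(matrix(0.5, 3, 2), w), class = "dp5_value_error")
  set.seed(2)
  p <- matrix(runif(12), 3, 4)
  wts <- boltzmann_weights(c(0, 1, 4))
  comb <- combine_conformers(p, wts)
  expect_true(all(comb >= apply(p, 2, min) - 1e-12 &
                    comb <= apply(p, 2, max) + 1e-12))
})

test_that("molecular probability is idempotent on constants, symmetric, monotone", {
  for (c0 in c(0.1, 0.5, 0.7)) {
    for (n in c(1, 4, 9)) {
      expect_equal(molecular_probability(rep(c0, n)), c0, tolerance = 1e-12)
    }
  }
  set.seed(5)
  p <- runif(7, 0.05, 0.95)
  expect_equal(molecular_probability(p), molecular_probability(sample(p)),
               tolerance = 1e-14)
  base <- molecular_probability(p)
  for (i in c(1, 4)) {
    q <- p; q[i] <- q[i] - 0.04
    expect_lte(molecular_probability(q), base)
  }
  # zero probabilities are floored, not fatal
  expect_silent(suppressMessages(pz <- molecular_probability(c(0, 0.5, 0.9))))
  expect_gte(pz, 0)
  expect_error(molecular_probability(numeric(0)), class = "dp5_value_error")
})

test_that("indistinguishable classes calibrate to the prior, separated ones to confident posteriors", {
  set.seed(14)
  # at 2000/class the pointwise KDE-ratio noise is small enough that the
  # posterior tracks the prior across the whole data-supported range
  same_a <- rbeta(2000, 4, 4)
  same_b <- rbeta(2000, 4, 4)
  cal <- fit_calibration(same_a, same_b, prior_correct = 0.5)
  x <- seq(0.1, 0.9, by = 0.05)
  expect_lt(max(abs(dp5_probability(x, cal) - 0.5)), 0.05)
  # at 200/class the same holds more loosely in the bulk, and the uniform
  # regulariser pulls data-free tails back toward the prior
  cal200 <- fit_calibration(rbeta(200, 4, 4), rbeta(200, 4, 4))
  xq <- seq(0.25, 0.75, by = 0.05)
  expect_lt(max(abs(dp5_probability(xq, cal200) - 0.5)), 0.15)

  correct <- rbeta(400, 35, 15)    # concentrated near 0.7
  incorrect <- rbeta(400, 6, 54)   # concentrated near 0.1
  cal2 <- fit_calibration(correct, incorrect)
  expect_gt(dp5_probability(0.7, cal2), 0.9)
  expect_lt(dp5_probability(0.1, cal2), 0.1)

  # class densities integrate to one on [0, 1] (fine composite trapezoid
  # over the piecewise-linear density)
  fine <- seq(0, 1, length.out = 200001)
  for (cls in c("correct", "incorrect")) {
    mass <- dp5:::trapz(fine, calibration_density(cal2, fine, cls))
    expect_equal(mass, 1, tolerance = 1e-6)
  }

  expect_error(fit_calibration(runif(10), runif(200)),
               class = "dp5_calibration_error")
  expect_error(fit_calibration(runif(100), runif(100), prior_correct = 1),
               class = "dp5_parameter_error")
})

test_that("the Bayes posterior reproduces hand-computed arithmetic", {
  grid <- seq(0.001, 0.999, length.out = 512)
  f_c <- dnorm(grid, 0.6, 0.1); f_c <- f_c / dp5:::trapz(grid, f_c)
  f_i <- dnorm(grid, 0.3, 0.15); f_i <- f_i / dp5:::trapz(grid, f_i)
  model <- structure(list(p_grid = grid, f_correct = f_c, f_incorrect = f_i,
                          prior_correct = 0.4, transform = "logit"),
                     class = "dp5_calibration")
  at <- grid[c(50, 200, 400)]
  manual <- 0.4 * f_c[c(50, 200, 400)] /
    (0.4 * f_c[c(50, 200, 400)] + 0.6 * f_i[c(50, 200, 400)])
  expect_equal(dp5_probability(at, model), manual, tolerance = 1e-10)

  # f_i = 0, f_c > 0 gives certainty; both zero falls back to the prior
  model$f_incorrect[200] <- 0
  expect_equal(dp5_probability(grid[200], model), 1)
  model$f_correct[200] <- 0
  expect_equal(dp5_probability(grid[200], model), 0.4)
  # equal densities return the prior exactly
  model2 <- model; model2$f_incorrect <- model2$f_correct
  expect_equal(dp5_probability(grid[300], model2), 0.4, tolerance = 1e-12)
})

test_that("calibration JSON round-trips", {
  cal <- small_calibration()
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(back$f_correct, cal$f_correct)
  expect_equal(back$prior_correct, cal$prior_correct)
  x <- c(0.2, 0.5, 0.8)
  expect_equal(dp5_probability(x, back), dp5_probability(x, cal))
})

test_that("run_dp5 is deterministic and dominates its perturbed-spectrum runs", {
  gen <- small_gen()
  db <- small_db()
  cal <- small_calibration()
  cfg <- dp5_config()
  mol <- gen$corpus[[4]]$molecule
  own <- peak_list(mol$conformers[[1]]$shifts)  # zero-error spectrum
  r_perfect <- run_dp5(mol, own, db, cal, cfg,
                       exclude_molecule = mol$molecule_id)
  r_again <- run_dp5(mol, own, db, cal, cfg,
                     exclude_molecule = mol$molecule_id)
  expect_identical(r_perfect, r_again)

  wrong <- generate_incorrect_spectrum(mol, gen$spec, inflation = 4)
  r_wrong <- run_dp5(mol, wrong, db, cal, cfg,
                     exclude_molecule = mol$molecule_id)
  expect_gt(r_perfect$molecular_probability, r_wrong$molecular_probability)
  expect_gte(r_perfect$dp5, r_wrong$dp5)
  expect_true(all(r_perfect$atomic_probabilities >= 0 &
                    r_perfect$atomic_probabilities <= 1))
})

test_that("multi-conformer molecules Boltzmann-average their atomic probabilities", {
  gen <- small_gen()
  db <- small_db()
  cfg <- dp5_config()
  mol <- gen$corpus[[6]]$molecule
  mol$conformers[[2]] <- mol$conformers[[1]]
  mol$conformers[[2]]$relative_energy <- 3
  mol$conformers[[2]]$shifts <- mol$conformers[[1]]$shifts + 0.8
  peaks <- gen$corpus[[6]]$peaks
  res <- run_dp5(mol, peaks, db, config = cfg,
                 exclude_molecule = mol$molecule_id)
  w <- res$conformer_weights$weights
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(combine_conformers(res$diagnostics$per_conformer_p,
                                  res$conformer_weights),
               res$atomic_probabilities, tolerance = 1e-12)
})

test_that("inflating all errors never increases the molecular probability", {
  # unbiased (symmetric, zero-location) error laws so every bespoke density
  # is centred near zero and the window mass decays with |error|
  gen <- fixture("gen_symmetric", generate_corpus(synthetic_spec(
    n_molecules = 25, cluster_error_location = c(0, 0, 0), seed = 77)))
  db <- fixture("db_symmetric", build_error_database(gen$corpus))
  cfg <- dp5_config()
  mol <- gen$corpus[[8]]$molecule
  shifts <- mol$conformers[[1]]$shifts
  set.seed(19)
  delta <- runif(length(shifts), -0.8, 0.8)
  prev <- Inf
  for (fac in c(1, 1.5, 2.5, 4)) {
    res <- run_dp5(mol, peak_list(shifts - fac * delta), db, config = cfg,
                   exclude_molecule = mol$molecule_id)
    expect_lte(res$molecular_probability, prev + 1e-9)
    prev <- res$molecular_probability
  }
})
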