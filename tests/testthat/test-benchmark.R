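# Pair construction, MAE matching, leave-one-out evaluation, ranking.

test_that("spectrum permutation builds n correct and n(n-1) same-size incorrect pairs", {
  gen <- generate_corpus(synthetic_spec(n_molecules = 3, carbons_range = c(6, 6),
                                        seed = 51))
  # unfiltered enumeration: permutation incorrect pairs between random
  # molecules have huge errors, so disable the case-1 gate for counting
  ps <- make_pairs(gen, case = "case1", max_error_filter = Inf)
  s <- ps$samples
  expect_equal(sum(s$label == "correct"), 3)
  expect_equal(sum(s$label == "incorrect"), 6)
  expect_false(anyDuplicated(s[, c("structure_id", "spectrum_id")]) > 0)

  # differing carbon counts: no incorrect pairs at all
  g1 <- generate_corpus(synthetic_spec(n_molecules = 1, carbons_range = c(5, 5),
                                       seed = 52))
  g2 <- generate_corpus(synthetic_spec(n_molecules = 1, carbons_range = c(8, 8),
                                       seed = 53))
  mixed <- c(g1$corpus, g2$corpus)
  mixed[[2]]$molecule$molecule_id <- "other"
  suppressMessages(ps2 <- make_pairs(mixed, case = "case1"))
  expect_equal(sum(ps2$samples$label == "incorrect"), 0)
})

test_that("case 1 discards incorrect pairs with max scaled error of 10 ppm or more", {
  gen <- fixture("gen_filter", generate_corpus(synthetic_spec(
    n_molecules = 20, incorrect_inflation = 12, seed = 61)))
  # inflated incorrect spectra, gate disabled, then re-filtered under the rule
  p_all <- make_regime_pairs(gen, "case1", n_incorrect = 40, seed = 62,
                             max_error_filter = Inf)
  p_filtered <- dp5:::apply_case(p_all, "case1")
  inc <- p_filtered$samples[p_filtered$samples$label == "incorrect", ]
  expect_true(all(inc$max_error < 10))
  dropped <- p_all$samples$label == "incorrect" & p_all$samples$max_error >= 10
  expect_gt(sum(dropped), 0)
  expect_equal(nrow(p_filtered$samples), nrow(p_all$samples) - sum(dropped))
})

test_that("MAE-matching weights are a clipped, normalised density ratio", {
  set.seed(41)
  same_c <- rgamma(500, 6, 4)
  same_i <- rgamma(500, 6, 4)
  w_same <- mae_matching_weights(same_c, same_i)
  expect_equal(mean(w_same), 1, tolerance = 1e-12)
  # equal laws: the bulk of the ratio sits at 1 (tails of a KDE ratio are noisy)
  expect_lt(median(abs(w_same - 1)), 0.2)
  expect_gt(mean(w_same > 0.6 & w_same < 1.6), 0.8)

  doubled <- 2 * rgamma(500, 6, 4)
  w2 <- mae_matching_weights(same_c, doubled)
  expect_true(all(is.finite(w2) & w2 >= 0))
  # analytic ratio decreases in MAE over the overlap region
  expect_lt(cor(doubled, w2, method = "spearman"), -0.5)
  # weighting pulls the incorrect-MAE mean most of the way to the correct mean
  gap_before <- abs(mean(doubled) - mean(same_c))
  gap_after <- abs(sum(w2 * doubled) / sum(w2) - mean(same_c))
  expect_lt(gap_after, 0.3 * gap_before)

  expect_error(mae_matching_weights(rnorm(100, 100, 0.5), rnorm(100, 1, 0.1)),
               class = "dp5_value_error")
})

test_that("leave-one-out evaluation never consults the test structure's own records", {
  gen <- small_gen()
  db <- small_db()
  cfg <- dp5_config()
  entry <- gen$corpus[[2]]
  id <- entry$molecule$molecule_id
  # flip the sign of this molecule's own errors: |errors| and eps* are
  # unchanged, so if (and only if) its records are excluded the result is
  # bit-identical
  db_flipped <- error_database(db$descriptors,
                               ifelse(db$molecule_ids == id, -db$errors, db$errors),
                               db$molecule_ids, db$params)
  expect_equal(db_flipped$eps_star, db$eps_star)
  r1 <- run_dp5(entry$molecule, entry$peaks, db, config = cfg,
                exclude_molecule = id)
  r2 <- run_dp5(entry$molecule, entry$peaks, db_flipped, config = cfg,
                exclude_molecule = id)
  expect_identical(r1$molecular_probability, r2$molecular_probability)
  r3 <- run_dp5(entry$molecule, entry$peaks, db_flipped, config = cfg)
  expect_false(identical(r1$molecular_probability, r3$molecular_probability))
})

test_that("benchmark reports carry coherent AUROC, reliability and a null at chance", {
  rep <- small_report()
  expect_true(rep$auroc >= 0 && rep$auroc <= 1)
  expect_gt(rep$auroc, 0.8)   # grossly wrong spectra are easy to reject
  s <- rep$samples[!is.na(rep$samples$dp5), ]
  expect_true(all(s$dp5 >= 0 & s$dp5 <= 1))
  # label shuffle collapses discrimination to chance
  set.seed(77)
  null_auc <- replicate(30, weighted_auroc(s$dp5, sample(s$label == "correct"),
                                           s$weight))
  expect_lt(abs(mean(null_auc) - 0.5), 0.05)
  # unweighted AUROC agrees with an independent implementation
  expect_equal(weighted_auroc(s$Pn, s$label == "correct"),
               as.numeric(pROC::auc(pROC::roc(s$label == "correct", s$Pn,
                                              quiet = TRUE, direction = "<"))),
               tolerance = 1e-12)
})

test_that("candidate ranking scores independently and normalises by candidate count", {
  gen <- small_gen()
  db <- small_db()
  cal <- small_calibration()
  cfg <- dp5_config()
  mol <- gen$corpus[[10]]$molecule
  peaks <- gen$corpus[[10]]$peaks
  twin <- mol; twin$molecule_id <- "twin"
  perturbed <- mol
  perturbed$molecule_id <- "perturbed"
  set.seed(91)
  perturbed$conformers[[1]]$shifts <-
    perturbed$conformers[[1]]$shifts + rnorm(length(carbon_indices(mol)), 0, 6)

  rk <- rank_candidates(list(mol, twin, perturbed), peaks, db, cal, cfg)
  expect_equal(rk$dp5[1], rk$dp5[2])          # identical structures tie
  expect_identical(attr(rk, "best"), 1L)      # earliest wins the tie
  expect_gt(rk$dp5[1], rk$dp5[3])             # own shifts beat perturbed
  expect_equal(rk$dp5_normalized, rk$dp5 / 3)
  expect_lte(sum(rk$dp5_normalized), 1)
  expect_error(rank_candidates(list(mol), peaks, db, cal, cfg),
               class = "dp5_value_error")
})
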