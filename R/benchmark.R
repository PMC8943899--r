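# Cross-validation benchmark: spectrum permutation, case-1 filtering,
# case-2 MAE-matched weighting, leave-one-out DP5 evaluation, and the
# candidate-ranking mode.

pair_stats <- function(molecule, peaks, conformer = 1L) {
  shifts <- molecule$conformers[[conformer]]$shifts
  asg <- assign_peaks(shifts, peaks)
  delta <- suppressWarnings(scale_errors(asg, shifts))
  d <- abs(delta[!is.na(delta)])
  list(mae = mean(d), max_error = max(d))
}

new_pair_set <- function(samples, peaks, molecules, case) {
  structure(list(samples = samples, peaks = peaks, molecules = molecules,
                 case = case), class = "dp5_pair_set")
}

#' @export
print.dp5_pair_set <- function(x, ...) {
  cat(sprintf("<dp5_pair_set (%s): %d correct, %d incorrect pairs>\n",
              x$case, sum(x$samples$label == "correct"),
              sum(x$samples$label == "incorrect")))
  invisible(x)
}

#' Permute spectra between structures to form correct and incorrect pairs
#'
#' Every molecule is paired with its own spectrum (correct pair) and with
#' spectra of other molecules having the same carbon count (incorrect
#' pairs). Under `case1`, incorrect pairs with a maximum absolute scaled
#' error of 10 ppm or more are discarded and the survivors carry unit
#' weight; under `case2` all incorrect pairs are kept and receive
#' MAE-matching sampling weights so that their MAE distribution
#' approximates that of the correct pairs.
#'
#' @param corpus List of `list(molecule, peaks)` entries (or a
#'   `dp5_synthetic_corpus`).
#' @param case `"case1"` or `"case2"`.
#' @param max_error_filter Case-1 exclusion threshold in ppm.
#' @param max_incorrect Optional cap on the number of incorrect pairs
#'   (seeded subsample).
#' @param seed Seed used only when subsampling incorrect pairs.
#' @param conformer Designated conformer for the pair statistics.
#'
#' @return A `dp5_pair_set`.
#' @export
make_pairs <- function(corpus, case = c("case1", "case2"),
                       max_error_filter = 10, max_incorrect = Inf,
                       seed = 1L, conformer = 1L) {
  case <- match.arg(case)
  if (inherits(corpus, "dp5_synthetic_corpus")) corpus <- corpus$corpus
  mols <- lapply(corpus, `[[`, "molecule")
  ids <- vapply(mols, `[[`, character(1), "molecule_id")
  names(mols) <- ids
  ncarb <- vapply(mols, function(m) length(carbon_indices(m)), integer(1))

  rows <- list(); pk <- list()
  for (i in seq_along(corpus)) {
    st <- pair_stats(mols[[i]], corpus[[i]]$peaks, conformer)
    rows[[length(rows) + 1L]] <- data.frame(
      structure_id = ids[i], spectrum_id = ids[i], label = "correct",
      mae = st$mae, max_error = st$max_error, weight = 1)
    pk[[length(pk) + 1L]] <- corpus[[i]]$peaks
  }
  cand <- which(outer(ncarb, ncarb, "==") & !diag(length(ids)), arr.ind = TRUE)
  if (nrow(cand) > 0L && nrow(cand) > max_incorrect) {
    set.seed(seed)
    cand <- cand[sample.int(nrow(cand), max_incorrect), , drop = FALSE]
  }
  lone <- setdiff(seq_along(ids), unique(cand[, 1]))
  if (length(lone) > 0L && nrow(cand) < length(ids) * (length(ids) - 1)) {
    message(sprintf("dp5: %d molecule(s) contribute only their correct pair",
                    length(lone)))
  }
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    st <- pair_stats(mols[[i]], corpus[[j]]$peaks, conformer)
    rows[[length(rows) + 1L]] <- data.frame(
      structure_id = ids[i], spectrum_id = ids[j], label = "incorrect",
      mae = st$mae, max_error = st$max_error, weight = 1)
    pk[[length(pk) + 1L]] <- corpus[[j]]$peaks
  }
  samples <- do.call(rbind, rows)
  apply_case(new_pair_set(samples, pk, mols, case), case, max_error_filter)
}

apply_case <- function(pair_set, case, max_error_filter = 10) {
  s <- pair_set$samples
  if (case == "case1") {
    keep <- s$label == "correct" | s$max_error < max_error_filter
    pair_set$samples <- s[keep, , drop = FALSE]
    pair_set$peaks <- pair_set$peaks[keep]
    pair_set$samples$weight <- 1
  } else {
    inc <- s$label == "incorrect"
    if (any(inc)) {
      s$weight[inc] <- mae_matching_weights(s$mae[s$label == "correct"],
                                            s$mae[inc])
    }
    pair_set$samples <- s
  }
  rownames(pair_set$samples) <- NULL
  pair_set$case <- case
  pair_set
}

#' Correct/incorrect pairs in a controlled error regime
#'
#' Builds the benchmark pair population from a synthetic corpus using
#' generated incorrect spectra instead of exhaustive permutation: the
#' case-1 regime inflates the incorrect-pair errors
#' (`spec$incorrect_inflation`) and applies the max-error filter; the
#' case-2 regime draws incorrect errors from the same magnitude law as the
#' correct pairs (inflation 1, environment-mismatched) and attaches
#' MAE-matching weights.
#'
#' @param gen A `dp5_synthetic_corpus`.
#' @param case `"case1"` or `"case2"`.
#' @param n_incorrect Number of incorrect pairs to generate.
#' @param seed RNG seed for spectrum generation.
#' @param max_error_filter Case-1 exclusion threshold in ppm.
#'
#' @return A `dp5_pair_set`.
#' @export
make_regime_pairs <- function(gen, case = c("case1", "case2"),
                              n_incorrect = length(gen$corpus), seed = 1L,
                              max_error_filter = 10) {
  case <- match.arg(case)
  stopifnot(inherits(gen, "dp5_synthetic_corpus"))
  corpus <- gen$corpus
  mols <- lapply(corpus, `[[`, "molecule")
  ids <- vapply(mols, `[[`, character(1), "molecule_id")
  names(mols) <- ids
  inflation <- if (case == "case1") gen$spec$incorrect_inflation else 1.0
  set.seed(seed)
  rows <- list(); pk <- list()
  for (i in seq_along(corpus)) {
    st <- pair_stats(mols[[i]], corpus[[i]]$peaks)
    rows[[length(rows) + 1L]] <- data.frame(
      structure_id = ids[i], spectrum_id = ids[i], label = "correct",
      mae = st$mae, max_error = st$max_error, weight = 1)
    pk[[length(pk) + 1L]] <- corpus[[i]]$peaks
  }
  pool <- gen$truth$cluster
  targets <- rep(seq_along(corpus), length.out = n_incorrect)
  for (k in seq_along(targets)) {
    i <- targets[k]
    wrong <- generate_incorrect_spectrum(mols[[i]], gen$spec,
                                         inflation = inflation,
                                         cluster_pool = pool)
    st <- pair_stats(mols[[i]], wrong)
    rows[[length(rows) + 1L]] <- data.frame(
      structure_id = ids[i], spectrum_id = sprintf("%s_wrong%03d", ids[i], k),
      label = "incorrect", mae = st$mae, max_error = st$max_error, weight = 1)
    pk[[length(pk) + 1L]] <- wrong
  }
  samples <- do.call(rbind, rows)
  apply_case(new_pair_set(samples, pk, mols, case), case, max_error_filter)
}

#' MAE-matching importance weights for incorrect pairs
#'
#' Importance weights proportional to the density ratio
#' `f_correct(mae) / f_incorrect(mae)` (one-dimensional KDEs), clipped at
#' the 99.5th weight percentile to bound their variance and normalised to
#' mean one. After weighting, the incorrect-pair MAE distribution
#' approximates that of the correct pairs.
#'
#' @param correct_maes MAE values (ppm) of the correct pairs.
#' @param incorrect_maes MAE values of the incorrect pairs.
#' @param clip_quantile Clipping quantile for the raw weights.
#'
#' @return Non-negative weights over the incorrect pairs, mean 1.
#' @export
mae_matching_weights <- function(correct_maes, incorrect_maes,
                                 clip_quantile = 0.995) {
  if (length(correct_maes) == 0L || length(incorrect_maes) == 0L) {
    dp5_stop("both MAE samples must be nonempty", "dp5_value_error")
  }
  dc <- stats::density(correct_maes, n = 1024)
  di <- stats::density(incorrect_maes, n = 1024)
  fc <- stats::approx(dc$x, dc$y, xout = incorrect_maes, yleft = 0, yright = 0)$y
  fi <- stats::approx(di$x, di$y, xout = incorrect_maes, yleft = 0, yright = 0)$y
  w <- fc / pmax(fi, 1e-12)
  if (all(w == 0)) {
    dp5_stop("correct and incorrect MAE supports are disjoint; the corpora are not comparable",
             "dp5_value_error")
  }
  w <- pmin(w, stats::quantile(w, clip_quantile))
  w / mean(w)
}

#' Leave-one-out DP5 evaluation of a pair population
#'
#' For every pair the molecular probability is computed with the test
#' structure's own atoms excluded from the reference database; the Bayesian
#' calibration is refitted k-fold over structures (each pair is scored by a
#' calibration fitted without any pair of its own structure). The report
#' aggregates the weighted DP5 distributions, AUROC, and a decile
#' reliability curve.
#'
#' @param pair_set A `dp5_pair_set`.
#' @param config A `dp5_config`.
#' @param db Optional prebuilt `dp5_error_db`; by default one is built from
#'   the correct pairs of the pair set.
#' @param folds Number of calibration folds.
#' @param seed Seed for the fold assignment.
#'
#' @return An object of class `dp5_benchmark_report`.
#' @export
loo_evaluate <- function(pair_set, config = dp5_config(), db = NULL,
                         folds = config$benchmark$folds, seed = 1L) {
  s <- pair_set$samples
  params <- params_from_config(config)
  if (is.null(db)) {
    corr <- which(s$label == "correct")
    db <- build_error_database(
      lapply(corr, function(r) list(molecule = pair_set$molecules[[s$structure_id[r]]],
                                    peaks = pair_set$peaks[[r]])),
      params = params)
  }
  config$kernel$sigma <- resolve_sigma(db, config)
  n <- nrow(s)
  Pn <- rep(NA_real_, n)
  failures <- character(0)
  for (r in seq_len(n)) {
    res <- tryCatch(
      run_dp5(pair_set$molecules[[s$structure_id[r]]], pair_set$peaks[[r]],
              db, model = NULL, config = config,
              exclude_molecule = s$structure_id[r]),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s/%s: %s", s$structure_id[r],
                                      s$spectrum_id[r], conditionMessage(res)))
    } else {
      Pn[r] <- res$molecular_probability
    }
  }
  if (length(failures) > 0L) {
    dp5_warn(sprintf("%d pair(s) failed during evaluation: %s",
                     length(failures),
                     paste(utils::head(failures, 3), collapse = "; ")),
             "dp5_pair_failure_warning")
  }
  s$Pn <- Pn
  # k-fold calibration refit over structures
  set.seed(seed)
  sid <- unique(s$structure_id)
  fold_of <- setNames(sample(rep(seq_len(folds), length.out = length(sid))), sid)
  s$fold <- fold_of[s$structure_id]
  s$dp5 <- NA_real_
  prior <- config$calibration$prior_correct
  for (f in seq_len(folds)) {
    train <- s$fold != f & !is.na(s$Pn)
    test <- s$fold == f & !is.na(s$Pn)
    if (!any(test)) next
    cal <- fit_calibration(s$Pn[train & s$label == "correct"],
                           s$Pn[train & s$label == "incorrect"],
                           incorrect_weights = s$weight[train & s$label == "incorrect"],
                           prior_correct = prior,
                           n_grid = config$calibration$n_grid)
    s$dp5[test] <- dp5_probability(s$Pn[test], cal)
  }
  model <- fit_calibration(s$Pn[s$label == "correct" & !is.na(s$Pn)],
                           s$Pn[s$label == "incorrect" & !is.na(s$Pn)],
                           incorrect_weights = s$weight[s$label == "incorrect" & !is.na(s$Pn)],
                           prior_correct = prior,
                           n_grid = config$calibration$n_grid)
  ok <- !is.na(s$dp5)
  auroc <- weighted_auroc(s$dp5[ok], s$label[ok] == "correct", s$weight[ok])
  rel <- reliability_curve(s$dp5[ok], s$label[ok] == "correct", s$weight[ok])
  structure(list(samples = s, auroc = auroc, reliability = rel,
                 case = pair_set$case, db = db, calibration = model,
                 effective_n = c(correct = sum(s$label == "correct"),
                                 incorrect_effective =
                                   sum(s$weight[s$label == "incorrect"])),
                 failures = failures),
            class = "dp5_benchmark_report")
}

# Decile reliability curve and its expected-calibration-error style summary
# (bin deviations averaged with the bins' effective weights).
reliability_curve <- function(dp5, correct, weight) {
  edges <- seq(0, 1, by = 0.1)
  bin <- cut(dp5, edges, include.lowest = TRUE)
  mids <- (utils::head(edges, -1) + utils::tail(edges, -1)) / 2
  out <- data.frame(bin = levels(bin), midpoint = mids,
                    weight = NA_real_, fraction_correct = NA_real_)
  for (b in seq_along(levels(bin))) {
    in_bin <- !is.na(bin) & as.integer(bin) == b
    wsum <- sum(weight[in_bin])
    out$weight[b] <- wsum
    if (wsum > 0) {
      out$fraction_correct[b] <- sum(weight[in_bin] * correct[in_bin]) / wsum
    }
  }
  occ <- !is.na(out$fraction_correct)
  mad <- sum(out$weight[occ] * abs(out$fraction_correct[occ] - out$midpoint[occ])) /
    sum(out$weight[occ])
  attr(out, "mad") <- mad
  out
}

#' @export
print.dp5_benchmark_report <- function(x, ...) {
  cat(sprintf("<dp5_benchmark_report (%s): AUROC %.3f, reliability MAD %.3f, %d correct / %.0f effective incorrect>\n",
              x$case, x$auroc, attr(x$reliability, "mad"),
              x$effective_n["correct"], x$effective_n["incorrect_effective"]))
  invisible(x)
}

#' Rank candidate structures against one spectrum
#'
#' Computes an independent DP5 probability for each candidate (no
#' renormalisation across candidates: each probability stands alone) and
#' additionally reports `dp5 / k` for `k` candidates, the convention that
#' keeps the sum of reported probabilities within `[0, 1]` when candidates
#' enumerate e.g. the diastereomers of one constitution.
#'
#' @param candidates List of `dp5_molecule`s with calculated shifts.
#' @param peaks A `dp5_peaklist`.
#' @param db A `dp5_error_db`.
#' @param model A fitted `dp5_calibration`.
#' @param config A `dp5_config`.
#'
#' @return An object of class `dp5_ranking`: a data frame of per-candidate
#'   probabilities (input order) with attribute `best` (index of the
#'   highest-DP5 candidate, earliest on ties).
#' @export
rank_candidates <- function(candidates, peaks, db, model,
                            config = dp5_config()) {
  if (length(candidates) < 2L) {
    dp5_stop("candidate ranking needs at least two structures", "dp5_value_error")
  }
  k <- length(candidates)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    res <- tryCatch(run_dp5(candidates[[i]], peaks, db, model, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      dp5_warn(sprintf("candidate %d ('%s') failed and is excluded: %s", i,
                       candidates[[i]]$molecule_id, conditionMessage(res)),
               "dp5_candidate_warning")
      rows[[i]] <- data.frame(candidate = candidates[[i]]$molecule_id,
                              Pn = NA_real_, dp5 = NA_real_,
                              dp5_normalized = NA_real_)
    } else {
      rows[[i]] <- data.frame(candidate = candidates[[i]]$molecule_id,
                              Pn = res$molecular_probability, dp5 = res$dp5,
                              dp5_normalized = res$dp5 / k)
    }
  }
  out <- do.call(rbind, rows)
  best <- which.max(ifelse(is.na(out$dp5), -Inf, out$dp5))
  attr(out, "best") <- best
  class(out) <- c("dp5_ranking", class(out))
  out
}
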