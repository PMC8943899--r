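# Conformer combination, molecular probability, empirical Bayesian
# calibration, and the end-to-end DP5 pipeline.

#' Boltzmann conformer weights
#'
#' `w_i` proportional to `exp(-E_i / RT)` with `R = 8.31446e-3 kJ/(mol K)`.
#' Energies are taken relative to the minimum conformer.
#'
#' @param relative_energies Conformer energies in kJ/mol.
#' @param temperature Temperature in Kelvin (default 298.15).
#'
#' @return An object of class `dp5_boltzmann` with normalised `weights`
#'   (summing to 1) and `temperature`.
#' @export
#'
#' @examples
#' boltzmann_weights(c(0, 8.31446e-3 * 298.15 * log(2)))$weights  # 2/3, 1/3
boltzmann_weights <- function(relative_energies, temperature = 298.15) {
  if (length(relative_energies) == 0L) {
    dp5_stop("no conformer energies supplied", "dp5_value_error")
  }
  if (any(!is.finite(relative_energies))) {
    dp5_stop("non-finite conformer energy", "dp5_value_error")
  }
  if (temperature <= 0) dp5_stop("temperature must be > 0", "dp5_parameter_error")
  e <- relative_energies - min(relative_energies)
  w <- exp(-e / (.RGAS_KJ * temperature))
  structure(list(weights = w / sum(w), temperature = temperature),
            class = "dp5_boltzmann")
}

#' Boltzmann-average per-conformer atomic probabilities
#'
#' @param per_conformer_p Matrix of atomic probabilities, one row per
#'   conformer, one column per carbon.
#' @param weights A `dp5_boltzmann` for the same conformers.
#'
#' @return Per-atom averaged probabilities.
#' @export
combine_conformers <- function(per_conformer_p, weights) {
  per_conformer_p <- as.matrix(per_conformer_p)
  if (nrow(per_conformer_p) != length(weights$weights)) {
    dp5_stop(sprintf("probability table has %d rows for %d conformer weights",
                     nrow(per_conformer_p), length(weights$weights)),
             "dp5_value_error")
  }
  as.numeric(colSums(per_conformer_p * weights$weights))
}

#' Molecular probability from atomic probabilities
#'
#' Symmetric geometric-mean combination: with `g(p)` the geometric mean of
#' the atomic probabilities and `g(1-p)` that of their complements,
#' `Pn = g(p) / (g(p) + g(1-p))`. The geometric mean tempers the influence
#' of any single atom with an extreme probability; the odds form keeps the
#' result a probability with `Pn = c` whenever all atomic probabilities
#' equal `c`, and monotone non-decreasing in every atomic probability.
#' Probabilities are floored at `1e-12` (and capped at `1 - 1e-12`) before
#' taking logarithms.
#'
#' @param atomic_p Per-atom probabilities in `[0, 1]`.
#' @param floor Numerical floor applied before the log-domain arithmetic.
#'
#' @return The molecular probability `Pn` in `[0, 1]`.
#' @export
molecular_probability <- function(atomic_p, floor = 1e-12) {
  atomic_p <- atomic_p[!is.na(atomic_p)]
  if (length(atomic_p) == 0L) {
    dp5_stop("no atomic probabilities to combine", "dp5_value_error")
  }
  if (any(atomic_p <= 0 | atomic_p >= 1)) {
    message("dp5: atomic probabilities clipped to (", floor, ", 1 - ", floor,
            ") before combination")
  }
  p <- clamp(atomic_p, floor, 1 - floor)
  log_gp <- mean(log(p))
  log_gq <- mean(log1p(-p))
  1 / (1 + exp(log_gq - log_gp))
}

# ---- Empirical Bayesian calibration ----------------------------------------

#' Fit the empirical calibration mapping Pn to P(correct | Pn)
#'
#' Estimates one-dimensional densities of the molecular probability for
#' known-correct and known-incorrect structure-spectrum pairs. Densities are
#' fitted on the logit scale (weighted Gaussian KDE) and back-transformed
#' with the Jacobian so they are proper densities on `[0, 1]`; each is
#' renormalised to integrate to one on its evaluation grid. Incorrect-pair
#' sampling weights (e.g. the MAE-matching weights of the case-2 benchmark)
#' are honoured.
#'
#' Each class density is a mixture `(1 - reg) * KDE + reg * Uniform(0, 1)`.
#' The uniform floor regularises the likelihood ratio where one class has
#' little data (raw KDE tails are noisy and would make the posterior swing
#' wildly on a handful of samples), and it encodes that no molecular
#' probability value is ever impossible for either class -- so the
#' calibrated probability can approach but never reach 0 or 1.
#'
#' @param correct_Pn Molecular probabilities of correct pairs (>= 30).
#' @param incorrect_Pn Molecular probabilities of incorrect pairs (>= 30).
#' @param incorrect_weights Optional non-negative sampling weights for the
#'   incorrect pairs.
#' @param prior_correct Prior probability that a proposed structure is
#'   correct (default 0.5: a proposal is a priori as likely to be right as
#'   wrong).
#' @param n_grid Number of logit-spaced density knots.
#' @param reg Weight of the uniform regularising component in each class
#'   density.
#'
#' @return An object of class `dp5_calibration` with fields `p_grid`,
#'   `f_correct`, `f_incorrect`, `prior_correct`, `transform`.
#' @export
fit_calibration <- function(correct_Pn, incorrect_Pn, incorrect_weights = NULL,
                            prior_correct = 0.5, n_grid = 512L, reg = 0.1) {
  if (length(correct_Pn) < 30L || length(incorrect_Pn) < 30L) {
    dp5_stop(sprintf(
      "calibration refused: need >= 30 samples per class (got %d correct, %d incorrect)",
      length(correct_Pn), length(incorrect_Pn)), "dp5_calibration_error")
  }
  if (prior_correct <= 0 || prior_correct >= 1) {
    dp5_stop("prior_correct must lie in (0, 1)", "dp5_parameter_error")
  }
  if (is.null(incorrect_weights)) incorrect_weights <- rep(1, length(incorrect_Pn))
  if (length(incorrect_weights) != length(incorrect_Pn) ||
      any(incorrect_weights < 0) || sum(incorrect_weights) == 0) {
    dp5_stop("incorrect_weights must be non-negative, aligned, not all zero",
             "dp5_value_error")
  }
  eps <- 1e-6
  zgrid <- seq(stats::qlogis(1e-4), stats::qlogis(1 - 1e-4), length.out = n_grid)
  pgrid <- stats::plogis(zgrid)
  fit_one <- function(x, w) {
    z <- stats::qlogis(clamp(x, eps, 1 - eps))
    w <- w / sum(w)
    # twice the reference bandwidth: calibration curves are low-complexity
    # and a ratio of two densities is far more sensitive to undersmoothing
    # than either density alone
    h <- 2 * stats::bw.nrd0(z)
    d <- stats::density(z, weights = w, bw = h, n = 1024,
                        from = min(z) - 3 * h, to = max(z) + 3 * h)
    fz <- stats::approx(d$x, d$y, xout = zgrid, yleft = 0, yright = 0)$y
    fp <- fz / (pgrid * (1 - pgrid))
    area <- trapz(pgrid, fp)
    if (area <= 0) dp5_stop("degenerate calibration density", "dp5_calibration_error")
    fp <- (1 - reg) * fp / area + reg
    fp / trapz(pgrid, fp)
  }
  structure(list(p_grid = pgrid,
                 f_correct = fit_one(correct_Pn, rep(1, length(correct_Pn))),
                 f_incorrect = fit_one(incorrect_Pn, incorrect_weights),
                 prior_correct = prior_correct,
                 transform = "logit"),
            class = "dp5_calibration")
}

#' Evaluate a calibration density
#' @param model A `dp5_calibration`.
#' @param p Points in `[0, 1]`.
#' @param class Which class density, `"correct"` or `"incorrect"`.
#' @return Density values (0 outside the knot range).
#' @export
calibration_density <- function(model, p, class = c("correct", "incorrect")) {
  class <- match.arg(class)
  y <- if (class == "correct") model$f_correct else model$f_incorrect
  stats::approx(model$p_grid, y, xout = p, yleft = 0, yright = 0)$y
}

#' The DP5 probability: Bayes posterior of correctness given Pn
#'
#' `P(correct | Pn) = pi f_c(Pn) / (pi f_c(Pn) + (1 - pi) f_i(Pn))` with
#' `pi` the stored prior. Where both densities vanish (numeric underflow far
#' outside the calibration support) the prior is returned.
#'
#' @param Pn Molecular probability value(s) in `[0, 1]`.
#' @param model A fitted `dp5_calibration`.
#'
#' @return Posterior probability value(s) in `[0, 1]`.
#' @export
dp5_probability <- function(Pn, model) {
  if (!inherits(model, "dp5_calibration")) {
    dp5_stop("model must be a fitted dp5_calibration", "dp5_value_error")
  }
  fc <- calibration_density(model, Pn, "correct")
  fi <- calibration_density(model, Pn, "incorrect")
  num <- model$prior_correct * fc
  den <- num + (1 - model$prior_correct) * fi
  out <- ifelse(den > 0, num / den, model$prior_correct)
  clamp(out, 0, 1)
}

#' Write a calibration model to JSON
#' @param model A `dp5_calibration`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_calibration <- function(model, path) {
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a calibration model written by [write_calibration()]
#' @param path JSON path.
#' @return A `dp5_calibration`.
#' @export
read_calibration <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (m$prior_correct <= 0 || m$prior_correct >= 1) {
    dp5_stop("stored prior outside (0, 1)", "dp5_consistency_error")
  }
  structure(m[c("p_grid", "f_correct", "f_incorrect", "prior_correct",
                "transform")], class = "dp5_calibration")
}

# ---- End-to-end pipeline ----------------------------------------------------

#' Run the full DP5 analysis for one structure and one spectrum
#'
#' Pipeline: assign calculated shifts to peaks and internally scale the
#' errors (per conformer); compute environment descriptors; form
#' similarity-weighted bespoke error densities from the reference database;
#' integrate them to atomic probabilities; Boltzmann-average over
#' conformers; combine into the molecular probability; and, if a
#' calibration model is supplied, apply the Bayes correction to obtain the
#' DP5 probability. Deterministic given inputs and configuration.
#'
#' @param molecule A `dp5_molecule` with calculated shifts on every
#'   conformer.
#' @param peaks A `dp5_peaklist`.
#' @param db A `dp5_error_db` (descriptor parameters must match the
#'   configuration in use).
#' @param model Optional fitted `dp5_calibration`; without it the result
#'   carries `dp5 = NA`.
#' @param config A `dp5_config`.
#' @param exclude_molecule Optional molecule id excluded from the database
#'   (leave-one-out evaluation).
#'
#' @return An object of class `dp5_result`: `atomic_probabilities` (one per
#'   carbon, Boltzmann-averaged), `molecular_probability`, `dp5`,
#'   `assignment` and `scaled_errors` (of the minimum-energy conformer),
#'   `conformer_weights`, and `diagnostics` (per-conformer tables).
#' @export
run_dp5 <- function(molecule, peaks, db, model = NULL, config = dp5_config(),
                    exclude_molecule = NULL) {
  params <- db$params %||% params_from_config(config)
  sigma <- resolve_sigma(db, config)
  scheme <- config$error_model$scheme
  bandwidth <- config$error_model$bandwidth
  n_conf <- length(molecule$conformers)
  cidx <- carbon_indices(molecule)
  p_table <- matrix(NA_real_, n_conf, length(cidx))
  assignments <- vector("list", n_conf)
  deltas <- vector("list", n_conf)
  energies <- vapply(molecule$conformers, `[[`, numeric(1), "relative_energy")
  for (k in seq_len(n_conf)) {
    shifts <- molecule$conformers[[k]]$shifts
    if (is.null(shifts)) {
      dp5_stop(sprintf("stage assign: conformer %d of '%s' has no calculated shifts",
                       k, molecule$molecule_id), "dp5_incomplete_error")
    }
    asg <- assign_peaks(shifts, peaks)
    delta <- scale_errors(asg, shifts)
    X <- compute_descriptor_matrix(molecule, k, params)
    ok <- which(!is.na(delta))
    if (length(ok) == 0L) {
      dp5_stop(sprintf("stage assign: no carbon of conformer %d could be assigned", k),
               "dp5_value_error")
    }
    W <- kernel_weight_matrix(X[ok, , drop = FALSE], db, sigma,
                              exclude_molecule)
    for (r in seq_along(ok)) {
      pdf <- build_atomic_pdf(W[r, ], db, bandwidth)
      p_table[k, ok[r]] <- atomic_probability(pdf, delta[ok[r]], db$eps_star,
                                              scheme)
    }
    assignments[[k]] <- asg
    deltas[[k]] <- delta
  }
  bw <- boltzmann_weights(energies, config$temperature_K)
  if (!anyNA(p_table)) {
    atomic_p <- combine_conformers(p_table, bw)
  } else {
    # atoms unassigned in some conformers: renormalise over the conformers
    # that did assign them; atoms never assigned stay NA
    atomic_p <- vapply(seq_len(ncol(p_table)), function(j) {
      col <- p_table[, j]; ok <- !is.na(col)
      if (!any(ok)) return(NA_real_)
      sum(col[ok] * bw$weights[ok]) / sum(bw$weights[ok])
    }, numeric(1))
  }
  Pn <- molecular_probability(atomic_p)
  kmin <- which.min(energies)
  structure(list(
    atomic_probabilities = atomic_p,
    molecular_probability = Pn,
    dp5 = if (is.null(model)) NA_real_ else dp5_probability(Pn, model),
    assignment = assignments[[kmin]],
    scaled_errors = as.numeric(deltas[[kmin]]),
    conformer_weights = bw,
    diagnostics = list(per_conformer_p = p_table, assignments = assignments,
                       scaled_errors = deltas, sigma = sigma,
                       scheme = scheme, eps_star = db$eps_star)),
    class = "dp5_result")
}

#' @export
print.dp5_result <- function(x, ...) {
  cat(sprintf("<dp5_result: Pn = %.4f, DP5 = %s, %d carbon(s), %d conformer(s)>\n",
              x$molecular_probability,
              if (is.na(x$dp5)) "NA (no calibration)" else sprintf("%.4f", x$dp5),
              length(x$atomic_probabilities),
              length(x$conformer_weights$weights)))
  invisible(x)
}
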