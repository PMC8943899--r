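# Reference error database, bespoke per-atom error densities (weighted KDE)
# and their integration to atomic probabilities.

#' Construct an error database
#'
#' The reference set behind every bespoke error density: one record per
#' carbon atom, holding its environment descriptor, its (internally scaled)
#' prediction error and its source molecule id (used for leave-one-out
#' exclusion). `eps_star`, the mean absolute prediction error of the
#' database, is computed here and re-checked on load.
#'
#' @param descriptors Numeric matrix, one descriptor row per record.
#' @param errors Scaled prediction errors in ppm, one per record.
#' @param molecule_ids Source molecule id per record.
#' @param params The `dp5_descriptor_params` used, or `NULL` for externally
#'   supplied representations.
#'
#' @return An object of class `dp5_error_db`.
#' @export
error_database <- function(descriptors, errors, molecule_ids, params = NULL) {
  descriptors <- as.matrix(descriptors)
  if (nrow(descriptors) < 1L) dp5_stop("empty error database", "dp5_value_error")
  if (nrow(descriptors) != length(errors) ||
      length(errors) != length(molecule_ids)) {
    dp5_stop("descriptors, errors and molecule_ids must align", "dp5_value_error")
  }
  if (any(!is.finite(errors)) || any(!is.finite(descriptors))) {
    dp5_stop("non-finite entries in error database", "dp5_value_error")
  }
  structure(list(descriptors = unname(descriptors), errors = as.numeric(errors),
                 molecule_ids = as.character(molecule_ids),
                 eps_star = mean(abs(errors)), params = params),
            class = "dp5_error_db")
}

#' @export
print.dp5_error_db <- function(x, ...) {
  cat(sprintf("<dp5_error_db: %d records from %d molecules, descriptor dim %d, eps* = %.3f ppm>\n",
              nrow(x$descriptors), length(unique(x$molecule_ids)),
              ncol(x$descriptors), x$eps_star))
  invisible(x)
}

#' Build an error database from a corpus
#'
#' For each (molecule, peak list) pair: assigns the designated conformer's
#' calculated shifts to the experimental peaks, internally scales the
#' errors, computes environment descriptors, and appends one record per
#' assigned carbon.
#'
#' @param corpus List of `list(molecule = <dp5_molecule>, peaks =
#'   <dp5_peaklist>)` entries.
#' @param params Descriptor hyperparameters shared by all records.
#' @param conformer Which conformer of each molecule to use (the reference
#'   protocol uses a single designated conformer per molecule).
#'
#' @return A `dp5_error_db`.
#' @export
build_error_database <- function(corpus, params = descriptor_params(),
                                 conformer = 1L) {
  desc <- list(); errs <- list(); ids <- list()
  for (entry in corpus) {
    mol <- entry$molecule
    shifts <- mol$conformers[[conformer]]$shifts
    if (is.null(shifts)) {
      dp5_stop(sprintf("molecule '%s' conformer %d has no calculated shifts",
                       mol$molecule_id, conformer), "dp5_incomplete_error")
    }
    asg <- assign_peaks(shifts, entry$peaks)
    delta <- scale_errors(asg, shifts)
    ok <- !is.na(delta)
    if (!any(ok)) next
    X <- compute_descriptor_matrix(mol, conformer, params)
    desc[[length(desc) + 1L]] <- X[ok, , drop = FALSE]
    errs[[length(errs) + 1L]] <- as.numeric(delta[ok])
    ids[[length(ids) + 1L]] <- rep(mol$molecule_id, sum(ok))
  }
  error_database(do.call(rbind, desc), unlist(errs), unlist(ids), params)
}

#' Write an error database to JSON
#' @param db A `dp5_error_db`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_error_database <- function(db, path) {
  payload <- list(descriptors = db$descriptors, errors_ppm = db$errors,
                  molecule_ids = db$molecule_ids, eps_star = db$eps_star,
                  params = strip_class(db$params))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

strip_class <- function(x) { if (is.list(x)) x <- lapply(x, strip_class); unclass(x) }

#' Read an error database written by [write_error_database()]
#'
#' Recomputes `eps_star` from the stored errors and refuses the file if it
#' disagrees with the stored value by more than 1e-9.
#'
#' @param path JSON path.
#' @return A `dp5_error_db`.
#' @export
read_error_database <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- NULL
  if (!is.null(payload$params) && length(payload$params) > 0L) {
    params <- do.call(descriptor_params,
                      payload$params[c("cutoff", "n_radial_bins", "width",
                                       "elements", "include_angular",
                                       "n_angular_bins")])
  }
  db <- error_database(payload$descriptors, payload$errors_ppm,
                       payload$molecule_ids, params)
  if (abs(db$eps_star - payload$eps_star) > 1e-9) {
    dp5_stop(sprintf("stored eps_star (%.12f) does not match recomputed value (%.12f)",
                     payload$eps_star, db$eps_star), "dp5_consistency_error")
  }
  db
}

# ---- Bespoke atomic error PDF ----------------------------------------------

#' Build a bespoke atomic error density by weighted KDE
#'
#' Gaussian-kernel density over the database errors with mixture weights
#' proportional to the supplied similarity weights:
#' `f(x) = sum_j w_j N(x; error_j, bandwidth^2)`, weights normalised to sum
#' to one. The `"auto"` bandwidth is Silverman's rule evaluated on the
#' weighted sample with the effective sample size `1 / sum(w_j^2)`, floored
#' at 0.1 ppm.
#'
#' @param weights Non-negative similarity weights over database records.
#' @param db A `dp5_error_db`.
#' @param bandwidth Bandwidth in ppm, or `"auto"`.
#'
#' @return An object of class `dp5_atomic_pdf` with fields `errors`,
#'   `weights` (summing to 1) and `bandwidth`.
#' @export
build_atomic_pdf <- function(weights, db, bandwidth = "auto") {
  if (length(weights) != length(db$errors)) {
    dp5_stop("weight vector does not match database size", "dp5_value_error")
  }
  if (any(weights < 0) || any(!is.finite(weights))) {
    dp5_stop("weights must be finite and non-negative", "dp5_value_error")
  }
  s <- sum(weights)
  if (s <= 0) dp5_stop("at least one weight must be positive", "dp5_value_error")
  w <- weights / s
  # prune numerically irrelevant components, then renormalise
  keep <- w > 1e-12
  w <- w[keep] / sum(w[keep])
  e <- db$errors[keep]
  if (identical(bandwidth, "auto")) {
    if (length(e) == 1L) {
      bandwidth <- 0.1
    } else {
      n_eff <- 1 / sum(w^2)
      m <- sum(w * e)
      sdev <- sqrt(sum(w * (e - m)^2))
      iqr <- diff(weighted_quantile(e, w, c(0.25, 0.75)))
      spread <- if (iqr > 0) min(sdev, iqr / 1.34) else sdev
      bandwidth <- max(0.9 * spread * n_eff^(-1/5), 0.1)
    }
  }
  if (!is.numeric(bandwidth) || bandwidth <= 0) {
    dp5_stop("bandwidth must be positive", "dp5_parameter_error")
  }
  structure(list(errors = e, weights = w, bandwidth = bandwidth),
            class = "dp5_atomic_pdf")
}

#' Evaluate an atomic error density
#' @param pdf A `dp5_atomic_pdf`.
#' @param x Points (ppm) at which to evaluate the density.
#' @return Density values.
#' @export
pdf_density <- function(pdf, x) {
  vapply(x, function(xi)
    sum(pdf$weights * stats::dnorm(xi, mean = pdf$errors, sd = pdf$bandwidth)),
    numeric(1))
}

#' Cumulative distribution of an atomic error density
#' @param pdf A `dp5_atomic_pdf`.
#' @param x Points (ppm).
#' @return CDF values.
#' @export
pdf_cdf <- function(pdf, x) {
  vapply(x, function(xi)
    sum(pdf$weights * stats::pnorm(xi, mean = pdf$errors, sd = pdf$bandwidth)),
    numeric(1))
}

#' Atomic probability of an observed prediction error
#'
#' Integrates the bespoke error density around the observed scaled error.
#' Under the default `"window"` scheme the probability is the density mass
#' within one database-wide mean absolute error (`eps_star`) of the observed
#' error, `p = F(delta + eps*) - F(delta - eps*)`: large for errors typical
#' of that environment, small for outliers. The `"two_tail"` alternative is
#' `P(|X| >= |delta|)` under the density. Both use the closed-form Gaussian
#' mixture CDF.
#'
#' @param pdf A `dp5_atomic_pdf`.
#' @param delta Observed scaled prediction error (ppm).
#' @param eps_star Mean absolute prediction error of the database (> 0).
#' @param scheme `"window"` (default) or `"two_tail"`.
#'
#' @return Probability in `[0, 1]`.
#' @export
atomic_probability <- function(pdf, delta, eps_star,
                               scheme = c("window", "two_tail")) {
  scheme <- match.arg(scheme)
  if (!is.finite(delta)) dp5_stop("non-finite error delta", "dp5_value_error")
  if (!is.numeric(eps_star) || eps_star <= 0) {
    dp5_stop("eps_star must be positive", "dp5_parameter_error")
  }
  p <- if (scheme == "window") {
    pdf_cdf(pdf, delta + eps_star) - pdf_cdf(pdf, delta - eps_star)
  } else {
    pdf_cdf(pdf, -abs(delta)) + 1 - pdf_cdf(pdf, abs(delta))
  }
  clamp(p, 0, 1)
}
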