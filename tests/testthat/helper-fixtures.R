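# Shared fixtures, built in code and memoised so expensive objects are
# constructed once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, expr, envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Small synthetic corpus + database for unit tests (large enough that a
# 5-fold calibration refit keeps >= 30 pairs per class in every training
# split).
small_gen <- function() fixture("small_gen",
  generate_corpus(synthetic_spec(n_molecules = 60, seed = 42)))

small_db <- function() fixture("small_db", build_error_database(small_gen()$corpus))

small_report <- function() fixture("small_report", {
  pairs <- make_regime_pairs(small_gen(), "case1", n_incorrect = 60, seed = 5)
  suppressWarnings(suppressMessages(
    loo_evaluate(pairs, dp5_config(), folds = 5, seed = 6)))
})

small_calibration <- function() fixture("small_calibration",
  small_report()$calibration)

# A hand-built, geometry-exact three-carbon chain (symmetric about the
# central atom) used for descriptor invariance checks; no external parser
# involved.
chain_molecule <- function(shifts = c(15, 30, 15)) {
  elements <- c("C", "C", "C", "H", "H")
  coords <- rbind(c(-1.54, 0, 0), c(0, 0, 0), c(1.54, 0, 0),
                  c(-2.1, 1.0, 0), c(2.1, 1.0, 0))
  bonds <- rbind(c(1, 2, 1), c(2, 3, 1), c(1, 4, 1), c(3, 5, 1))
  new_molecule("chain3", elements, bonds,
               list(list(coords = coords, relative_energy = 0,
                         shifts = shifts)))
}

rotate_z90 <- function(coords) {
  R <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  coords %*% t(R)
}

# Brute-force minimum-cost assignment over all injections of the smaller
# side into the larger (independent oracle for assign_peaks).
brute_force_assignment_cost <- function(shifts, peaks) {
  na <- length(shifts); np <- length(peaks)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  best <- Inf
  if (na <= np) {
    for (sel in utils::combn(np, na, simplify = FALSE)) {
      for (p in perms(sel)) {
        best <- min(best, sum(abs(shifts - peaks[p])))
      }
    }
  } else {
    for (sel in utils::combn(na, np, simplify = FALSE)) {
      for (p in perms(sel)) {
        best <- min(best, sum(abs(shifts[p] - peaks)))
      }
    }
  }
  best
}

# Numerical quadrature of an atomic error density over an interval
# (independent oracle for atomic_probability).
quadrature_mass <- function(pdf, lo, hi) {
  stats::integrate(function(x) pdf_density(pdf, x), lo, hi,
                   subdivisions = 2000L, rel.tol = 1e-10,
                   abs.tol = 1e-10)$value
}

# Fabricated minimal result object for annotation I/O tests.
fake_result <- function(p, mapping = NULL, errors = NULL) {
  structure(list(atomic_probabilities = p,
                 molecular_probability = mean(p),
                 dp5 = NA_real_,
                 assignment = structure(list(mapping = mapping %||% seq_along(p) * 10,
                                             peak_index = seq_along(p),
                                             unassigned_atoms = integer(0),
                                             cost = 0),
                                        class = "dp5_assignment"),
                 scaled_errors = errors %||% rep(0, length(p))),
            class = "dp5_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
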