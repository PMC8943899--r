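# Atomic environment descriptors and Gaussian-kernel similarity.
#
# The descriptor is a per-element-channel, Gaussian-smeared radial
# distribution histogram around a central carbon, with each neighbour's
# contribution damped by r^-decay_power so that the bonded first shell --
# the part of the environment that chiefly determines the prediction-error
# law -- dominates the vector, as in physics-inspired two-body
# representations. Optionally a smeared histogram of the angles subtended
# at the centre by pairs of neighbours is concatenated. The descriptor
# depends only on interatomic distances/angles within the cutoff and on
# neighbour elements, so it is invariant to translation, rotation and
# neighbour permutation. An externally computed representation (e.g. an
# FCHL vector) can be supplied instead via `error_database()`'s
# direct-matrix interface.

#' Descriptor hyperparameters
#'
#' @param cutoff Radial cutoff in Angstrom (> 0).
#' @param n_radial_bins Number of radial bins (>= 1).
#' @param width Gaussian smearing width in Angstrom (> 0).
#' @param elements Ordered element channels; neighbours of other elements
#'   are ignored.
#' @param decay_power Radial damping exponent: a neighbour at distance d
#'   contributes with weight `d^-decay_power`, concentrating the descriptor
#'   on the bonded first shell (0 disables damping).
#' @param include_angular Concatenate the angular histogram?
#' @param n_angular_bins Number of angular bins over `[0, pi]`.
#'
#' @return An object of class `dp5_descriptor_params` carrying a
#'   `params_hash` used to refuse comparisons between incompatible
#'   descriptors.
#' @export
descriptor_params <- function(cutoff = 5.0, n_radial_bins = 24L, width = 0.5,
                              elements = c("C", "H", "O", "N"),
                              decay_power = 4,
                              include_angular = FALSE, n_angular_bins = 12L) {
  if (cutoff <= 0 || width <= 0) {
    dp5_stop("descriptor cutoff and width must be > 0", "dp5_parameter_error")
  }
  if (n_radial_bins < 1L || n_angular_bins < 1L) {
    dp5_stop("descriptor bin counts must be >= 1", "dp5_parameter_error")
  }
  if (decay_power < 0) {
    dp5_stop("decay_power must be >= 0", "dp5_parameter_error")
  }
  p <- list(cutoff = cutoff, n_radial_bins = as.integer(n_radial_bins),
            width = width, elements = elements, decay_power = decay_power,
            include_angular = isTRUE(include_angular),
            n_angular_bins = as.integer(n_angular_bins))
  p$params_hash <- paste(c(format(c(cutoff, width, decay_power), digits = 15),
                           n_radial_bins, elements,
                           p$include_angular, n_angular_bins), collapse = "|")
  class(p) <- "dp5_descriptor_params"
  p
}

descriptor_length <- function(params) {
  params$n_radial_bins * length(params$elements) +
    if (params$include_angular) params$n_angular_bins else 0L
}

#' Compute the environment descriptor of one carbon atom
#'
#' @param molecule A `dp5_molecule`.
#' @param conformer_index Which conformer's geometry to use.
#' @param atom_index 1-based atom index; must be a carbon.
#' @param params A `dp5_descriptor_params`.
#'
#' @return An object of class `dp5_descriptor` with fields `vector`,
#'   `element` and `params_hash`.
#' @export
compute_descriptor <- function(molecule, conformer_index, atom_index,
                               params = descriptor_params()) {
  n <- length(molecule$elements)
  if (atom_index < 1L || atom_index > n) {
    dp5_stop(sprintf("atom index %d out of range 1..%d", atom_index, n),
             "dp5_index_error")
  }
  if (molecule$elements[atom_index] != "C") {
    dp5_stop(sprintf("atom %d is %s; descriptors are computed for carbon centres only",
                     atom_index, molecule$elements[atom_index]),
             "dp5_domain_error")
  }
  coords <- molecule$conformers[[conformer_index]]$coords
  v <- descriptor_vector(coords, molecule$elements, atom_index, params)
  structure(list(vector = v, element = "C", params_hash = params$params_hash),
            class = "dp5_descriptor")
}

descriptor_vector <- function(coords, elements, centre, params) {
  rel <- sweep(coords, 2, coords[centre, ])
  d <- sqrt(rowSums(rel^2))
  nb <- which(d <= params$cutoff & seq_along(d) != centre &
                elements %in% params$elements)
  centres_r <- (seq_len(params$n_radial_bins) - 0.5) *
    params$cutoff / params$n_radial_bins
  v <- numeric(descriptor_length(params))
  # damping distance floored at covalent-contact range so pathological
  # close contacts in user-supplied geometries cannot blow up the vector
  damp <- if (params$decay_power > 0) {
    pmax(d, 0.9)^(-params$decay_power)
  } else {
    rep(1, length(d))
  }
  for (ci in seq_along(params$elements)) {
    jj <- nb[elements[nb] == params$elements[ci]]
    if (length(jj) > 0L) {
      contrib <- outer(centres_r, d[jj],
                       function(r, dj) exp(-(r - dj)^2 / (2 * params$width^2)))
      v[(ci - 1L) * params$n_radial_bins + seq_len(params$n_radial_bins)] <-
        as.numeric(contrib %*% damp[jj])
    }
  }
  if (params$include_angular && length(nb) >= 2L) {
    u <- rel[nb, , drop = FALSE] / d[nb]
    cosang <- clamp(tcrossprod(u), -1, 1)
    ang <- acos(cosang[upper.tri(cosang)])
    centres_a <- (seq_len(params$n_angular_bins) - 0.5) * pi / params$n_angular_bins
    wa <- pi / params$n_angular_bins
    av <- rowSums(outer(centres_a, ang,
                        function(a, t) exp(-(a - t)^2 / (2 * wa^2))))
    v[params$n_radial_bins * length(params$elements) +
        seq_len(params$n_angular_bins)] <- av
  }
  v
}

#' Descriptor matrix for all carbons of one conformer
#'
#' @inheritParams compute_descriptor
#' @return Matrix with one row per carbon (ascending atom index).
#' @export
compute_descriptor_matrix <- function(molecule, conformer_index = 1L,
                                      params = descriptor_params()) {
  cidx <- carbon_indices(molecule)
  coords <- molecule$conformers[[conformer_index]]$coords
  t(vapply(cidx, function(i) descriptor_vector(coords, molecule$elements, i, params),
           numeric(descriptor_length(params))))
}

#' Euclidean distance between two environment descriptors
#'
#' @param a,b `dp5_descriptor` objects built with the same parameters.
#' @return Non-negative l2 distance.
#' @export
descriptor_distance <- function(a, b) {
  if (!identical(a$params_hash, b$params_hash)) {
    dp5_stop("descriptors built with different parameters are not comparable",
             "dp5_incompatibility_error")
  }
  sqrt(sum((a$vector - b$vector)^2))
}

#' Gaussian kernel similarity
#'
#' `exp(-d^2 / (2 sigma^2))` with the pre-exponential factor fixed at one,
#' so the kernel value at distance zero is exactly 1 and values can be read
#' as similarities in `(0, 1]`.
#'
#' @param distance Non-negative distance(s).
#' @param sigma Kernel length scale (> 0).
#' @return Similarity value(s) in `(0, 1]`.
#' @export
gaussian_kernel <- function(distance, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    dp5_stop("kernel sigma must be a single positive number", "dp5_parameter_error")
  }
  if (any(!is.finite(distance))) {
    dp5_stop("non-finite distance passed to gaussian_kernel", "dp5_value_error")
  }
  exp(-distance^2 / (2 * sigma^2))
}

#' Kernel length scale by the pairwise-distance quantile heuristic
#'
#' A quantile of the pairwise descriptor distances over a deterministic
#' stride subsample of at most `max_points` database records. The default
#' quantile 0.1 is deliberately below the median: environment descriptors
#' form groups of comparable environments, so the pairwise-distance
#' distribution is multimodal (similar environments close, dissimilar far)
#' and the median is inflated by the between-group modes; a length scale
#' set there makes every environment look similar to every other and
#' washes out the environment-conditioned weighting that is the point of
#' the method. The low quantile tracks the within-group mode, so
#' similarity weights localise on genuinely comparable environments while
#' keeping the effective sample size of the weighted KDE large.
#' `quantile = 0.5` recovers the plain median heuristic.
#'
#' @param db A `dp5_error_db`.
#' @param quantile Which pairwise-distance quantile to use.
#' @param max_points Subsample ceiling.
#' @return Positive sigma.
#' @export
kernel_sigma_auto <- function(db, quantile = 0.1, max_points = 400L) {
  X <- db$descriptors
  idx <- unique(round(seq(1, nrow(X), length.out = min(max_points, nrow(X)))))
  d <- as.numeric(stats::dist(X[idx, , drop = FALSE]))
  d <- d[d > 0]
  if (length(d) == 0L) return(1.0)
  as.numeric(stats::quantile(d, quantile))
}

params_from_config <- function(config) {
  descriptor_params(
    cutoff = config$descriptor$cutoff,
    n_radial_bins = config$descriptor$n_radial_bins,
    width = config$descriptor$width,
    elements = config$descriptor$elements,
    decay_power = config$descriptor$decay_power %||% 4,
    include_angular = config$descriptor$angular,
    n_angular_bins = config$descriptor$n_angular_bins)
}

resolve_sigma <- function(db, config) {
  s <- config$kernel$sigma
  if (identical(s, "auto")) {
    kernel_sigma_auto(db, quantile = config$kernel$sigma_quantile %||% 0.1)
  } else {
    if (!is.numeric(s) || s <= 0) {
      dp5_stop("kernel.sigma must be 'auto' or a positive number",
               "dp5_parameter_error")
    }
    s
  }
}

#' Similarity weights of a test environment against a database
#'
#' @param test A `dp5_descriptor` or a bare numeric vector of the database's
#'   descriptor dimension.
#' @param db A `dp5_error_db`.
#' @param sigma Kernel length scale.
#' @param exclude_molecule Optional molecule id whose records get weight
#'   exactly 0 (leave-one-out).
#'
#' @return Non-negative weight vector over database records with at least
#'   one strictly positive entry.
#' @export
kernel_weights <- function(test, db, sigma, exclude_molecule = NULL) {
  if (inherits(test, "dp5_descriptor")) {
    if (!is.null(db$params) &&
        !identical(test$params_hash, db$params$params_hash)) {
      dp5_stop("test descriptor and database use different descriptor parameters",
               "dp5_incompatibility_error")
    }
    test <- test$vector
  }
  W <- kernel_weight_matrix(matrix(test, nrow = 1), db, sigma, exclude_molecule)
  as.numeric(W[1, ])
}

# Rows of `test` are descriptor vectors; returns an m x N weight matrix.
kernel_weight_matrix <- function(test, db, sigma, exclude_molecule = NULL) {
  X <- db$descriptors
  if (ncol(test) != ncol(X)) {
    dp5_stop("descriptor dimension mismatch with database", "dp5_incompatibility_error")
  }
  keep <- rep(TRUE, nrow(X))
  if (!is.null(exclude_molecule)) keep <- !(db$molecule_ids %in% exclude_molecule)
  if (!any(keep)) {
    dp5_stop("no database records left after leave-one-out exclusion",
             "dp5_value_error")
  }
  d2 <- outer(rowSums(test^2), rep(1, nrow(X))) +
    outer(rep(1, nrow(test)), rowSums(X^2)) - 2 * tcrossprod(test, X)
  d2 <- pmax(d2, 0)
  # snap rounding noise of the expansion to zero so identical environments
  # get self-similarity exactly 1
  thr <- 1e-12 * (max(rowSums(test^2)) + max(rowSums(X^2)) + 1)
  d2[d2 < thr] <- 0
  W <- exp(-d2 / (2 * sigma^2))
  W[, !keep] <- 0
  if (any(rowSums(W) == 0)) {
    dp5_stop("all kernel weights underflowed to zero; increase kernel.sigma",
             "dp5_degenerate_kernel_error")
  }
  W
}
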