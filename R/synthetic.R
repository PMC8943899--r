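# Synthetic corpora: randomly grown 3D molecules whose carbons belong to
# latent environment clusters with cluster-specific, heavy-tailed
# (Student-t) prediction-error laws. Every stage of the pipeline and the
# full benchmark can run on these corpora with no external data.

#' Specification of a synthetic corpus
#'
#' Defaults are the package's reference study conditions: three environment
#' clusters whose error laws differ in location and spread, Student-t tails
#' (df 5) because wide-tailed laws are required to describe DFT-NMR
#' prediction errors, and a corpus-wide mean absolute error of about
#' 1.5-2 ppm for correct pairings. The cluster error locations (+1.5, -1.5,
#' 0 ppm) emulate systematic environment-specific prediction biases; they
#' are deliberately non-monotone in the cluster baseline shifts so that the
#' per-molecule linear scaling cannot absorb them -- this is what makes a
#' small error in the wrong environment improbable, and a larger error in a
#' biased environment expected.
#'
#' @param n_molecules Number of molecules.
#' @param carbons_range Inclusive range of carbons per molecule.
#' @param n_hetero_range Inclusive range of O/N heteroatoms per molecule.
#' @param n_clusters Number of latent environment clusters.
#' @param cluster_shift_ppm Baseline calculated 13C shift per cluster (ppm).
#' @param cluster_error_location Error-law location per cluster (ppm).
#' @param cluster_error_scale Error-law scale per cluster (ppm, > 0).
#' @param error_df Student-t degrees of freedom (> 2).
#' @param shift_noise_ppm SD of within-cluster shift variation (ppm).
#' @param incorrect_inflation Multiplier applied to the whole error draw
#'   when generating an incorrect spectrum (1 = same law as correct pairs).
#' @param seed RNG seed recorded in every output.
#'
#' @return An object of class `dp5_synthetic_spec`.
#' @export
synthetic_spec <- function(n_molecules = 50L, carbons_range = c(5L, 9L),
                           n_hetero_range = c(0L, 2L), n_clusters = 3L,
                           cluster_shift_ppm = c(25, 75, 135),
                           cluster_error_location = c(1.5, -1.5, 0),
                           cluster_error_scale = c(0.8, 1.5, 3.0),
                           error_df = 5, shift_noise_ppm = 6,
                           incorrect_inflation = 3.0, seed = 1L) {
  if (any(cluster_error_scale <= 0)) {
    dp5_stop("cluster error scales must be > 0", "dp5_parameter_error")
  }
  if (error_df <= 2) dp5_stop("error_df must be > 2", "dp5_parameter_error")
  if (length(cluster_shift_ppm) != n_clusters ||
      length(cluster_error_location) != n_clusters ||
      length(cluster_error_scale) != n_clusters) {
    dp5_stop("per-cluster parameter vectors must have length n_clusters",
             "dp5_parameter_error")
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 carbons_range = as.integer(carbons_range),
                 n_hetero_range = as.integer(n_hetero_range),
                 n_clusters = as.integer(n_clusters),
                 cluster_shift_ppm = cluster_shift_ppm,
                 cluster_error_location = cluster_error_location,
                 cluster_error_scale = cluster_error_scale,
                 error_df = error_df, shift_noise_ppm = shift_noise_ppm,
                 incorrect_inflation = incorrect_inflation,
                 seed = as.integer(seed)),
            class = "dp5_synthetic_spec")
}

element_valence <- c(C = 4L, N = 3L, O = 2L, H = 1L)
bond_length <- function(e1, e2) {
  if (e1 == "H" || e2 == "H") return(1.09)
  if ("O" %in% c(e1, e2)) return(1.43)
  if ("N" %in% c(e1, e2)) return(1.47)
  1.54
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# sample() treats a length-1 vector as 1:n; draw from a closed range safely
sample_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)

# Grow a random acyclic molecule: heavy-atom tree with clash-avoiding
# geometry, remaining valence filled with explicit hydrogens.
grow_molecule <- function(n_carbons, n_hetero, molecule_id) {
  heavy <- c(rep("C", n_carbons),
             if (n_hetero > 0) sample(c("O", "N"), n_hetero, replace = TRUE))
  heavy <- sample(heavy)
  nh <- length(heavy)
  coords <- matrix(0, nh, 3)
  bonds <- matrix(integer(0), 0, 3)
  deg <- integer(nh)
  for (k in seq_len(nh)[-1]) {
    open <- which(deg[seq_len(k - 1L)] < element_valence[heavy[seq_len(k - 1L)]])
    if (length(open) == 0L) {
      dp5_stop("infeasible valence while growing synthetic molecule",
               "dp5_generation_error")
    }
    parent <- if (length(open) == 1L) open else sample(open, 1L)
    L <- bond_length(heavy[parent], heavy[k])
    placed <- FALSE
    for (try in 1:80) {
      pos <- coords[parent, ] + L * random_unit_vector()
      others <- setdiff(seq_len(k - 1L), parent)
      if (length(others) == 0L ||
          min(sqrt(rowSums(sweep(coords[others, , drop = FALSE], 2, pos)^2))) >= 1.8) {
        placed <- TRUE; break
      }
    }
    if (!placed) {
      dp5_stop("could not place atom without steric clash after bounded retries",
               "dp5_generation_error")
    }
    coords[k, ] <- pos
    bonds <- rbind(bonds, c(parent, k, 1L))
    deg[parent] <- deg[parent] + 1L
    deg[k] <- deg[k] + 1L
  }
  # hydrogens on remaining valence
  elements <- heavy
  for (a in seq_len(nh)) {
    nfree <- element_valence[heavy[a]] - deg[a]
    for (h in seq_len(max(0L, nfree))) {
      placed <- FALSE
      for (try in 1:60) {
        pos <- coords[a, ] + 1.09 * random_unit_vector()
        d <- sqrt(rowSums(sweep(coords, 2, pos)^2))
        d[a] <- Inf
        if (min(d) >= 1.4) { placed <- TRUE; break }
      }
      if (!placed) {
        dp5_stop("could not place hydrogen without steric clash after bounded retries",
                 "dp5_generation_error")
      }
      coords <- rbind(coords, pos)
      elements <- c(elements, "H")
      bonds <- rbind(bonds, c(a, length(elements), 1L))
    }
  }
  list(elements = elements, coords = unname(coords), bonds = bonds,
       heavy_deg = deg)
}

# Latent environment cluster of each carbon: a deterministic function of
# the local bonding pattern (heavy-neighbour count and heteroatom
# neighbours), so the geometric descriptor carries the cluster signal.
carbon_clusters <- function(elements, bonds, n_clusters) {
  cidx <- which(elements == "C")
  vapply(cidx, function(a) {
    nb <- c(bonds[bonds[, 1] == a, 2], bonds[bonds[, 2] == a, 1])
    nb_el <- elements[nb]
    heavy_deg <- sum(nb_el != "H")
    het <- sum(nb_el %in% c("O", "N"))
    ((heavy_deg + 2L * het - 1L) %% n_clusters) + 1L
  }, integer(1))
}

draw_errors <- function(clusters, spec, inflation = 1.0) {
  loc <- spec$cluster_error_location[clusters]
  sc <- spec$cluster_error_scale[clusters]
  inflation * (loc + sc * stats::rt(length(clusters), df = spec$error_df))
}

#' Generate a synthetic corpus
#'
#' Each molecule is a randomly grown acyclic C/H/O/N structure with one
#' embedded conformer. Every carbon belongs to a latent cluster determined
#' by its bonding pattern; its calculated shift is the cluster baseline plus
#' noise, and its experimental peak is the calculated shift minus an error
#' drawn from the cluster's Student-t law. Deterministic given the spec's
#' seed.
#'
#' @param spec A `dp5_synthetic_spec`.
#'
#' @return An object of class `dp5_synthetic_corpus`: `corpus` (list of
#'   `list(molecule, peaks)`), `truth` (data frame of molecule id, atom
#'   index, cluster, drawn error, calculated shift) and `spec`.
#' @export
generate_corpus <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  corpus <- vector("list", spec$n_molecules)
  truth <- vector("list", spec$n_molecules)
  for (i in seq_len(spec$n_molecules)) {
    id <- sprintf("syn%04d", i)
    nc <- sample_range(spec$carbons_range)
    nh <- sample_range(spec$n_hetero_range)
    g <- NULL
    for (attempt in 1:20) {
      g <- tryCatch(grow_molecule(nc, nh, id), dp5_generation_error = function(e) NULL)
      if (!is.null(g)) break
    }
    if (is.null(g)) {
      dp5_stop(sprintf("failed to grow synthetic molecule %s", id),
               "dp5_generation_error")
    }
    clusters <- carbon_clusters(g$elements, g$bonds, spec$n_clusters)
    calc <- spec$cluster_shift_ppm[clusters] +
      stats::rnorm(length(clusters), 0, spec$shift_noise_ppm)
    err <- draw_errors(clusters, spec, inflation = 1.0)
    mol <- new_molecule(id, g$elements, g$bonds,
                        list(list(coords = g$coords, relative_energy = 0,
                                  shifts = calc)),
                        provenance = sprintf("synthetic(seed=%d)", spec$seed))
    corpus[[i]] <- list(molecule = mol, peaks = peak_list(calc - err))
    truth[[i]] <- data.frame(molecule_id = id,
                             atom_index = which(g$elements == "C"),
                             cluster = clusters, error = err,
                             calc_shift = calc)
  }
  structure(list(corpus = corpus, truth = do.call(rbind, truth), spec = spec),
            class = "dp5_synthetic_corpus")
}

#' Generate an incorrect spectrum for a molecule
#'
#' Emulates pairing the structure with the spectrum of a different molecule:
#' peaks are the molecule's calculated shifts minus errors drawn from
#' randomly chosen clusters (so the error magnitudes no longer match the
#' atoms' environments), scaled by the inflation factor. `inflation = 1`
#' yields incorrect pairs statistically indistinguishable from correct
#' pairs by their MAE (the hard, case-2-like regime); larger factors give
#' grossly wrong spectra (the case-1-like regime).
#'
#' @param molecule A molecule from a generated corpus.
#' @param spec The corpus's `dp5_synthetic_spec`.
#' @param inflation Error inflation factor; defaults to
#'   `spec$incorrect_inflation`.
#' @param cluster_pool Pool of cluster labels to resample environment
#'   mismatches from (defaults to the corpus occupancy if given, else
#'   uniform over clusters).
#'
#' @return A `dp5_peaklist` with attributes `errors` and `clusters`.
#' @export
generate_incorrect_spectrum <- function(molecule, spec,
                                        inflation = spec$incorrect_inflation,
                                        cluster_pool = NULL) {
  calc <- molecule$conformers[[1]]$shifts
  if (is.null(calc)) {
    dp5_stop("molecule has no calculated shifts", "dp5_incomplete_error")
  }
  nc <- length(calc)
  pool <- cluster_pool %||% seq_len(spec$n_clusters)
  clusters <- pool[sample.int(length(pool), nc, replace = TRUE)]
  err <- draw_errors(clusters, spec, inflation = inflation)
  pk <- peak_list(calc - err)
  attr(pk, "errors") <- err
  attr(pk, "clusters") <- clusters
  pk
}

#' Direct-vector synthetic error database
#'
#' Bypasses geometry: descriptor-space Gaussian clusters with
#' cluster-specific error SDs. Used to test the environment-conditioning
#' behaviour of the weighted KDE in isolation.
#'
#' @param n_records Total records.
#' @param cluster_error_sd Per-cluster error SD in ppm (length = number of
#'   clusters).
#' @param dim Descriptor dimension.
#' @param cluster_sep Distance of each cluster centre from the origin along
#'   its own axis.
#' @param descriptor_noise SD of descriptor scatter around the centre.
#' @param seed RNG seed.
#'
#' @return A list with `db` (a `dp5_error_db`), `clusters` (record labels)
#'   and `centers` (cluster centre matrix).
#' @export
synthetic_error_db <- function(n_records = 2000L, cluster_error_sd = c(1, 5),
                               dim = 8L, cluster_sep = 4,
                               descriptor_noise = 0.2, seed = 1L) {
  set.seed(seed)
  k <- length(cluster_error_sd)
  stopifnot(dim >= k)
  centers <- matrix(0, k, dim)
  for (j in seq_len(k)) centers[j, j] <- cluster_sep
  clusters <- rep(seq_len(k), length.out = n_records)
  X <- centers[clusters, , drop = FALSE] +
    matrix(stats::rnorm(n_records * dim, 0, descriptor_noise), n_records, dim)
  errors <- stats::rnorm(n_records, 0, cluster_error_sd[clusters])
  db <- error_database(X, errors,
                       molecule_ids = sprintf("synrec%05d", seq_len(n_records)))
  list(db = db, clusters = clusters, centers = centers)
}
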