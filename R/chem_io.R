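# Structure, shift-table, peak-list and annotation I/O.
#
# SDF (V2000) reading/writing goes through ChemmineR; SMILES and InChI are
# converted (with explicit hydrogens and one embedded 3D conformer) through
# ChemmineOB/OpenBabel. Atom indices are 1-based throughout the package and
# in every CSV interface; SDF files are natively 1-based so no translation
# is needed at that boundary.

#' Construct a molecule object
#'
#' Low-level constructor used by the readers and the synthetic generator.
#'
#' @param molecule_id Identifier string.
#' @param elements Character vector of element symbols, one per atom.
#' @param bonds Integer matrix with columns `i`, `j`, `order` (1-based atom
#'   indices).
#' @param conformers List of conformers; each a list with `coords` (n x 3
#'   matrix, Angstrom), `relative_energy` (kJ/mol) and optionally `shifts`
#'   (numeric, one calculated 13C shift in ppm per carbon, in ascending atom
#'   index order).
#' @param provenance Free-text source description (SMILES string, file path).
#'
#' @return An object of class `dp5_molecule`.
#' @export
new_molecule <- function(molecule_id, elements, bonds, conformers,
                         provenance = "") {
  n <- length(elements)
  if (n < 1L) dp5_stop("molecule has no atoms", "dp5_domain_error")
  if (!any(elements == "C")) {
    dp5_stop(sprintf("molecule '%s' contains no carbon atoms; 13C analysis impossible",
                     molecule_id), "dp5_domain_error")
  }
  if (length(conformers) < 1L) {
    dp5_stop("molecule must carry at least one conformer", "dp5_domain_error")
  }
  bonds <- as.matrix(bonds)
  if (nrow(bonds) > 0L) {
    if (ncol(bonds) < 3L) dp5_stop("bonds need columns i, j, order", "dp5_format_error")
    if (any(bonds[, 1:2] < 1L | bonds[, 1:2] > n)) {
      dp5_stop("bond endpoint outside atom range", "dp5_domain_error")
    }
  }
  colnames(bonds) <- c("i", "j", "order")[seq_len(max(3L, ncol(bonds)))][1:3]
  nc <- sum(elements == "C")
  for (k in seq_along(conformers)) {
    cf <- conformers[[k]]
    cf$coords <- as.matrix(cf$coords)
    if (nrow(cf$coords) != n || ncol(cf$coords) != 3L) {
      dp5_stop(sprintf("conformer %d coordinate block is %d x %d, expected %d x 3",
                       k, nrow(cf$coords), ncol(cf$coords), n), "dp5_domain_error")
    }
    cf$relative_energy <- cf$relative_energy %||% 0
    if (!is.null(cf$shifts) && length(cf$shifts) != nc) {
      dp5_stop(sprintf("conformer %d carries %d shifts for %d carbons",
                       k, length(cf$shifts), nc), "dp5_incomplete_error")
    }
    conformers[[k]] <- cf
  }
  structure(list(molecule_id = molecule_id, elements = elements,
                 bonds = bonds, conformers = conformers,
                 provenance = provenance),
            class = "dp5_molecule")
}

#' Indices of the carbon atoms of a molecule
#' @param molecule A `dp5_molecule`.
#' @return Integer vector of 1-based atom indices.
#' @export
carbon_indices <- function(molecule) which(molecule$elements == "C")

#' @export
print.dp5_molecule <- function(x, ...) {
  cat(sprintf("<dp5_molecule '%s': %d atoms (%d C), %d bonds, %d conformer(s)>\n",
              x$molecule_id, length(x$elements), sum(x$elements == "C"),
              nrow(x$bonds), length(x$conformers)))
  invisible(x)
}

#' Read a candidate structure
#'
#' Reads an SDF (V2000) file, a SMILES string, or an InChI string into a
#' molecule object. SMILES/InChI inputs have hydrogens added and a single 3D
#' conformer embedded deterministically (OpenBabel `gen3d`); multi-record SDF
#' files are interpreted as conformers of one molecule and must share the
#' atom ordering and bond list. Calculated shifts and conformer energies are
#' picked up from `DP5_SHIFTS_<k>` / `DP5_SHIFTS` and `DP5_ENERGY_KJMOL`
#' property tags when present.
#'
#' @param source File path (sdf) or structure string (smiles, inchi).
#' @param format One of `"sdf"`, `"smiles"`, `"inchi"`.
#' @param molecule_id Optional identifier; defaults to the SDF title or the
#'   input string.
#'
#' @return A `dp5_molecule`.
#' @export
#'
#' @examples
#' mol <- read_structure("CCO", format = "smiles")
#' length(carbon_indices(mol))
read_structure <- function(source, format = c("sdf", "smiles", "inchi"),
                           molecule_id = NULL) {
  format <- match.arg(format)
  if (format %in% c("smiles", "inchi")) {
    string <- source
    if (length(string) == 1L && file.exists(string)) {
      string <- trimws(readLines(string, warn = FALSE)[1])
    }
    ob_format <- if (format == "smiles") "SMI" else "INCHI"
    sdf_text <- tryCatch(
      ChemmineOB::convertFormat(
        ob_format, "SDF", string,
        options = data.frame(names = c("gen3d", "h"), args = c("", ""))),
      error = function(e) dp5_stop(
        sprintf("could not parse %s input '%s': %s", format, string,
                conditionMessage(e)), "dp5_format_error"))
    if (!nzchar(gsub("\\s", "", sdf_text %||% ""))) {
      dp5_stop(sprintf("could not parse %s input '%s'", format, string),
               "dp5_format_error")
    }
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(sdf_text, tmp)
    mol <- read_structure(tmp, format = "sdf",
                          molecule_id = molecule_id %||% string)
    mol$provenance <- paste0(format, ":", string, " (3D embedded, deterministic gen3d)")
    return(mol)
  }

  sdfset <- tryCatch(ChemmineR::read.SDFset(source),
                     error = function(e) dp5_stop(
                       sprintf("failed to read SDF '%s': %s", source,
                               conditionMessage(e)), "dp5_format_error"))
  if (length(sdfset) < 1L) {
    dp5_stop(sprintf("no records in SDF '%s'", source), "dp5_format_error")
  }
  if (!all(ChemmineR::validSDF(sdfset))) {
    bad <- which(!ChemmineR::validSDF(sdfset))
    dp5_stop(sprintf("invalid SDF record(s) %s in '%s'",
                     paste(bad, collapse = ", "), source), "dp5_format_error")
  }
  recs <- lapply(seq_along(sdfset), function(k) sdfset[[k]])
  elem_of <- function(sdf) sub("_\\d+$", "", rownames(ChemmineR::atomblock(sdf)))
  elements <- elem_of(recs[[1]])
  bond_of <- function(sdf) {
    bb <- ChemmineR::bondblock(sdf)
    if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1)
    m <- matrix(as.integer(as.matrix(bb[, 1:3, drop = FALSE])), ncol = 3)
    colnames(m) <- c("i", "j", "order")
    m
  }
  bonds <- bond_of(recs[[1]])
  nc <- sum(elements == "C")
  conformers <- vector("list", length(recs))
  energies <- numeric(length(recs))
  have_energy <- FALSE
  for (k in seq_along(recs)) {
    if (!identical(elem_of(recs[[k]]), elements) ||
        !identical(bond_of(recs[[k]]), bonds)) {
      dp5_stop(sprintf(
        "record %d of '%s' does not share the atom ordering/bonds of record 1; multi-record files must be conformer blocks of one molecule",
        k, source), "dp5_format_error")
    }
    ab <- ChemmineR::atomblock(recs[[k]])
    coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
    db <- ChemmineR::datablock(recs[[k]])
    shifts <- NULL
    for (tag in c("DP5_SHIFTS", paste0("DP5_SHIFTS_", k))) {
      if (tag %in% names(db)) {
        shifts <- as.numeric(strsplit(trimws(db[[tag]]), "\\s+")[[1]])
        if (anyNA(shifts) || length(shifts) != nc) {
          dp5_stop(sprintf("tag %s of record %d has %d values for %d carbons",
                           tag, k, length(shifts), nc), "dp5_incomplete_error")
        }
      }
    }
    if ("DP5_ENERGY_KJMOL" %in% names(db)) {
      energies[k] <- as.numeric(db[["DP5_ENERGY_KJMOL"]])
      have_energy <- TRUE
    }
    conformers[[k]] <- list(coords = coords, relative_energy = 0,
                            shifts = shifts)
  }
  if (have_energy) {
    energies <- energies - min(energies)
    for (k in seq_along(conformers)) conformers[[k]]$relative_energy <- energies[k]
  }
  id <- molecule_id %||% ChemmineR::header(recs[[1]])[["Molecule_Name"]]
  if (is.null(id) || !nzchar(id)) id <- basename(source)
  new_molecule(id, elements, bonds, conformers, provenance = source)
}

#' Read a calculated shift table into a molecule
#'
#' CSV columns: `conformer_id` (1-based), `atom_index` (1-based, must be a
#' carbon), `shift_ppm`, and optionally `energy_kjmol` (one value per
#' conformer, repeated or given on any row of that conformer). Every carbon
#' of every conformer must receive exactly one shift. Energies are shifted so
#' the minimum is zero.
#'
#' @param path CSV file path.
#' @param molecule A `dp5_molecule` whose conformers the table populates; the
#'   number of distinct `conformer_id`s must equal the conformer count.
#' @param units Energy units in the file: `"kJ/mol"` (default), `"kcal/mol"`
#'   or `"hartree"`; converted to kJ/mol on read.
#'
#' @return The molecule with `shifts` and `relative_energy` populated.
#' @export
read_shift_table <- function(path, molecule, units = c("kJ/mol", "kcal/mol", "hartree")) {
  units <- match.arg(units)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("conformer_id", "atom_index", "shift_ppm")
  if (!all(need %in% names(tab))) {
    dp5_stop(sprintf("shift table '%s' must have columns %s", path,
                     paste(need, collapse = ", ")), "dp5_format_error")
  }
  cidx <- carbon_indices(molecule)
  if (any(!tab$atom_index %in% cidx)) {
    bad <- setdiff(unique(tab$atom_index), cidx)
    dp5_stop(sprintf("shift table references non-carbon or unknown atom index(es): %s",
                     paste(bad, collapse = ", ")), "dp5_index_error")
  }
  conf_ids <- sort(unique(tab$conformer_id))
  if (!identical(as.integer(conf_ids), seq_along(molecule$conformers))) {
    dp5_stop(sprintf("shift table conformer ids (%s) do not match the molecule's %d conformer(s)",
                     paste(conf_ids, collapse = ", "),
                     length(molecule$conformers)), "dp5_index_error")
  }
  if (anyDuplicated(tab[, c("conformer_id", "atom_index")])) {
    dp5_stop("duplicate (conformer_id, atom_index) rows in shift table",
             "dp5_format_error")
  }
  scale <- switch(units, "kJ/mol" = 1, "kcal/mol" = 4.184, "hartree" = 2625.4996)
  energies <- numeric(length(conf_ids))
  for (k in conf_ids) {
    rows <- tab[tab$conformer_id == k, ]
    missing <- setdiff(cidx, rows$atom_index)
    if (length(missing) > 0L) {
      dp5_stop(sprintf("conformer %d is missing shifts for carbon atom(s): %s",
                       k, paste(missing, collapse = ", ")),
               "dp5_incomplete_error")
    }
    ord <- match(cidx, rows$atom_index)
    molecule$conformers[[k]]$shifts <- rows$shift_ppm[ord]
    if ("energy_kjmol" %in% names(tab)) {
      ev <- unique(rows$energy_kjmol[is.finite(rows$energy_kjmol)])
      if (length(ev) > 1L) {
        dp5_stop(sprintf("conformer %d has conflicting energies", k),
                 "dp5_format_error")
      }
      if (length(ev) == 1L) energies[k] <- ev * scale
    }
  }
  energies <- energies - min(energies)
  for (k in conf_ids) molecule$conformers[[k]]$relative_energy <- energies[k]
  molecule
}

#' Read an experimental 13C peak list
#'
#' Plain text with one shift (ppm) per line, or CSV lines `shift_ppm,count`
#' where `count` is the number of equivalent carbons under the peak.
#'
#' @param path File path.
#' @return An object of class `dp5_peaklist` with fields `shifts` (sorted
#'   ascending) and `multiplicity`.
#' @export
read_peak_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    dp5_stop(sprintf("peak list '%s' is empty", path), "dp5_format_error")
  }
  if (grepl(",", lines[1]) && grepl("[A-Za-z]", lines[1])) lines <- lines[-1] # header
  shifts <- numeric(0); mult <- integer(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], ",")[[1]]
    v <- suppressWarnings(as.numeric(trimws(parts[1])))
    if (is.na(v)) {
      dp5_stop(sprintf("non-numeric peak value on line %d of '%s': '%s'",
                       i, path, lines[i]), "dp5_format_error")
    }
    m <- if (length(parts) > 1L) suppressWarnings(as.integer(trimws(parts[2]))) else 1L
    if (is.na(m) || m < 1L) {
      dp5_stop(sprintf("invalid multiplicity on line %d of '%s'", i, path),
               "dp5_format_error")
    }
    shifts <- c(shifts, v); mult <- c(mult, m)
  }
  peak_list(shifts, mult)
}

#' Construct a peak list
#' @param shifts Numeric 13C shifts in ppm.
#' @param multiplicity Integer count of equivalent carbons per peak.
#' @return A `dp5_peaklist` sorted by shift.
#' @export
peak_list <- function(shifts, multiplicity = NULL) {
  if (length(shifts) == 0L) dp5_stop("empty peak list", "dp5_format_error")
  if (any(!is.finite(shifts))) dp5_stop("non-finite peak value", "dp5_format_error")
  if (is.null(multiplicity)) multiplicity <- rep(1L, length(shifts))
  o <- order(shifts)
  structure(list(shifts = shifts[o], multiplicity = as.integer(multiplicity[o])),
            class = "dp5_peaklist")
}

#' Write a peak list
#' @param peaks A `dp5_peaklist`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_peak_list <- function(peaks, path) {
  lines <- ifelse(peaks$multiplicity > 1L,
                  sprintf("%.6f,%d", peaks$shifts, peaks$multiplicity),
                  sprintf("%.6f", peaks$shifts))
  writeLines(lines, path)
  invisible(path)
}

# ---- SDF writing ------------------------------------------------------------

format_ppm <- function(x) sprintf("%.6f", x)

molecule_to_sdfset <- function(molecule, extra_tags = character(0)) {
  n <- length(molecule$elements)
  nb <- nrow(molecule$bonds)
  sdfs <- vector("list", length(molecule$conformers))
  for (k in seq_along(molecule$conformers)) {
    cf <- molecule$conformers[[k]]
    ab <- cbind(cf$coords, matrix(0, n, 12))
    colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:16))
    rownames(ab) <- paste0(molecule$elements, "_", seq_len(n))
    bb <- cbind(molecule$bonds[, 1:3, drop = FALSE], matrix(0L, nb, 4))
    colnames(bb) <- paste0("C", 1:7)
    rownames(bb) <- seq_len(nb)
    header <- c(Molecule_Name = molecule$molecule_id, Source = "dp5",
                Comment = "",
                Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
    tags <- c(DP5_ENERGY_KJMOL = format_ppm(cf$relative_energy))
    if (!is.null(cf$shifts)) {
      tags[paste0("DP5_SHIFTS_", k)] <- paste(format_ppm(cf$shifts), collapse = " ")
    }
    tags <- c(tags, extra_tags)
    sdfs[[k]] <- methods::new("SDF", header = header, atomblock = ab,
                              bondblock = bb, datablock = tags)
  }
  methods::new("SDFset", SDF = sdfs,
               ID = paste0(molecule$molecule_id, "_conf", seq_along(sdfs)))
}

#' Write a molecule to SDF with shift/energy property tags
#'
#' One record per conformer; calculated shifts are stored as
#' `DP5_SHIFTS_<k>` (space-separated ppm, ascending carbon atom index) and
#' energies as `DP5_ENERGY_KJMOL`, so `read_structure()` round-trips the
#' object.
#'
#' @param molecule A `dp5_molecule`.
#' @param path Output SDF path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(molecule, path) {
  ChemmineR::write.SDF(molecule_to_sdfset(molecule), path)
  invisible(path)
}

# ---- Annotations ------------------------------------------------------------

#' Write per-atom probability annotations
#'
#' Writes the machine-readable annotation table
#' (`atom_index,element,assigned_peak_ppm,scaled_error_ppm,atomic_probability`)
#' and an SDF copy of the molecule tagged with the atomic probabilities
#' (`DP5_ATOMIC_PROBABILITIES`, space-separated, ascending carbon index),
#' the file-based counterpart of overlaying atomic probabilities on a
#' structure drawing.
#'
#' @param result A `dp5_result` computed for `molecule`.
#' @param molecule The `dp5_molecule` the result belongs to.
#' @param path Output CSV path.
#' @param sdf_path Output SDF path (default: `path` with `_annotated.sdf`).
#' @return Invisibly, a list with both paths.
#' @export
write_annotations <- function(result, molecule, path,
                              sdf_path = paste0(sub("\\.csv$", "", path), "_annotated.sdf")) {
  cidx <- carbon_indices(molecule)
  p <- result$atomic_probabilities
  if (length(p) != length(cidx)) {
    dp5_stop("result and molecule disagree on the number of carbon atoms",
             "dp5_consistency_error")
  }
  if (any(is.finite(p) & (p < 0 | p > 1))) {
    dp5_stop("atomic probabilities outside [0, 1]; refusing to write",
             "dp5_value_error")
  }
  tab <- data.frame(
    atom_index = cidx,
    element = molecule$elements[cidx],
    assigned_peak_ppm = result$assignment$mapping,
    scaled_error_ppm = result$scaled_errors,
    atomic_probability = p
  )
  utils::write.csv(format(tab, digits = 12, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  tags <- c(DP5_ATOMIC_PROBABILITIES = paste(format_ppm(p), collapse = " "),
            DP5_MOLECULAR_PROBABILITY = format_ppm(result$molecular_probability))
  if (!is.null(result$dp5) && is.finite(result$dp5)) {
    tags["DP5_PROBABILITY"] <- format_ppm(result$dp5)
  }
  ChemmineR::write.SDF(molecule_to_sdfset(molecule, extra_tags = tags), sdf_path)
  invisible(list(csv = path, sdf = sdf_path))
}

#' Read an annotation table written by [write_annotations()]
#' @param path CSV path.
#' @return A data frame of per-atom annotations.
#' @export
read_annotations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
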