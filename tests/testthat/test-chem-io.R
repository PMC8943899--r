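# Structure, shift table, peak list and annotation I/O.

test_that("SMILES and InChI inputs parse with explicit hydrogens and one 3D conformer", {
  mol <- read_structure("CCO", format = "smiles")
  expect_s3_class(mol, "dp5_molecule")
  expect_equal(sum(mol$elements %in% c("C", "O")), 3)   # heavy atoms
  expect_length(carbon_indices(mol), 2)
  expect_equal(sum(mol$elements == "H"), 6)             # hydrogens explicit
  expect_length(mol$conformers, 1)
  expect_equal(dim(mol$conformers[[1]]$coords), c(9, 3))

  inchi <- read_structure("InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3", format = "inchi")
  expect_equal(sort(table(inchi$elements)), sort(table(mol$elements)))
})

test_that("ring closure is resolved: cyclopropane has 3 C-C bonds", {
  mol <- read_structure("C1CC1", format = "smiles")
  expect_length(carbon_indices(mol), 3)
  # valence arithmetic for C3H6: 3 ring bonds among carbons, 6 C-H bonds
  cc <- sum(mol$elements[mol$bonds[, "i"]] == "C" &
              mol$elements[mol$bonds[, "j"]] == "C")
  expect_equal(cc, 3)
  expect_equal(nrow(mol$bonds), 9)
  expect_equal(sum(mol$elements == "H"), 6)
})

test_that("structures with no carbon are refused", {
  expect_error(read_structure("O", format = "smiles"), class = "dp5_domain_error")
  expect_error(read_structure("not_a_smiles((", format = "smiles"),
               class = "dp5_format_error")
})

test_that("SDF write/read round-trips atoms, bonds, conformers, shifts and energies", {
  gen <- small_gen()
  mol <- gen$corpus[[3]]$molecule
  mol$conformers[[2]] <- mol$conformers[[1]]
  mol$conformers[[2]]$relative_energy <- 2.5
  mol$conformers[[2]]$shifts <- mol$conformers[[1]]$shifts + 0.25
  path <- withr::local_tempfile(fileext = ".sdf")
  write_structure(mol, path)
  back <- read_structure(path, format = "sdf")
  expect_identical(back$elements, mol$elements)
  expect_equal(length(back$conformers), 2)
  expect_equal(back$bonds[, 1:2], mol$bonds[, 1:2])
  expect_equal(back$conformers[[1]]$shifts, mol$conformers[[1]]$shifts,
               tolerance = 1e-6)
  expect_equal(back$conformers[[2]]$relative_energy, 2.5, tolerance = 1e-6)
  expect_equal(back$conformers[[1]]$coords, mol$conformers[[1]]$coords,
               tolerance = 1e-4)
})

test_that("multi-record SDF files must be conformer blocks of one molecule", {
  gen <- small_gen()
  f1 <- withr::local_tempfile(fileext = ".sdf")
  f2 <- withr::local_tempfile(fileext = ".sdf")
  write_structure(gen$corpus[[1]]$molecule, f1)
  write_structure(gen$corpus[[2]]$molecule, f2)
  both <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(readLines(f1), readLines(f2)), both)
  expect_error(read_structure(both, format = "sdf"), class = "dp5_format_error")
})

test_that("shift tables populate conformers and shift energies to min zero", {
  mol <- chain_molecule()
  mol$conformers[[2]] <- mol$conformers[[1]]
  tab <- data.frame(conformer_id = rep(1:2, each = 3),
                    atom_index = rep(1:3, 2),
                    shift_ppm = c(11, 21, 31, 12, 22, 32),
                    energy_kjmol = rep(c(5, 2), each = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  out <- read_shift_table(path, mol)
  expect_equal(out$conformers[[1]]$relative_energy, 3)
  expect_equal(out$conformers[[2]]$relative_energy, 0)
  expect_equal(out$conformers[[2]]$shifts, c(12, 22, 32))

  # single conformer: relative energy 0 even if absolute energy given
  m1 <- chain_molecule()
  t1 <- tab[tab$conformer_id == 1, ]
  write.csv(t1, path, row.names = FALSE)
  expect_equal(read_shift_table(path, m1)$conformers[[1]]$relative_energy, 0)

  # duplicate (conformer, atom) row
  write.csv(rbind(t1, t1[1, ]), path, row.names = FALSE)
  expect_error(read_shift_table(path, m1), class = "dp5_format_error")

  # missing carbon shift names the atom
  write.csv(t1[-2, ], path, row.names = FALSE)
  expect_error(read_shift_table(path, m1), class = "dp5_incomplete_error")
  # non-carbon atom index
  bad <- t1; bad$atom_index[1] <- 4L
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_shift_table(path, m1), class = "dp5_index_error")
})

test_that("peak lists parse plain and CSV forms, sorted, with line-addressed errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("128.5", "77.0", "21.3"), path)
  pk <- read_peak_list(path)
  expect_equal(pk$shifts, c(21.3, 77.0, 128.5))

  writeLines(c("21.3,2", "77.0"), path)
  pk2 <- read_peak_list(path)
  expect_equal(pk2$multiplicity, c(2L, 1L))

  writeLines(character(0), path)
  expect_error(read_peak_list(path), class = "dp5_format_error")

  writeLines(c("21.3", "oops"), path)
  expect_error(read_peak_list(path), regexp = "line 2")
})

test_that("annotations write one row per carbon and round-trip through SDF tags", {
  gen <- small_gen()
  mol <- gen$corpus[[1]]$molecule
  nc <- length(carbon_indices(mol))
  p <- round(seq(0.05, 0.95, length.out = nc), 6)
  res <- fake_result(p)
  csv <- withr::local_tempfile(fileext = ".csv")
  paths <- write_annotations(res, mol, csv)
  tab <- read_annotations(csv)
  expect_equal(nrow(tab), nc)
  expect_equal(tab$atomic_probability, p, tolerance = 1e-9)
  expect_equal(tab$atom_index, carbon_indices(mol))

  # SDF tag preserves probabilities to 6 decimals
  sdf <- ChemmineR::read.SDFset(paths$sdf)
  tag <- ChemmineR::datablock(sdf[[1]])[["DP5_ATOMIC_PROBABILITIES"]]
  expect_equal(as.numeric(strsplit(tag, " ")[[1]]), p, tolerance = 1e-6)

  # probabilities outside [0, 1] refused
  expect_error(write_annotations(fake_result(c(p[-1], 1.2)), mol, csv),
               class = "dp5_value_error")
  # atom count mismatch refused
  expect_error(write_annotations(fake_result(p[-1]), mol, csv),
               class = "dp5_consistency_error")
})
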