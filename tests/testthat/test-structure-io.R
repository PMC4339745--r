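test_that("atomic and CA-only dimers parse with the right resolution mode", {
  p <- withr::local_tempfile(fileext = ".pdb")
  write_test_dimer(p)
  s <- read_structure(p)
  expect_s3_class(s, "pc_structure")
  expect_setequal(unique(s$atoms$chain), c("A", "B"))
  expect_identical(s$mode, "atomic")
  expect_equal(nrow(pcalign:::residue_table(s)), 6L)

  # strip everything but CA -> ca_only
  lines <- readLines(p)
  writeLines(grep(" CA ", lines, value = TRUE, fixed = TRUE), p)
  s2 <- read_structure(p)
  expect_identical(s2$mode, "ca_only")
})

test_that("MSE HETATM is mapped to methionine, other HETATM dropped", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, elem = "C"),
    pdb_atom_line(2, "CA", "MSE", "A", 2, 3.8, 0, 0, elem = "C",
                  type = "HETATM"),
    pdb_atom_line(3, "O", "HOH", "A", 100, 9, 9, 9, elem = "O",
                  type = "HETATM"),
    "END"), p)
  s <- read_structure(p)
  rt <- pcalign:::residue_table(s)
  expect_equal(rt$aa, c("A", "M"))
})

test_that("hydrogens are dropped and altlocs resolve to highest occupancy", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, elem = "C"),
    pdb_atom_line(2, "HA", "ALA", "A", 1, 0.5, 0.5, 0, elem = "H"),
    pdb_atom_line(3, "CA", "SER", "A", 2, 3.8, 0, 0, elem = "C",
                  altloc = "A", occ = 0.4),
    pdb_atom_line(4, "CA", "SER", "A", 2, 4.2, 0, 0, elem = "C",
                  altloc = "B", occ = 0.6),
    pdb_atom_line(5, "CA", "LYS", "A", 3, 7.6, 0, 0, elem = "C",
                  altloc = "A", occ = 0.5),
    pdb_atom_line(6, "CA", "LYS", "A", 3, 8.0, 0, 0, elem = "C",
                  altloc = "B", occ = 0.5),
    "END"), p)
  s <- read_structure(p)
  expect_false(any(grepl("^H", s$atoms$elety)))
  # SER: occupancy 0.6 wins; LYS: tie -> altloc A
  expect_equal(s$atoms$x[s$atoms$aa == "S"], 4.2)
  expect_equal(s$atoms$x[s$atoms$aa == "K"], 7.6)
})

test_that("requested model is honored and missing models error", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    pdb_atom_line(1, "CA", "ALA", "A", 1, 1, 0, 0, elem = "C"),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "CA", "ALA", "A", 1, 2, 0, 0, elem = "C"),
    "ENDMDL", "END"), p)
  expect_equal(read_structure(p)$atoms$x, 1)
  expect_equal(read_structure(p, model_index = 2)$atoms$x, 2)
  expect_error(read_structure(p, model_index = 3),
               class = "pcalign_user_error")
})

test_that("mode detection follows the below-half side-chain rule", {
  # 10 residues, 1 glycine; 3 of the 9 non-Gly residues carry a CB
  p <- withr::local_tempfile(fileext = ".pdb")
  lines <- character(0)
  aa <- c(rep("ALA", 9), "GLY")
  s <- 0L
  for (i in 1:10) {
    s <- s + 1L
    lines <- c(lines, pdb_atom_line(s, "CA", aa[i], "A", i, i * 3.8, 0, 0,
                                    elem = "C"))
    if (i <= 3) {
      s <- s + 1L
      lines <- c(lines, pdb_atom_line(s, "CB", aa[i], "A", i, i * 3.8, 1.5,
                                      0, elem = "C"))
    }
  }
  writeLines(c(lines, "END"), p)
  st <- read_structure(p)
  expect_identical(detect_resolution_mode(st), "ca_only")  # 3/9 < 0.5

  # reordering residues does not change the call
  st2 <- st
  st2$atoms <- st2$atoms[rev(seq_len(nrow(st2$atoms))), ]
  expect_identical(detect_resolution_mode(st2), "ca_only")
})

test_that("CA-only structures round-trip through PDB at format precision", {
  x <- generate_synthetic_interface(fixture_spec(6, seed = 3))
  p <- withr::local_tempfile(fileext = ".pdb")
  r <- x$residues
  pcalign:::write_pdb_atoms(p, r$chain, r$resno, r$insert, r$aa,
                            rep("CA", nrow(r)), x$ca)
  s <- read_structure(p)
  rt <- pcalign:::residue_table(s)
  expect_equal(rt$aa, r$aa)
  expect_equal(rt$chain, r$chain)
  expect_equal(rt$resno, r$resno)
  expect_equal(cbind(rt$ca_x, rt$ca_y, rt$ca_z), unname(x$ca),
               tolerance = 1e-3)
})

test_that("write_alignment emits the transformed PDB and score table", {
  x <- generate_synthetic_interface(fixture_spec(6, seed = 11))
  res <- align_and_score(x, x)
  prefix <- withr::local_tempfile()
  files <- write_alignment(res, x, x, prefix)
  tab <- read.table(paste0(prefix, ".tsv"), sep = "\t")
  expect_equal(nrow(tab), res$L_ali)
  expect_true(all(abs(tab[[9]]) < 1e-3))  # self-alignment: zero distances
  hdr <- readLines(paste0(prefix, ".tsv"))
  expect_match(hdr[1], "pc_score\t1")
  # round-trip: transformed coordinates match at PDB precision
  s <- read_structure(paste0(prefix, ".pdb"))
  rt <- pcalign:::residue_table(s)
  expect_equal(nrow(rt), 2L * nrow(x$residues))
  ca2 <- apply_transform(res$transform, x$ca)
  got <- cbind(rt$ca_x, rt$ca_y, rt$ca_z)[rt$chain %in% c("C", "D"), ]
  expect_equal(got, unname(ca2), tolerance = 1e-3)
})
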