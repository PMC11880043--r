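test_that("PDB parsing yields the atom table, resolving altlocs by occupancy", {
  path <- write_mini_pdb(c(
    pdb_atom_line("ATOM", 1, "N", " ", "ALA", "A", 1, " ", 11.104, 6.134, -6.504),
    pdb_atom_line("ATOM", 2, "CA", " ", "ALA", "A", 1, " ", 11.639, 6.071, -5.147),
    pdb_atom_line("ATOM", 3, "CA", "A", "LYS", "A", 2, " ", 12.0, 7.0, -4.0, occ = 0.4),
    pdb_atom_line("ATOM", 4, "CA", "B", "LYS", "A", 2, " ", 12.5, 7.5, -4.5, occ = 0.6),
    pdb_atom_line("ATOM", 5, "HA", " ", "LYS", "A", 2, " ", 12.1, 7.1, -4.1,
                  element = "H"),
    pdb_atom_line("HETATM", 6, "FE", " ", "HEM", "A", 201, " ", 13, 8, -3,
                  element = "FE")
  ))
  s <- read_structure(path)
  expect_s3_class(s, "qty_structure")
  expect_equal(nrow(s), 4)                         # H dropped, one altloc kept
  kept <- s[s$resno == 2 & s$atom == "CA", ]
  expect_equal(kept$x, 12.5)                       # occupancy 0.6 wins
  expect_false(any(s$element == "H"))
  expect_equal(s$is_polymer, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(s$resname[!s$is_polymer], "HEM")
})

test_that("equal-occupancy altlocs fall back to conformer A", {
  path <- write_mini_pdb(c(
    pdb_atom_line("ATOM", 1, "CA", "B", "ALA", "A", 1, " ", 1, 0, 0, occ = 0.5),
    pdb_atom_line("ATOM", 2, "CA", "A", "ALA", "A", 1, " ", 2, 0, 0, occ = 0.5),
    pdb_atom_line("ATOM", 3, "CA", " ", "GLY", "A", 2, " ", 3, 0, 0),
    pdb_atom_line("ATOM", 4, "CA", " ", "GLY", "A", 3, " ", 4, 0, 0)
  ))
  s <- read_structure(path)
  expect_equal(s$x[s$resno == 1], 2)
})

test_that("the same content parses identically from PDB and mmCIF", {
  pdb <- write_mini_pdb(c(
    pdb_atom_line("ATOM", 1, "N", " ", "ALA", "A", 1, " ", 11.104, 6.134, -6.504),
    pdb_atom_line("ATOM", 2, "CA", " ", "ALA", "A", 1, " ", 11.639, 6.071, -5.147),
    pdb_atom_line("HETATM", 3, "FE", " ", "HEM", "A", 201, " ", 13, 8, -3,
                  element = "FE")
  ))
  cif <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_test", "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id", "auth_comp_id",
      "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")),
    "ATOM 1 N N . ALA A 1 1 ? 11.104 6.134 -6.504 1.00 0.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 11.639 6.071 -5.147 1.00 0.00 ? 1 ALA A CA 1",
    "HETATM 3 FE FE . HEM B 2 . ? 13.000 8.000 -3.000 1.00 0.00 ? 201 HEM A FE 1"
  ), cif)
  a <- read_structure(pdb)
  b <- read_structure(cif)
  cols <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z",
            "is_polymer")
  expect_equal(as.data.frame(a[cols]), as.data.frame(b[cols]))
})

test_that("unreadable or atom-free files raise structure errors", {
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", bad)
  expect_error(read_structure(bad))
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("protomer extraction keeps one chain plus its nearest ligands", {
  s <- read_structure(mini_complex_pdb())
  a <- extract_protomer(s, "A")
  expect_equal(sort(unique(a$chain[a$is_polymer])), "A")
  expect_true("HEM" %in% a$resname)                # heme 3 A from chain A
  b <- extract_protomer(s, "B")
  expect_false("HEM" %in% b$resname)
  expect_error(extract_protomer(s, "Z"), "not found")
})

test_that("residue-number pairing trims residues missing from either model", {
  fx <- synthetic_tm_protein(n_helices = 2, helix_len = 12, loop_len = 4,
                             seed = 5)
  full <- fx$model
  p_same <- pair_residues(full, full)
  expect_equal(nrow(p_same), nrow(full))

  gap <- as_structure(dplyr::filter(tibble::as_tibble(full),
                                    !(resno %in% 10:20)))
  p_gap <- pair_residues(full, gap)
  expect_false(any(p_gap$resno_b %in% 10:20))
  expect_equal(nrow(p_gap), nrow(full) - length(10:20))
  # trimming monotonicity: removing residues never adds pairs
  expect_lte(nrow(p_gap), nrow(p_same))

  # pairing symmetry
  p_rev <- pair_residues(gap, full)
  expect_equal(p_rev$resno_a, p_gap$resno_b)
  expect_equal(p_rev$resno_b, p_gap$resno_a)

  # offset: model renumbered from 101 matches with offset -100 on b
  shifted <- tibble::as_tibble(full)
  shifted$resno <- shifted$resno + 100L
  p_off <- pair_residues(as_structure(shifted), full, offset = 100L)
  expect_equal(nrow(p_off), nrow(full))

  tiny <- as_structure(tibble::as_tibble(full)[1:2, ])
  expect_error(pair_residues(full, tiny), "at least 3 CA")
})

test_that("alignment pairing treats QTY substitutions as matches", {
  fx <- synthetic_tm_protein(n_helices = 2, helix_len = 12, loop_len = 4,
                             seed = 7)
  q <- qty_apply(fx$record)
  analog <- thread_analog(fx$model, q)
  # renumber the analog so resnum pairing is impossible
  at <- tibble::as_tibble(analog)
  at$resno <- at$resno + 500L
  analog <- as_structure(at)
  p <- pair_residues(fx$model, analog, policy = "align")
  expect_equal(nrow(p), nrow(fx$model))            # every column pairs
  # substituted columns are paired across different residue names
  sub_pos <- q$substitutions[[1]]$position
  expect_true(all(sub_pos %in% p$resno_a))
  i <- match(sub_pos, p$resno_a)
  expect_true(all(p$resname_a[i] != p$resname_b[i]))
})
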