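test_that("synthetic backbones survive a PDB write/read round trip", {
  bb <- ideal_alpha_strand("VGSNK", entry_id = "SYNT")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_backbone_pdb(bb, f, method = "NMR")
  back <- read_structures(f)
  expect_equal(nrow(back), nrow(bb))
  expect_equal(back$resname, bb$resname)
  expect_equal(back$aa, bb$aa)
  expect_equal(back$res_seq, bb$res_seq)
  expect_equal(attr(back, "method"), "NMR")
  for (col in c("N_x", "N_y", "N_z", "CA_x", "CA_y", "CA_z",
                "C_x", "C_y", "C_z", "O_x", "O_y", "O_z")) {
    expect_lt(max(abs(back[[col]] - bb[[col]])), 1e-3)
  }
})

test_that("multi-model files yield one model per MODEL block", {
  # a 10-model ensemble of a 42-residue helix-like chain
  one <- build_backbone(paste(rep("A", 42), collapse = ""),
                        phi = -60, psi = -45)
  models <- dplyr::bind_rows(lapply(1:10, function(m) {
    one$model <- m
    one
  }))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_backbone_pdb(models, f, method = "NMR")
  back <- read_structures(f)
  expect_equal(sort(unique(back$model)), 1:10)
  expect_equal(nrow(back), 10 * 42)
  expect_true(all(table(back$model) == 42))
})

test_that("mmCIF files parse through the same residue policies", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_TST1", "#", "_exptl.method 'SOLUTION NMR'", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 0.000 0.000 0.000 1.00 0.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 1.458 0.000 0.000 1.00 0.00 ? 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 2.009 1.420 0.000 1.00 0.00 ? 1 ALA A C 1",
    "ATOM 4 N N . ALA A 1 2 ? 1.329 2.440 0.000 1.00 0.00 ? 2 ALA A N 1",
    "ATOM 5 C CA . ALA A 1 2 ? 1.800 3.800 0.000 1.00 0.00 ? 2 ALA A CA 1",
    "ATOM 6 C C . ALA A 1 2 ? 3.300 3.900 0.000 1.00 0.00 ? 2 ALA A C 1",
    "#"
  ), f)
  bb <- read_structures(f)
  expect_equal(nrow(bb), 2)
  expect_equal(bb$res_seq, 1:2)
  expect_equal(attr(bb, "method"), "NMR")
  expect_equal(bb$N_x[2], 1.329)
})

test_that("nucleic-acid-only entries are flagged non-protein", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  P     G A   1      0.000   0.000   0.000  1.00  0.00           P",
    "ATOM      2  C1'   G A   1      1.500   0.000   0.000  1.00  0.00           C",
    "END"
  ), f)
  bb <- read_structures(f)
  expect_equal(nrow(bb), 0)
  expect_true(attr(bb, "non_protein"))
})

test_that("alternate locations keep the highest occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "EXPDTA    X-RAY DIFFRACTION",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  N  AALA A   2       1.329   2.440   0.000  0.40  0.00           N",
    "ATOM      5  N  BALA A   2       1.339   2.450   0.000  0.60  0.00           N",
    "ATOM      6  CA  ALA A   2       1.800   3.800   0.000  1.00  0.00           C",
    "ATOM      7  C   ALA A   2       3.300   3.900   0.000  1.00  0.00           C",
    "END"
  ), f)
  bb <- read_structures(f)
  expect_equal(attr(bb, "method"), "XRAY")
  expect_equal(bb$N_x[2], 1.339)
})

test_that("unreadable structure files raise a parse error", {
  expect_error(read_structures(file.path(tempdir(), "nope.pdb")),
               "does not exist")
})

test_that("dihedral tables parse the commented whitespace dialect", {
  f <- withr::local_tempfile()
  writeLines(c(
    "# produced by a dihedral extractor",
    "@ xaxis label",
    "-181.0 10.0 VAL-24", "-60 -45 GLY-25", "100 20 SER-26",
    "-170.0 12.0 VAL-24", "-61 -46 GLY-25", "101 21 SER-26",
    "-171.0 13.0 VAL-24", "-62 -47 GLY-25", "102 22 SER-26",
    "-172.0 14.0 VAL-24", "-63 -48 GLY-25", "103 23 SER-26"
  ), f)
  tab <- read_dihedral_table(f)
  expect_equal(nrow(tab), 12)
  expect_equal(unique(tab$frame), 0:3)
  expect_equal(tab$time_ps[tab$frame == 3][1], 6)
  expect_equal(tab$phi[1], 179)   # -181 wrapped into (-180, 180]
})

test_that("an explicit frame column overrides recurrence inference", {
  f <- withr::local_tempfile()
  writeLines(c(
    "0 -60 -45 G25", "0 60 45 S26",
    "5 -60 -45 G25", "5 60 45 S26"
  ), f)
  tab <- read_dihedral_table(f, stride_ps = 2)
  expect_equal(unique(tab$frame), c(0L, 5L))
  expect_equal(unique(tab$time_ps), c(0, 10))
})

test_that("comment-only tables are empty, malformed rows are named errors", {
  f <- withr::local_tempfile()
  writeLines(c("@ header", "# more header"), f)
  expect_equal(nrow(read_dihedral_table(f)), 0)

  f2 <- withr::local_tempfile()
  writeLines(c("-60 -45 G25", "abc -45 S26"), f2)
  expect_error(read_dihedral_table(f2), "row 2.*non-numeric")

  f3 <- withr::local_tempfile()
  writeLines("-400 10 G25", f3)
  expect_error(read_dihedral_table(f3), "outside \\[-360, 360\\]")
})

test_that("reports round-trip through TSV and JSON", {
  hits <- scan_structure(ideal_alpha_strand("AVGSA", start_state = "L"),
                         motif = "VGS")
  expect_equal(nrow(hits), 1)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_report(hits, tsv)
  back <- read_report(tsv)
  expect_equal(as.data.frame(back), as.data.frame(hits))

  # window summary round trip, TSV rows = frames
  sim <- simulate_states(n_frames = 50, n_residues = 3,
                         baseline_states = c("R", "L", "R"),
                         residue_labels = c("V24", "G25", "S26"),
                         flip_on_prob = 0.2, flip_off_prob = 0.2, seed = 3)
  ws <- window_summary(sim$states, 24:26, "RLR")
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  write_report(ws, tsv2)
  back2 <- read_report(tsv2)
  expect_equal(nrow(back2), 50)
  expect_equal(sum(back2$match), ws$frame_count)

  js <- withr::local_tempfile(fileext = ".json")
  write_report(ws, js)
  back3 <- read_report(js)
  expect_equal(back3$frame_count, ws$frame_count)
  expect_equal(back3$pattern, ws$pattern)

  # empty hit table -> header-only TSV
  none <- scan_structure(ideal_alpha_strand("AVGSA"), motif = "XXX")
  tsv3 <- withr::local_tempfile(fileext = ".tsv")
  write_report(none, tsv3)
  expect_equal(length(readLines(tsv3)), 1)
})
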