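minimal_pdb <- c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       2.009   0.774  -1.190  1.00  0.00           C",
  "ATOM      4  O   ALA A   1       1.383   0.843  -2.245  1.00  0.00           O",
  "ATOM      5  CB  ALA A   1       1.989  -0.733   1.224  1.00  0.00           C",
  "END"
)

test_that("a minimal hand-written ATOM block parses to 1 chain / 1 residue / 5 atoms", {
  s <- parse_pdb(minimal_pdb)
  expect_equal(nrow(s), 5)
  expect_equal(unique(s$chain), "A")
  expect_equal(unique(s$resno), 1L)
  expect_equal(s$atom, c("N", "CA", "C", "O", "CB"))
  expect_equal(s$x[2], 1.458)
  expect_equal(unique(s$chain_type), "protein")
})

test_that("parse errors name the offending line and empty input is rejected", {
  bad <- minimal_pdb
  substr(bad[3], 31, 38) <- "  xx.yyy"
  expect_error(parse_pdb(bad), "line 3")
  expect_error(parse_pdb("REMARK nothing here"), "no atoms")
  expect_error(parse_pdb(character(0)), "no atoms")
})

test_that("alt-locs keep the highest occupancy, ties broken alphabetically", {
  two <- c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.60  0.00           N",
    "ATOM      2  N  BALA A   1       9.000   9.000   9.000  0.40  0.00           N",
    "ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      4  C   ALA A   1       2.000   0.700  -1.200  1.00  0.00           C"
  )
  s <- parse_pdb(two)
  n_rows <- s[s$atom == "N", ]
  expect_equal(nrow(n_rows), 1)
  expect_equal(n_rows$alt, "A")
  expect_equal(n_rows$x, 0)

  tie <- sub("0.60", "0.40", two, fixed = TRUE)
  s2 <- parse_pdb(tie)
  expect_equal(s2[s2$atom == "N", ]$alt, "A")  # alphabetical on equal occ
})

test_that("atom count is conserved by alt-loc resolution", {
  lines <- c(minimal_pdb[1:5],
    "ATOM      6  CG AXXX A   2       0.000   0.000   9.000  0.50  0.00           C",
    "ATOM      7  CG BXXX A   2       0.000   0.000   9.500  0.50  0.00           C",
    "END")
  s <- parse_pdb(lines)
  expect_equal(nrow(s), 6)  # 7 records, one alt-loc pair collapsed
})

test_that("multi-model files default to the first model, others on request", {
  m <- c("MODEL        1", minimal_pdb[1:5], "ENDMDL",
         "MODEL        2",
         sub("0.000   0.000   0.000", "9.000   0.000   0.000",
             minimal_pdb[1:5]),
         "ENDMDL", "END")
  s1 <- parse_pdb(m)
  s2 <- parse_pdb(m, model = 2)
  expect_equal(nrow(s1), 5)
  expect_equal(s1$x[1], 0)
  expect_equal(s2$x[1], 9)
  expect_error(parse_pdb(m, model = 3), "not present")
})

test_that("PDB round-trip preserves hierarchy and coordinates to 1e-3 A", {
  for (fix in list(make_ideal_helix(12), make_ideal_strand(8),
                   make_scaffold(D = 10, theta = 90, seed = 4),
                   make_dimer(2, 3, seed = 5))) {
    s2 <- parse_pdb(write_pdb(fix))
    expect_equal(nrow(s2), nrow(fix))
    expect_equal(s2$atom, fix$atom)
    expect_equal(s2$resno, fix$resno)
    expect_equal(s2$chain, fix$chain)
    expect_lt(max(abs(coords_of(s2) - coords_of(fix))), 1e-3)
  }
})

test_that("PDB writer follows the fixed-column rules", {
  s <- make_ideal_helix(4)
  s$resno <- s$resno + 9995L  # residue number 9996..9999
  lines <- write_pdb(s)
  atom1 <- lines[1]
  expect_equal(substr(atom1, 23, 26), "9996")
  expect_equal(substr(lines[16], 23, 26), "9999")
  expect_equal(substr(atom1, 55, 60), "  1.00")
  expect_equal(substr(atom1, 13, 16), " N  ")
  expect_true(any(startsWith(lines, "TER")))
  expect_equal(lines[length(lines)], "END")
  s$chain <- "AB"
  expect_error(write_pdb(s), "chain_id")
})

test_that("a hand-written 3-atom _atom_site loop parses", {
  cif <- c(
    "data_test", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "ATOM 1 N N ALA A 1 0.000 0.000 0.000",
    "ATOM 2 C CA ALA A 1 1.458 0.000 0.000",
    "ATOM 3 C C ALA A 1 2.009 0.774 -1.190"
  )
  s <- parse_mmcif(cif)
  expect_equal(nrow(s), 3)
  expect_equal(unique(s$chain), "A")
  expect_equal(s$atom, c("N", "CA", "C"))
  expect_equal(s$x, c(0, 1.458, 2.009))
})

test_that("mmCIF quoted values containing spaces survive tokenization", {
  cif <- c(
    "data_q", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "HETATM 1 C C1 \"MY LIG\" A 1 0.0 0.0 0.0",
    "HETATM 2 C 'C 2' 'MY LIG' A 1 1.0 0.0 0.0"
  )
  s <- parse_mmcif(cif)
  # same expectations as the reference mmCIF tokenizer (gemmi) on this file
  expect_equal(s$resname, c("MY LIG", "MY LIG"))
  expect_equal(s$atom, c("C1", "C 2"))
})

test_that("mmCIF errors: missing loop and ragged rows", {
  expect_error(parse_mmcif(c("data_x", "_cell.length_a  10")), "_atom_site")
  ragged <- c(
    "data_r", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "ATOM 1 0.0 0.0 0.0",
    "ATOM 2 1.0 0.0"
  )
  expect_error(parse_mmcif(ragged), "mismatch")
})

test_that("PDB and mmCIF renderings of one fixture parse to equal structures", {
  for (fix in list(make_ideal_helix(12), make_dimer(2, 3, seed = 7))) {
    from_pdb <- parse_pdb(write_pdb(fix))
    from_cif <- parse_mmcif(write_mmcif(fix))
    expect_equal(from_cif$atom, from_pdb$atom)
    expect_equal(from_cif$resno, from_pdb$resno)
    expect_equal(from_cif$chain, from_pdb$chain)
    expect_equal(coords_of(from_cif), coords_of(from_pdb), tolerance = 1e-9)
  }
})

test_that("coordinates agree with an independent PDB reader (bio3d)", {
  skip_if_not_installed("bio3d")
  f <- tempfile(fileext = ".pdb")
  write_pdb(make_ideal_helix(12), f)
  ref <- bio3d::read.pdb(f)
  s <- read_pdb(f)
  expect_equal(nrow(s), nrow(ref$atom))
  expect_equal(s$x, ref$atom$x, tolerance = 1e-9)
  expect_equal(s$resno, ref$atom$resno)
  expect_equal(s$atom, ref$atom$elety)
})

test_that("chain_sequence handles amino acids, MSE, nucleotides and unknowns", {
  expect_equal(chain_sequence(make_ideal_helix(12)), "AAAAAAAAAAAA")
  atoms <- tibble::tibble(
    atom = "CA", resname = c("MET", "MSE", "GLY", "ZZZ"), chain = "A",
    resno = 1:4, x = c(0, 4, 8, 12), y = 0, z = 0, element = "C")
  expect_equal(chain_sequence(as_structure(atoms)), "MMGX")
  dna <- tibble::tibble(atom = "P", resname = c("DA", "DC", "DG", "DT"),
                        chain = "B", resno = 1:4, x = c(0, 4, 8, 12),
                        y = 0, z = 0, element = "P")
  expect_equal(chain_sequence(as_structure(dna)), "ACGT")
  het <- tibble::tibble(atom = "O", resname = "HOH", chain = "W",
                        resno = 1:3, x = c(0, 4, 8), y = 0, z = 0,
                        element = "O", het = TRUE)
  expect_error(chain_sequence(as_structure(het)), "not protein or nucleic")
})

test_that("extract_range is inclusive, insertion-code aware, and validates ids", {
  h <- make_ideal_helix(6)
  one <- extract_range(h, "1", "1")
  expect_equal(unique(one$resno), 1L)
  expect_equal(extract_range(h, "1", "6"), h)

  # residues numbered 30, 30A, 31: file-order scan keeps all three
  ins <- h
  ins$resno <- rep(c(30L, 30L, 31L, 32L, 33L, 34L), each = 5)
  ins$ins <- rep(c("", "A", "", "", "", ""), each = 5)
  got <- extract_range(ins, "30", "31")
  expect_equal(length(unique(paste0(got$resno, got$ins))), 3)

  expect_error(extract_range(h, "1", "99"), "99")
  expect_error(extract_range(h, "5", "2"), "after end")
})

test_that("structure_info summarises chains with their types", {
  d <- make_dimer(1, 3, seed = 1)
  info <- structure_info(d)
  expect_equal(info$chain, c("A", "B"))
  expect_equal(info$chain_type, c("protein", "protein"))
  expect_equal(info$n_residues, c(10, 10))
})
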