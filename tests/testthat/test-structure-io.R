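test_that("a hand-written PDB file loads with residues and atoms intact", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00 10.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00 10.00           O",
    "ATOM      5  N   GLY A   2       3.332   1.536   0.000  1.00 10.00           N",
    "ATOM      6  CA  GLY A   2       3.988   2.839   0.000  1.00 10.00           C",
    "END"), f)
  s <- load_structure(f)
  expect_s3_class(s, "eph_structure")
  expect_equal(n_atoms(s), 6)
  rt <- ephcompare:::residue_table(s)
  expect_equal(nrow(rt), 2)
  expect_equal(rt$resid, c("ALA", "GLY"))
  expect_equal(ephcompare:::get_atom(s, 2, "CA"), c(3.988, 2.839, 0))
})

test_that("PDB and mmCIF readers agree field by field on the same content", {
  s <- make_tilted_complex(5)
  fp <- withr::local_tempfile(fileext = ".pdb")
  fc <- withr::local_tempfile(fileext = ".cif")
  write_structure(s, fp)
  write_mmcif(s, fc)
  sp <- load_structure(fp)
  sc <- load_structure(fc)
  for (col in c("chain", "resno", "resid", "elety"))
    expect_equal(sc$atoms[[col]], sp$atoms[[col]], info = col)
  expect_lt(max(abs(as.matrix(sc$atoms[, c("x", "y", "z")]) -
                    as.matrix(sp$atoms[, c("x", "y", "z")]))), 1e-3)
})

test_that("altloc resolution keeps the highest occupancy, ties to A", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CA AGLY A   2       3.000   0.000   0.000  0.50 10.00           C",
    "ATOM      4  CA BGLY A   2       4.000   0.000   0.000  0.50 10.00           C",
    "END"), f)
  s <- load_structure(f)
  expect_equal(n_atoms(s), 2)
  expect_equal(s$atoms$x, c(2, 3))       # B wins on occupancy, then A on tie
  expect_equal(s$atoms$o, c(0.6, 0.5))
})

test_that("write/load round-trip preserves inventory and coordinates to 1e-3 A", {
  s <- make_tilted_complex(12)
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f1)
  s1 <- load_structure(f1)
  write_structure(s1, f2)
  s2 <- load_structure(f2)
  expect_equal(s1$atoms[, c("chain", "resno", "resid", "elety")],
               s2$atoms[, c("chain", "resno", "resid", "elety")])
  expect_lt(max(abs(as.matrix(s1$atoms[, c("x", "y", "z")]) -
                    as.matrix(s2$atoms[, c("x", "y", "z")]))), 1e-3)
})

test_that("extract_complex selects disjoint deep copies and validates input", {
  s <- make_tilted_complex(0)
  cx <- extract_complex(s, complex_spec("A", "B"))
  expect_equal(nrow(ephcompare:::residue_table(cx$receptor)), 50)
  expect_equal(nrow(ephcompare:::residue_table(cx$ligand)), 16)
  ranged <- extract_complex(s, complex_spec("A", "B",
                                            receptor_range = c(145, 189)))
  expect_equal(nrow(ephcompare:::residue_table(ranged$receptor)), 45)
  expect_error(extract_complex(s, complex_spec("A", "Z")), "chain 'Z'")
  expect_error(extract_complex(s, complex_spec("A", "B",
                                               ligand_range = c(300, 310))),
               "no residues")
  ## deep copy: mutating the selection leaves the source untouched
  x0 <- s$atoms$x[1]
  cx$receptor$atoms$x[1] <- 999
  expect_equal(s$atoms$x[1], x0)
})

test_that("parse failures and empty structures raise informative errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a coordinate file", f)
  expect_error(load_structure(f), "parse|empty|structure")
  expect_error(load_structure(tempfile(fileext = ".pdb")), "not found")
})
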