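test_that("single-sphere SASA matches the analytic area within quadrature error", {
  s <- make_sphere_cluster(matrix(0, 1, 3), 1.70)
  res <- shrake_rupley_sasa(s, keep_het = TRUE)
  analytic <- 4 * pi * (1.70 + 1.4)^2
  expect_lt(abs(res$total - analytic) / analytic, 0.01)
  expect_equal(res$total, sum(res$per_atom), tolerance = 1e-9)
})

test_that("two-sphere SASA matches the spherical-cap closed form", {
  for (d in c(2.5, 4.0, 5.5)) {
    s <- make_sphere_cluster(rbind(c(0, 0, 0), c(d, 0, 0)), c(1.70, 1.40))
    res <- shrake_rupley_sasa(s, keep_het = TRUE)
    analytic <- two_sphere_area(1.70 + 1.4, 1.40 + 1.4, d)
    expect_lt(abs(res$total - analytic) / analytic, 0.01,
              label = paste("d =", d))
  }
})

test_that("a fully enclosed atom has zero accessible area", {
  shell <- sphere_lattice(30) * 2.2
  s <- make_sphere_cluster(rbind(c(0, 0, 0), shell), c(1.0, rep(1.7, 30)))
  res <- shrake_rupley_sasa(s, keep_het = TRUE)
  expect_equal(res$per_atom[1], 0)
})

test_that("doubling the lattice density moves totals by less than 1 percent", {
  s <- make_random_cluster(40, seed = 5, box = 12)
  a1 <- shrake_rupley_sasa(s, n_points = 960, keep_het = TRUE)$total
  a2 <- shrake_rupley_sasa(s, n_points = 1920, keep_het = TRUE)$total
  expect_lt(abs(a1 - a2) / a2, 0.01)
})

test_that("unknown elements without radii are rejected", {
  s <- make_sphere_cluster(matrix(0, 1, 3), 1.7)
  s$atoms$radius <- NULL
  s$atoms$elesy <- "XX"
  expect_error(shrake_rupley_sasa(s, keep_het = TRUE), "radius")
})

test_that("chains far apart bury nothing; docked chains bury symmetrically", {
  far <- docked_clusters(gap = 25)
  rep_far <- buried_interface_area(far$a, far$b, keep_het = TRUE)
  expect_equal(rep_far$interface_area, 0)
  expect_length(rep_far$receptor_residues, 0)

  near <- docked_clusters(gap = 0.5)
  rep_ab <- buried_interface_area(near$a, near$b, keep_het = TRUE)
  rep_ba <- buried_interface_area(near$b, near$a, keep_het = TRUE)
  expect_gt(rep_ab$interface_area, 0)
  expect_equal(rep_ab$interface_area, rep_ba$interface_area, tolerance = 1e-9)
  expect_equal(rep_ab$interface_area,
               (rep_ab$bsa_receptor + rep_ab$bsa_ligand) / 2)
})

test_that("buried area agrees with a high-density recomputation within 2 percent", {
  near <- docked_clusters(gap = 0.5)
  a1 <- buried_interface_area(near$a, near$b, n_points = 960,
                              keep_het = TRUE)$interface_area
  a2 <- buried_interface_area(near$a, near$b, n_points = 10000,
                              keep_het = TRUE)$interface_area
  expect_lt(abs(a1 - a2) / a2, 0.02)
})

test_that("SASA of one chain decreases monotonically as a partner approaches", {
  gaps <- c(8, 4, 2, 1, 0.5)
  buried <- vapply(gaps, function(g) {
    d <- docked_clusters(gap = g)
    buried_interface_area(d$a, d$b, n_points = 480,
                          keep_het = TRUE)$bsa_receptor
  }, numeric(1))
  expect_true(all(diff(buried) >= 0))
})

test_that("contact classification applies distance rules and class precedence", {
  ## two alanine CB atoms at 3.0 A: plain vdW
  rec <- mini_structure(protein_atom("A", 1, "ALA", "CB", "C", 0))
  lig <- mini_structure(protein_atom("B", 1, "ALA", "CB", "C", 3.0))
  ct <- enumerate_contacts(rec, lig)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$contact_class, "vdw")
  expect_equal(ct$ligand_moiety, "SC")

  ## Lys NZ vs Glu OE1 at 3.2 A: satisfies the hbond distance but salt wins
  rec <- mini_structure(protein_atom("A", 1, "LYS", "CE", "C", -1.4),
                        protein_atom("A", 1, "LYS", "NZ", "N", 0))
  lig <- mini_structure(protein_atom("B", 1, "GLU", "OE1", "O", 3.2))
  ct <- enumerate_contacts(rec, lig)
  ct_nz <- ct[ct$receptor_atom == "NZ", ]
  expect_equal(ct_nz$contact_class, "salt")

  ## backbone N-H...O=C hydrogen bond at 3.0 A with a straight approach
  rec <- mini_structure(protein_atom("A", 1, "GLY", "CA", "C", -1.5),
                        protein_atom("A", 1, "GLY", "N", "N", 0))
  lig <- mini_structure(protein_atom("B", 1, "GLY", "O", "O", 3.0))
  ct <- enumerate_contacts(rec, lig)
  expect_equal(ct[ct$receptor_atom == "N", "contact_class"], "hbond")
  expect_equal(ct[ct$receptor_atom == "N", "receptor_moiety"], "BB")

  ## same pair but with the antecedent folded back (< 90 degrees): no hbond
  rec <- mini_structure(protein_atom("A", 1, "GLY", "CA", "C", 1.0, 0.5),
                        protein_atom("A", 1, "GLY", "N", "N", 0))
  ct <- enumerate_contacts(rec, lig)
  expect_equal(ct[ct$receptor_atom == "N", "contact_class"], "vdw")

  ## beyond every cutoff: nothing
  lig_far <- mini_structure(protein_atom("B", 1, "GLY", "O", "O", 9))
  expect_equal(nrow(enumerate_contacts(rec, lig_far)), 0)
})

test_that("hbond and salt records always satisfy their distance cutoffs", {
  set.seed(9)
  ## random Lys/Glu side-chain tips scattered near each other
  rec <- do.call(mini_structure, lapply(1:8, function(i)
    protein_atom("A", i, "LYS", "NZ", "N", runif(1, 0, 6), runif(1, 0, 6),
                 runif(1, 0, 6))))
  lig <- do.call(mini_structure, lapply(1:8, function(i)
    protein_atom("B", i, "GLU", "OE1", "O", runif(1, 0, 6), runif(1, 0, 6),
                 runif(1, 0, 6))))
  ct <- enumerate_contacts(rec, lig)
  if (nrow(ct)) {
    expect_true(all(ct$distance[ct$contact_class == "vdw"] <= 4.0))
    expect_true(all(ct$distance[ct$contact_class == "hbond"] <= 3.5))
    expect_true(all(ct$distance[ct$contact_class == "salt"] <= 4.0))
  }
  expect_equal(nrow(enumerate_contacts(rec, lig, vdw_cutoff = 0.1,
                                       hbond_cutoff = 0.1,
                                       salt_cutoff = 0.1)), 0)
})

test_that("residue summary groups by ligand residue and separates the GH loop", {
  expect_equal(nrow(residue_contact_summary(enumerate_contacts(
    mini_structure(protein_atom("A", 1, "ALA", "CB", "C", 0)),
    mini_structure(protein_atom("B", 1, "ALA", "CB", "C", 30))))), 0)

  rec <- mini_structure(protein_atom("A", 57, "GLY", "CA", "C", 0),
                        protein_atom("A", 58, "VAL", "CB", "C", 0, 3))
  lig <- mini_structure(protein_atom("B", 124, "PHE", "CZ", "C", 3.1),
                        protein_atom("B", 112, "LEU", "CD1", "C", 3.1, 3))
  sm <- residue_contact_summary(enumerate_contacts(rec, lig))
  expect_equal(nrow(sm), 2)
  expect_equal(sm$ligand_resno, c(124, 112))   # GH-loop rows first
  expect_equal(sm$in_gh_loop, c(TRUE, FALSE))
  expect_match(sm$receptor_partners[1], "GLY57\\(BB\\)")
  expect_match(sm$receptor_partners[2], "VAL58\\(SC\\)")
})
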