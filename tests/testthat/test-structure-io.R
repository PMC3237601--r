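test_that("min_atom_distance computes the exhaustive all-pairs minimum", {
  a <- matrix(c(0, 0, 0), 1, 3)
  b <- matrix(c(3, 4, 0), 1, 3)
  expect_equal(min_atom_distance(a, b), 5)
  expect_equal(min_atom_distance(a, a), 0)

  set.seed(5)
  A <- matrix(rnorm(4 * 3, sd = 4), 4, 3)
  B <- matrix(rnorm(6 * 3, sd = 4), 6, 3)
  brute <- min(apply(A, 1, function(p) {
    apply(B, 1, function(q) sqrt(sum((p - q)^2)))
  }))
  expect_equal(min_atom_distance(A, B), brute, tolerance = 1e-12)
  expect_equal(min_atom_distance(A, B), min_atom_distance(B, A))
  expect_error(min_atom_distance(matrix(numeric(0), 0, 3), B), "empty")
})

test_that("contact labelling is inclusive at the cutoff and covers the grid", {
  # chain B sits dy above chain A; pair (1,1) distance = dy exactly
  at_cut <- toy_complex("A", "W", dy = 6.0)
  expect_equal(extract_contacts(at_cut)$label, 1L)
  above <- toy_complex("A", "W", dy = 6.001)
  expect_equal(extract_contacts(above)$label, 0L)

  # dimer ligand (2 + 3 residues) x dimer receptor (4 + 1): 25 labelled pairs
  cx <- complex_structure("dimers",
    list(toy_chain("A", "AC", y = 0), toy_chain("B", "DEF", x0 = 100, y = 0)),
    list(toy_chain("C", "GHIK", y = 300), toy_chain("D", "L", x0 = 100, y = 300)))
  ct <- extract_contacts(cx)
  expect_equal(nrow(ct), 25L)
  expect_s3_class(ct, "contact_table")
  # no intra-side entries: every row pairs a ligand chain with a receptor one
  expect_true(all(ct$ligand_chain %in% c("A", "B")))
  expect_true(all(ct$receptor_chain %in% c("C", "D")))
})

test_that("contact labelling is invariant under swapping ligand and receptor", {
  g <- generate_complex(fixture_config(n_complexes = 1, seed = 31), seed = 31)
  cx <- g$structure
  swapped <- complex_structure(cx$complex_id, cx$receptor, cx$ligand)
  ct <- extract_contacts(cx)
  ct_sw <- extract_contacts(swapped)
  key <- paste(ct$ligand_chain, ct$ligand_idx, ct$receptor_chain, ct$receptor_idx)
  key_sw <- paste(ct_sw$receptor_chain, ct_sw$receptor_idx,
                  ct_sw$ligand_chain, ct_sw$ligand_idx)
  expect_equal(ct$label[order(key)], ct_sw$label[order(key_sw)])
  expect_equal(nrow(ct), nrow(ct_sw))
})

test_that("per-residue pooling matches a brute-force any() over rows/columns", {
  cx <- toy_complex("AC", "WY", dy = 5)  # only (1,1) and (2,2) in contact
  ct <- extract_contacts(cx)
  lab <- pool_single_residue_labels(ct)
  expect_equal(nrow(lab), 4L)
  expect_equal(lab$label, c(1L, 1L, 1L, 1L))

  # random labelled table
  set.seed(8)
  g <- generate_complex(fixture_config(n_complexes = 1, chains_per_side = c(1, 1),
                                       chain_length = c(10, 10),
                                       interface_size = c(4, 8), seed = 9),
                        seed = 9)
  ct <- g$contacts
  lab <- pool_single_residue_labels(ct)
  M <- contact_matrix(ct, "label")
  expect_equal(lab$label[lab$side == "ligand"], unname(apply(M, 1, max)))
  expect_equal(lab$label[lab$side == "receptor"], unname(apply(M, 2, max)))
  # all-zero table
  far <- extract_contacts(toy_complex("ACD", "WY", dy = 50))
  expect_true(all(pool_single_residue_labels(far)$label == 0L))
  # every positive residue has at least one positive pair
  expect_true(sum(ct$label) >= sum(lab$label) / 2)
})

test_that("PDB round-trip preserves residues, types and contact labels", {
  g <- generate_complex(fixture_config(n_complexes = 1, seed = 77), seed = 77)
  dir <- withr::local_tempdir()
  bench <- list(c(g, list(pssms = setNames(
    lapply(c(g$structure$ligand, g$structure$receptor),
           function(ch) generate_pssm(ch$aa, seed = 3, chain_id = ch$chain_id)),
    vapply(c(g$structure$ligand, g$structure$receptor), `[[`, "", "chain_id")))))
  class(bench) <- c("pair_benchmark", "list")
  manifest <- write_fixtures(bench, dir)
  back <- read_fixtures(dir)
  expect_length(back, 1L)
  cx <- back[[1]]$structure
  # residue counts and types equal the generator record
  expect_equal(vapply(cx$ligand, length, 1L),
               vapply(g$structure$ligand, length, 1L))
  expect_equal(lapply(cx$ligand, `[[`, "aa"), lapply(g$structure$ligand, `[[`, "aa"))
  expect_equal(lapply(cx$receptor, `[[`, "aa"),
               lapply(g$structure$receptor, `[[`, "aa"))
  # extractor applied to the written PDB recovers the planted labels
  ct <- extract_contacts(cx)
  expect_equal(ct$label, g$contacts$label)
})

test_that("read_complex reports missing chains and rejects empty ones", {
  g <- generate_complex(fixture_config(n_complexes = 1, seed = 5), seed = 5)
  dir <- withr::local_tempdir()
  pdb <- file.path(dir, "x.pdb")
  pairsite:::.write_pdb_complex(g$structure, pdb)
  expect_error(read_complex(pdb, "Z", "E"), "Z")
  lig_ids <- vapply(g$structure$ligand, `[[`, "", "chain_id")
  rec_ids <- vapply(g$structure$receptor, `[[`, "", "chain_id")
  expect_s3_class(read_complex(pdb, lig_ids, rec_ids), "complex_structure")
})

test_that("contact table TSV round-trips", {
  ct <- extract_contacts(toy_complex("ACD", "WY", dy = 5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_contacts(ct, f)
  back <- read_contacts(f)
  expect_equal(back$label, ct$label)
  expect_equal(back$min_dist, ct$min_dist, tolerance = 1e-9)
})
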