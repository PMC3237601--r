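test_that("count_pairs symmetrizes side-specific type counts consistently", {
  # ligand DR x receptor RY: ordered candidate pairs D-R, D-Y, R-R, R-Y
  ct <- extract_contacts(toy_complex("DR", "RY", dy = 50))
  pc <- count_pairs(ct)
  get <- function(i, j) pc$pair_count[pc$aa_i == i & pc$aa_j == j |
                                      pc$aa_i == j & pc$aa_j == i]
  expect_equal(get("D", "R"), 1)
  expect_equal(get("D", "Y"), 1)
  expect_equal(get("R", "R"), 1)
  expect_equal(get("R", "Y"), 1)
  expect_equal(attr(pc, "total_pairs"), 4)
  expect_equal(sum(pc$pair_count), attr(pc, "total_pairs"))

  # additivity: two identical complexes double every count
  pc2 <- count_pairs(list(ct, ct))
  expect_equal(pc2$pair_count, 2 * pc$pair_count)
  expect_equal(pc2$observed, 2 * pc$observed)
})

test_that("count_pairs totals equal an independent brute-force recount", {
  bench <- tiny_benchmark(n = 3, seed = 21)
  tabs <- lapply(bench, `[[`, "contacts")
  pc <- count_pairs(tabs)
  # brute force: loop over every row of every table
  brute_cnt <- new.env(); brute_obs <- new.env()
  for (ct in tabs) {
    for (r in seq_len(nrow(ct))) {
      key <- paste(sort(c(ct$ligand_aa[r], ct$receptor_aa[r])), collapse = "-")
      brute_cnt[[key]] <- (brute_cnt[[key]] %||% 0) + 1
      if (ct$label[r] == 1) brute_obs[[key]] <- (brute_obs[[key]] %||% 0) + 1
    }
  }
  for (k in seq_len(nrow(pc))) {
    key <- paste(sort(c(pc$aa_i[k], pc$aa_j[k])), collapse = "-")
    expect_equal(pc$pair_count[k], brute_cnt[[key]] %||% 0)
    expect_equal(pc$observed[k], brute_obs[[key]] %||% 0)
  }
  expect_equal(attr(pc, "total_pairs"),
               sum(vapply(tabs, nrow, 1L)))
  expect_equal(attr(pc, "total_contacts"),
               sum(vapply(tabs, function(x) sum(x$label), 1L)))
})

test_that("expected contacts, propensity and chi-squared follow their formulas", {
  expect_equal(expected_contacts(38053, 7750982, 11259), 55.276, tolerance = 1e-4)
  expect_equal(expected_contacts(10, 10, 7), 7)  # pair_count == total -> E == N_o
  expect_error(expected_contacts(1, 0, 5), "positive")

  expect_equal(pair_propensity(5, 5), 1)
  expect_true(is.na(pair_propensity(3, 0)))

  expect_equal(chi_squared(10, 10), 0)
  expect_equal(chi_squared(161, 55.276), (161 - 55.276)^2 / 55.276)
  expect_error(chi_squared(3, 0), "positive")

  # scale invariance: multiplying all counts leaves propensity unchanged
  E1 <- expected_contacts(100, 1000, 50)
  E2 <- expected_contacts(300, 3000, 150)
  expect_equal(pair_propensity(20, E1), pair_propensity(60, E2))
})

test_that("chi-squared p-value matches numerical integration of the density", {
  expect_equal(chi_squared_pvalue(0), 1)
  expect_error(chi_squared_pvalue(-1), "non-negative")
  # independent oracle: integrate the 1-df chi-squared density
  for (x in c(0.5, 3.8415, 10)) {
    num <- integrate(function(t) dchisq(t, df = 1), x, Inf,
                     rel.tol = 1e-10)$value
    expect_equal(chi_squared_pvalue(x), num, tolerance = 1e-8)
  }
  expect_equal(chi_squared_pvalue(3.8415), 0.05, tolerance = 1e-4)
  # strictly decreasing in chi2
  xs <- seq(0, 50, by = 0.5)
  expect_true(all(diff(chi_squared_pvalue(xs)) < 0))
})

test_that("propensity table conserves expected totals and sorts by p-value", {
  bench <- tiny_benchmark(n = 3, seed = 33)
  tab <- propensity_table(lapply(bench, `[[`, "contacts"))
  expect_equal(sum(tab$expected), attr(tab, "total_contacts"), tolerance = 1e-9)
  pv <- tab$p_value[!is.na(tab$p_value)]
  expect_true(all(diff(pv) >= 0))
  expect_true(all(tab$propensity[tab$observed > 0] > 0, na.rm = TRUE))
})

test_that("single-residue propensity is 1 under uniform interface membership", {
  # two facing chains, all residues in contact: every residue is interface
  cx <- toy_complex("ARND", "CQEG", dy = 5)
  ct <- extract_contacts(cx)
  sp <- single_residue_propensity(ct)
  present <- sp$n_total > 0
  expect_true(all(abs(sp$propensity[present] - 1) < 1e-12))
  # direction forced: only Arg in interfaces
  cx2 <- complex_structure("t",
    list(toy_chain("A", "RAAA", y = 0)),
    list(toy_chain("B", "RCCC", y = 50)))
  # move the two arginines together
  cx2$ligand[[1]]$atoms[[1]] <- matrix(c(0, 0, 0), 1, 3)
  cx2$receptor[[1]]$atoms[[1]] <- matrix(c(0, 5, 0), 1, 3)
  sp2 <- single_residue_propensity(extract_contacts(cx2))
  expect_gt(sp2$propensity[sp2$aa == "R"], 1)
  expect_true(all(sp2$propensity[sp2$aa %in% c("A", "C")] < 1))
})

test_that("planted three-fold pairing enrichments are recovered", {
  cfg <- fixture_config(n_complexes = 150, chains_per_side = c(1, 1),
                        chain_length = c(20, 20), interface_size = c(10, 10),
                        pair_preference = c("Y-Y" = 3, "D-R" = 3),
                        noise = 0, seed = 55)
  bench <- generate_benchmark(cfg)
  tab <- propensity_table(lapply(bench, `[[`, "contacts"))
  # a selection weight of 3 on a rare type pair translates to a propensity
  # near 3; the band is wide because only ~10-30 enriched contacts are
  # expected among the 1500 sampled
  for (p in c("Y-Y", "D-R")) {
    got <- tab$propensity[tab$pair == p]
    expect_gt(got, 1.5)
    expect_lt(got, 5.0)
  }
  # unenriched pairs stay near 1 on average
  rest <- tab[!tab$pair %in% c("Y-Y", "D-R") & tab$pair_count > 0, ]
  expect_lt(abs(sum(rest$observed) / sum(rest$expected) - 1), 0.15)
})
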