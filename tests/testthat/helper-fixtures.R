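# Shared helpers for building tiny in-code fixtures.

# a chain with one CA atom per residue placed on a line along x
toy_chain <- function(id, seq, x0 = 0, y = 0, spacing = 10) {
  seq <- strsplit(seq, "")[[1]]
  atoms <- lapply(seq_along(seq), function(i) {
    matrix(c(x0 + spacing * (i - 1), y, 0), 1, 3)
  })
  new_chain(id, seq, atoms)
}

# two facing chains: ligand residues at y = 0, receptor at y = dy; residue i
# of each chain shares an x slot, so pair (i, i) is at distance dy
toy_complex <- function(lig_seq = "ACD", rec_seq = "WY", dy = 5,
                        id = "toy") {
  complex_structure(id,
                    toy_chain("A", lig_seq, y = 0),
                    toy_chain("B", rec_seq, y = dy))
}

# small benchmark for model tests (shared settings, cheap networks)
tiny_benchmark <- function(n = 4, seed = 11) {
  cfg <- fixture_config(n_complexes = n, chains_per_side = c(1, 1),
                        chain_length = c(12, 16), interface_size = c(6, 9),
                        seed = seed)
  generate_benchmark(cfg)
}

tiny_params <- function() network_params(hidden_units = 2, epochs = 15)

# reduced feature grid keeping the four window-size extremes; used where a
# test needs ensemble structure but not all 24 members
small_grid <- function() list(feature_spec(1, 0), feature_spec(0, 1),
                              feature_spec(3, 1), feature_spec(1, 3))

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force Mann-Whitney AUC with ties counted 1/2 (independent oracle)
bruteforce_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
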