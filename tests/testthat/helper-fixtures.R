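# shared fixtures: a small untrained model and a SMILES list

test_model <- function(dim = 16L, hidden = 8L, seed = 1L, backend_seed = 0L) {
  hanna_model(hash_backend(dim = dim, seed = backend_seed),
              hidden = hidden, seed = seed)
}

# 22 parsable SMILES covering common functional groups
SMILES_FIXTURE <- c(
  "CCO", "OCC", "C(C)O", "O", "CO", "CCCCCC", "c1ccccc1", "Cc1ccccc1",
  "CC(=O)O", "CC(C)O", "CCOCC", "CC(=O)C", "C1CCCCC1", "ClCCl", "CCN",
  "N#N", "O=C=O", "CCOC(=O)C", "CC#N", "CS(=O)C", "OCC(O)CO", "C=CC=C"
)

# deterministic toy gamma records for IO tests
toy_gamma_records <- function(n = 10L, seed = 99L) {
  ds <- generate_dataset(n_systems = 3L, points_per_system = ceiling(n / 3),
                         seed = seed)
  ds$records[seq_len(n), ]
}
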