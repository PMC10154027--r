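# Shared in-code fixtures.

# 20 plausible HCNOS odorant-like molecules, all multi-atom, single
# fragment, well under 500 Da
valid_odorant_smiles <- c(
  "CCO", "CC(C)O", "CCCO", "CC(=O)C", "CC(=O)OCC", "CCCCCC=O",
  "c1ccccc1C=O", "CC(=O)OC1CCCCC1", "CCSC", "CCCN", "CC(C)CC(=O)O",
  "O=C(O)CCC", "CCOC(=O)C", "CC1=CCC(CC1)C(C)C", "CSSC", "c1ccc(cc1)O",
  "CC(=O)NC", "CCCCCCCCO", "O=CC1=CC=CO1", "CC(C)=CCCC(C)=CC=O")

# linear chain A -> B -> ... as a metabolic network
chain_network <- function(n, prefix = "C") {
  keys <- sprintf("%s%02d", prefix, seq_len(n))
  reactions <- data.frame(
    reaction_id = sprintf("R%02d", seq_len(n - 1)),
    species = "chain",
    reactants = keys[-n],
    products = keys[-1],
    stringsAsFactors = FALSE)
  list(net = build_network(reactions, "chain"), keys = keys)
}

small_embedding_table <- function(n, d, seed = 1, name = "emb",
                                  metric = "correlation_centered") {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * d), n, d,
              dimnames = list(sprintf("K%02d", seq_len(n)), NULL))
  representation_table(name, metric, m)
}
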