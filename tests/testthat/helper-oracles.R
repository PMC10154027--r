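# Independent oracles kept deliberately naive: breadth-first search over an
# adjacency list, pair-counting AUROC, coordinate-loop L1. They share no
# code with the package implementations they check.

# all-pairs shortest directed path lengths by explicit BFS
bfs_all_pairs <- function(adj, n) {
  d <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    d[s, ] <- dist
  }
  d
}

# AUROC as the fraction of correctly ordered (positive, negative) pairs,
# ties counted one half
auroc_pair_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

l1_loop_oracle <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + abs(a[i] - b[i])
  s
}

# random directed graph as a metapom network plus its adjacency list
random_digraph <- function(n, p_edge, seed) {
  set.seed(seed)
  keys <- sprintf("N%02d", seq_len(n))
  edges <- which(matrix(stats::runif(n * n) < p_edge, n, n) &
                   !diag(TRUE, n), arr.ind = TRUE)
  # one self-loop per node keeps every node in the network without
  # changing any shortest path
  edges <- rbind(edges, cbind(seq_len(n), seq_len(n)))
  reactions <- data.frame(
    reaction_id = sprintf("R%03d", seq_len(nrow(edges))),
    species = "test",
    reactants = keys[edges[, 1]],
    products = keys[edges[, 2]],
    stringsAsFactors = FALSE)
  adj <- lapply(seq_len(n), function(v) edges[edges[, 1] == v, 2])
  list(net = build_network(reactions, "test"), keys = keys, adj = adj,
       n = n)
}

random_rotation <- function(d, seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(d * d), d)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
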