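test_that("build_network expands reactions into directed edges", {
  rx <- data.frame(reaction_id = "R1", species = "s",
                   reactants = "A", products = "B;C",
                   stringsAsFactors = FALSE)
  net <- build_network(rx, "s")
  expect_setequal(net$nodes, c("A", "B", "C"))
  ed <- igraph::as_data_frame(net$graph)
  expect_setequal(paste(ed$from, ed$to), c("A B", "A C"))

  rx2 <- rbind(rx, data.frame(reaction_id = "R2", species = "s",
                              reactants = "B", products = "D"))
  net2 <- build_network(rx2, "s")
  expect_equal(sum(net2$nodes == "B"), 1)
})

test_that("build_network matches a brute-force tally on random tables", {
  set.seed(11)
  keys <- sprintf("M%02d", 1:25)
  rx <- data.frame(
    reaction_id = sprintf("R%02d", 1:50), species = "s",
    reactants = replicate(50, paste(sample(keys, sample(1:2, 1)),
                                    collapse = ";")),
    products = replicate(50, paste(sample(keys, sample(1:2, 1)),
                                   collapse = ";")),
    stringsAsFactors = FALSE)
  net <- build_network(rx, "s")
  # independent tally
  mentioned <- unique(unlist(strsplit(c(rx$reactants, rx$products), ";")))
  n_edges <- sum(vapply(seq_len(50), function(i) {
    length(strsplit(rx$reactants[i], ";")[[1]]) *
      length(strsplit(rx$products[i], ";")[[1]])
  }, numeric(1)))
  expect_setequal(net$nodes, mentioned)
  expect_equal(igraph::ecount(net$graph), n_edges)
})

test_that("build_network is invariant to reaction order", {
  set.seed(12)
  keys <- sprintf("M%02d", 1:15)
  rx <- data.frame(reaction_id = sprintf("R%02d", 1:20), species = "s",
                   reactants = sample(keys, 20, TRUE),
                   products = sample(keys, 20, TRUE),
                   stringsAsFactors = FALSE)
  a <- build_network(rx, "s")
  b <- build_network(rx[sample(20), ], "s")
  expect_identical(a$nodes, b$nodes)
  ed <- function(n) {
    df <- igraph::as_data_frame(n$graph)
    sort(paste(df$from, df$to, df$reaction_id))
  }
  expect_identical(ed(a), ed(b))
})

test_that("metabolic distance follows directed shortest paths", {
  ch <- chain_network(3)
  expect_equal(metabolic_distance(ch$net, ch$keys[1], ch$keys[3]), 2L)
  expect_true(is.na(metabolic_distance(ch$net, ch$keys[3], ch$keys[1])))
  expect_equal(metabolic_distance(ch$net, ch$keys[2], ch$keys[2]), 0L)
  expect_error(metabolic_distance(ch$net, "nope", ch$keys[1]), "unknown")
})

test_that("metabolic distance agrees with an exhaustive BFS oracle", {
  g <- random_digraph(30, 0.08, seed = 21)
  oracle <- bfs_all_pairs(g$adj, g$n)
  for (i in seq_len(g$n)) {
    for (j in seq_len(g$n)) {
      expect_identical(metabolic_distance(g$net, g$keys[i], g$keys[j]),
                       oracle[i, j])
    }
  }
})

test_that("triangle inequality holds for directed distances", {
  g <- random_digraph(20, 0.12, seed = 31)
  d <- bfs_all_pairs(g$adj, g$n)
  trip <- expand.grid(a = 1:20, b = 1:20, c = 1:20)
  trip <- trip[sample(nrow(trip), 500), ]
  for (k in seq_len(nrow(trip))) {
    ab <- d[trip$a[k], trip$b[k]]
    bc <- d[trip$b[k], trip$c[k]]
    ac <- d[trip$a[k], trip$c[k]]
    if (!is.na(ab) && !is.na(bc) && !is.na(ac)) expect_lte(ac, ab + bc)
  }
})

test_that("select_networks filters inclusively and sorts by size", {
  mk <- function(n) chain_network(n)$net
  nets <- list(mk(99), mk(100), mk(150))
  sel <- select_networks(nets, min_size = 100)
  expect_equal(vapply(sel, network_size, integer(1)), c(150L, 100L))
  expect_length(select_networks(nets, min_size = 200), 0)
  set.seed(5)
  sizes <- sample(50:150, 12)
  nets <- lapply(sizes, mk)
  sel <- select_networks(nets, 100)
  expect_equal(vapply(sel, network_size, integer(1)),
               sort(sizes[sizes >= 100], decreasing = TRUE))
})

test_that("a 13-node chain fills every stratum with all ordered pairs", {
  # a chain of 13 nodes has exactly 13 - d ordered pairs at distance d,
  # down to a single pair (the two ends) at d = 12
  ch <- chain_network(13)
  cfg <- sampling_config(pairs_per_distance = 50, seed = 4)
  pairs <- suppressWarnings(sample_pairs(ch$net, ch$keys, cfg))
  strata <- table(pairs$metabolic_distance)
  expect_equal(as.integer(names(strata)), 1:12)
  expect_equal(unname(c(strata)), 13L - 1:12)
  expect_equal(sum(pairs$metabolic_distance == 12), 1)
  p12 <- pairs[pairs$metabolic_distance == 12, ]
  expect_identical(c(p12$key_a, p12$key_b), c(ch$keys[1], ch$keys[13]))
})

test_that("stratified sampling is deterministic and oracle-consistent", {
  g <- random_digraph(40, 0.15, seed = 41)
  oracle <- bfs_all_pairs(g$adj, g$n)
  cfg <- sampling_config(pairs_per_distance = 5, d_min = 1, d_max = 4,
                         seed = 9)
  p1 <- suppressWarnings(sample_pairs(g$net, g$keys, cfg))
  p2 <- suppressWarnings(sample_pairs(g$net, g$keys, cfg))
  expect_identical(p1, p2)
  cfg2 <- cfg
  cfg2$seed <- 10
  p3 <- suppressWarnings(sample_pairs(g$net, g$keys, cfg2))
  expect_false(identical(p1, p3))
  for (k in seq_len(nrow(p1))) {
    expect_equal(p1$metabolic_distance[k],
                 oracle[match(p1$key_a[k], g$keys),
                        match(p1$key_b[k], g$keys)])
  }
})

test_that("strict sampling errors on empty strata, lax mode warns", {
  ch <- chain_network(4)   # distances 1..3 only
  strict <- sampling_config(d_min = 1, d_max = 6, seed = 1, strict = TRUE)
  expect_error(suppressWarnings(sample_pairs(ch$net, ch$keys, strict)),
               "distance")
  lax <- sampling_config(d_min = 1, d_max = 6, seed = 1)
  w <- capture_warnings(pairs <- sample_pairs(ch$net, ch$keys, lax))
  expect_true(any(grepl("no odorant pairs", w)))
  expect_true(any(grepl("under-filled", w)))
  expect_equal(max(pairs$metabolic_distance), 3)
})

test_that("reaction and pathway tables round-trip through tsv", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tspecies\treactants\tproducts",
               "R1\ts\tA;B\tC",
               "R2\ts\tC\tD;E"), tsv)
  rx <- read_reaction_table(tsv)
  expect_identical(rx$reactants[[1]], c("A", "B"))
  net <- build_network(rx, "s")
  expect_equal(igraph::ecount(net$graph), 4)

  pw <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pathway_id\tspecies\tmembers",
               "P1\ts\tA;C;D"), pw)
  expect_identical(read_pathways(pw), list(P1 = c("A", "C", "D")))
})
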