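# Directed metabolite graphs, shortest-path metabolic distance, network
# selection and stratified odorant-pair sampling.

# run expr with a deterministic RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Read a reaction table
#'
#' TSV with columns `reaction_id`, `species`, `reactants`, `products`;
#' reactants/products are `;`-separated molecule keys.
#'
#' @param path file path.
#' @return data.frame with list-columns `reactants` and `products`.
#' @export
read_reaction_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "species", "reactants", "products")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("reaction table ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  }
  df$reactants <- strsplit(df$reactants, ";", fixed = TRUE)
  df$products <- strsplit(df$products, ";", fixed = TRUE)
  df
}

#' Read a pathway table
#'
#' TSV with columns `pathway_id`, `species`, `members` (`;`-separated,
#' ordered molecule keys).
#'
#' @param path file path.
#' @return named list of ordered key vectors.
#' @export
read_pathways <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pathway_id", "members")
  if (!all(need %in% names(df))) {
    stop("pathway table ", path, " needs columns pathway_id, members")
  }
  stats::setNames(strsplit(df$members, ";", fixed = TRUE), df$pathway_id)
}

#' Build a directed metabolite network from reactions
#'
#' Every reaction contributes one directed edge from each of its reactants
#' to each of its products; nodes are the union of all mentioned
#' metabolites. Parallel edges from distinct reactions are kept (with their
#' `reaction_id`), but shortest-path distance counts any multiplicity once.
#'
#' @param reactions data.frame with columns `reaction_id`, `species` and
#'   list-columns (or `;`-separated strings) `reactants`, `products`, as
#'   produced by [read_reaction_table()].
#' @param species species label attached to the network; when `reactions`
#'   has a `species` column, rows are filtered to it.
#' @return object of class `metabolic_network`: list with `species`,
#'   `nodes`, and the underlying igraph `graph`.
#' @export
build_network <- function(reactions, species = "unknown") {
  if ("species" %in% names(reactions) && !is.null(species) &&
      species != "unknown") {
    reactions <- reactions[reactions$species == species, , drop = FALSE]
  }
  as_list <- function(x) if (is.list(x)) x else strsplit(x, ";", fixed = TRUE)
  rs <- as_list(reactions$reactants)
  ps <- as_list(reactions$products)
  from <- character(0); to <- character(0); rid <- character(0)
  for (i in seq_along(rs)) {
    if (!length(rs[[i]]) || !length(ps[[i]])) {
      stop("reaction ", reactions$reaction_id[i],
           " has empty reactants or products")
    }
    grid <- expand.grid(r = rs[[i]], p = ps[[i]],
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    from <- c(from, grid$r)
    to <- c(to, grid$p)
    rid <- c(rid, rep(reactions$reaction_id[i], nrow(grid)))
  }
  nodes <- sort(unique(c(from, to)))
  g <- igraph::make_empty_graph(n = length(nodes), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to), reaction_id = rid)
  }
  structure(list(species = species, nodes = nodes, graph = g),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %s: %d metabolites, %d reaction edges\n",
              x$species, length(x$nodes), igraph::ecount(x$graph)))
  invisible(x)
}

#' Number of metabolites in a network
#' @param net a `metabolic_network`.
#' @return integer node count.
#' @export
network_size <- function(net) length(net$nodes)

.check_keys <- function(net, keys) {
  unknown <- setdiff(keys, net$nodes)
  if (length(unknown)) {
    stop("unknown metabolite key(s): ", paste(unknown, collapse = ", "))
  }
}

#' Shortest-path metabolic distance
#'
#' Length of the shortest directed path from `a` to `b`: the minimum number
#' of documented reactions converting one metabolite into the other.
#'
#' @param net a `metabolic_network`.
#' @param a,b molecule keys present in the network.
#' @return non-negative integer, or `NA` when no directed path exists.
#' @export
metabolic_distance <- function(net, a, b) {
  .check_keys(net, c(a, b))
  d <- igraph::distances(net$graph, v = a, to = b, mode = "out",
                         algorithm = "unweighted")[1, 1]
  if (is.infinite(d)) NA_integer_ else as.integer(d)
}

# full odorous-to-odorous directed distance matrix (rows: from)
.distance_table <- function(net, keys) {
  igraph::distances(net$graph, v = keys, to = keys, mode = "out",
                    algorithm = "unweighted")
}

#' Select networks by size
#'
#' Keeps networks with at least `min_size` metabolites (inclusive
#' threshold), sorted by decreasing size.
#'
#' @param nets list of `metabolic_network`s.
#' @param min_size minimum node count; default 100.
#' @return filtered, size-sorted list.
#' @export
select_networks <- function(nets, min_size = 100) {
  sizes <- vapply(nets, network_size, integer(1))
  keep <- sizes >= min_size
  nets[keep][order(sizes[keep], decreasing = TRUE)]
}

#' Sampling configuration for odorant pairs
#'
#' @param pairs_per_distance pairs sampled per metabolic distance stratum
#'   (default 50).
#' @param d_min,d_max distance range sampled (defaults 1 and 12).
#' @param seed RNG seed making the sample reproducible.
#' @param strict error (instead of warn) when a stratum has no available
#'   pairs.
#' @return object of class `sampling_config`.
#' @export
sampling_config <- function(pairs_per_distance = 50, d_min = 1, d_max = 12,
                            seed = 1, strict = FALSE) {
  stopifnot(pairs_per_distance >= 1, d_min >= 1, d_min <= d_max)
  structure(list(pairs_per_distance = pairs_per_distance, d_min = d_min,
                 d_max = d_max, seed = seed, strict = strict),
            class = "sampling_config")
}

#' Sample odorant pairs stratified by metabolic distance
#'
#' For every distance `d` in `[d_min, d_max]`, draws
#' `min(pairs_per_distance, available)` ordered odorous pairs at exactly
#' directed distance `d`, uniformly without replacement. The draw is a pure
#' function of `(net, odorous, cfg)`.
#'
#' @param net a `metabolic_network`.
#' @param odorous character vector of odorous molecule keys (subset of the
#'   network's nodes).
#' @param cfg a [sampling_config()].
#' @return data.frame with columns `key_a`, `key_b`, `metabolic_distance`.
#' @export
sample_pairs <- function(net, odorous, cfg = sampling_config()) {
  stopifnot(inherits(cfg, "sampling_config"))
  .check_keys(net, odorous)
  odorous <- unique(odorous)
  dt <- .distance_table(net, odorous)
  out <- vector("list", cfg$d_max - cfg$d_min + 1)
  .with_seed(cfg$seed, {
    for (d in cfg$d_min:cfg$d_max) {
      hits <- which(dt == d, arr.ind = TRUE)
      n_avail <- nrow(hits)
      if (n_avail == 0) {
        if (cfg$strict) {
          stop("no odorant pairs available at metabolic distance ", d)
        }
        warning("no odorant pairs available at metabolic distance ", d)
        next
      }
      take <- min(cfg$pairs_per_distance, n_avail)
      if (take < cfg$pairs_per_distance) {
        warning(sprintf(
          "stratum d=%d under-filled: %d of %d pairs available",
          d, take, cfg$pairs_per_distance))
      }
      sel <- hits[sample.int(n_avail, take), , drop = FALSE]
      out[[d - cfg$d_min + 1]] <- data.frame(
        key_a = odorous[sel[, 1]], key_b = odorous[sel[, 2]],
        metabolic_distance = d, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(key_a = character(0), key_b = character(0),
                      metabolic_distance = integer(0))
  }
  rownames(res) <- NULL
  res
}
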