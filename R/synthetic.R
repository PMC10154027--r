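# Seeded generators emulating the statistical structure of every pipeline
# input: a metabolite tree whose node fingerprints drift by small edits per
# reaction, embeddings whose distances track graph distance at a tunable
# level, oils as metabolic neighborhoods, trial-resolved neural traces with
# planted responders, and feature/label datasets with controllable
# informativeness.

#' Synthetic-metabolome generator configuration
#'
#' @param n_metabolites number of metabolites grown (default 250; keeping
#'   it at or below `embed_dim` lets the embedding generator realize its
#'   target Gram matrix exactly).
#' @param branching probability that a new metabolite branches off a
#'   random existing node instead of extending a random current leaf
#'   (default 0.15; low values grow the long reaction chains needed to
#'   populate high metabolic-distance strata).
#' @param edit_rate mean number of count-fingerprint coordinates changed
#'   by one unit per reaction step (default 10). Steps draw from a
#'   two-point mixture: most reactions make a small edit, a fraction
#'   `cliff_prob` make a large one (a structural cliff, as when a
#'   reaction removes or adds a major substructure); the mixture mean is
#'   exactly `edit_rate`.
#' @param cliff_prob probability that a reaction step is a structural
#'   cliff (default 0.2).
#' @param cliff_mult cliff edit size as a multiple of `edit_rate`
#'   (default 3).
#' @param rho target pair-level Pearson correlation between metabolic
#'   distance and embedding correlation-distance, in `[0, 1]`.
#' @param embed_dim embedding width (default 256, the POM width).
#' @param noise_sd SD of the independent embedding noise (default 1).
#' @param fp_dim synthetic count-fingerprint length (default 1024).
#' @param corr_length correlation length (in reaction steps) of the clean
#'   embedding's Gram matrix `exp(-D / corr_length)` (default 6).
#' @param seed RNG seed; every generator is a pure function of its config.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_metabolites = 250, branching = 0.15,
                             edit_rate = 10, rho = 0.9, embed_dim = 256,
                             noise_sd = 1, fp_dim = 1024, corr_length = 6,
                             cliff_prob = 0.2, cliff_mult = 3, seed = 1) {
  stopifnot(n_metabolites >= 10, branching >= 0, branching <= 1,
            edit_rate >= 1, rho >= 0, rho <= 1, embed_dim >= 2,
            noise_sd >= 0, fp_dim >= 16, corr_length > 0,
            cliff_prob >= 0, cliff_prob < 1, cliff_mult >= 1)
  cliff_edits <- round(cliff_mult * edit_rate)
  base_edits <- (edit_rate - cliff_prob * cliff_edits) / (1 - cliff_prob)
  if (base_edits < 1 || cliff_edits > fp_dim) {
    stop("cliff_prob/cliff_mult incompatible with edit_rate/fp_dim")
  }
  structure(list(n_metabolites = n_metabolites, branching = branching,
                 edit_rate = edit_rate, rho = rho, embed_dim = embed_dim,
                 noise_sd = noise_sd, fp_dim = fp_dim,
                 corr_length = corr_length, cliff_prob = cliff_prob,
                 cliff_mult = cliff_mult, base_edits = base_edits,
                 cliff_edits = cliff_edits, seed = seed),
            class = "generator_config")
}

#' Generate a synthetic metabolome
#'
#' Grows a directed metabolite tree from a root: each new metabolite is
#' the product of a reaction whose reactant is either a random current
#' leaf (chain extension) or, with probability `branching`, a random
#' existing metabolite. Each product's count fingerprint is its parent's
#' with a number of coordinates moved by one unit (zero coordinates are
#' incremented): usually a small edit, occasionally a structural cliff
#' (see [generator_config()]), with mean exactly `edit_rate`. Fingerprint
#' L1 distance therefore grows with metabolic distance but carries the
#' heavy-tailed step noise real reaction chemistry shows. All maximal
#' root-to-leaf paths are extracted as pathways.
#'
#' @param cfg a [generator_config()].
#' @return object of class `synthetic_metabolome`: list with `network`
#'   (a `metabolic_network`), `fingerprints` (node x `fp_dim` count
#'   matrix), `pathways` (named list of ordered key vectors), `parent`
#'   (integer vector), and `cfg`.
#' @export
make_metabolome <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$n_metabolites
  keys <- sprintf("M%04d", seq_len(n))
  .with_seed(cfg$seed, {
    fp <- matrix(0L, n, cfg$fp_dim, dimnames = list(keys, NULL))
    base_idx <- sample.int(cfg$fp_dim, 64)
    fp[1, base_idx] <- sample(1:3, 64, replace = TRUE)
    parent <- integer(n)
    is_leaf <- logical(n)
    is_leaf[1] <- TRUE
    for (t in 2:n) {
      leaves <- which(is_leaf)
      p <- if (stats::runif(1) < cfg$branching || length(leaves) == 0) {
        sample.int(t - 1, 1)
      } else {
        leaves[sample.int(length(leaves), 1)]
      }
      parent[t] <- p
      is_leaf[p] <- FALSE
      is_leaf[t] <- TRUE
      child <- fp[p, ]
      k <- if (stats::runif(1) < cfg$cliff_prob) {
        cfg$cliff_edits
      } else {
        # randomized rounding keeps the mixture mean exactly edit_rate
        floor(cfg$base_edits) +
          stats::rbinom(1, 1, cfg$base_edits - floor(cfg$base_edits))
      }
      coords <- sample.int(cfg$fp_dim, k)
      delta <- ifelse(child[coords] == 0L, 1L,
                      sample(c(-1L, 1L), k, replace = TRUE))
      child[coords] <- child[coords] + delta
      fp[t, ] <- child
    }
  })
  reactions <- data.frame(
    reaction_id = sprintf("R%04d", seq_len(n - 1)),
    species = "synthetic",
    reactants = keys[parent[2:n]],
    products = keys[2:n],
    stringsAsFactors = FALSE)
  net <- build_network(reactions, species = "synthetic")
  leaves <- setdiff(seq_len(n), parent)
  pathways <- lapply(leaves, function(l) {
    path <- l
    while (path[1] != 1L) path <- c(parent[path[1]], path)
    keys[path]
  })
  names(pathways) <- sprintf("P%04d", seq_along(leaves))
  structure(list(network = net, fingerprints = fp, pathways = pathways,
                 parent = parent, cfg = cfg),
            class = "synthetic_metabolome")
}

#' @export
print.synthetic_metabolome <- function(x, ...) {
  cat(sprintf(
    "<synthetic_metabolome> %d metabolites, %d pathways, edit rate %d\n",
    length(x$network$nodes), length(x$pathways), x$cfg$edit_rate))
  invisible(x)
}

#' Count-fingerprint representation table of a synthetic metabolome
#'
#' @param met a `synthetic_metabolome`.
#' @param bits return the binary-support table (Tanimoto metric) instead
#'   of counts (L1 metric).
#' @return a `representation_table` named `"cfp_synthetic"` or
#'   `"bfp_synthetic"`.
#' @export
metabolome_fp_table <- function(met, bits = FALSE) {
  if (bits) {
    representation_table("bfp_synthetic", "tanimoto",
                         (met$fingerprints > 0) * 1)
  } else {
    representation_table("cfp_synthetic", "l1", met$fingerprints)
  }
}

#' Generate an embedding table correlated with metabolic distance
#'
#' Builds a clean geometric embedding from the undirected skeleton: the
#' target Gram matrix `C = exp(-D / corr_length)` of graph distances `D`
#' is positive semi-definite on a tree (tree metrics are of negative
#' type), and when the node count does not exceed `embed_dim` it is
#' realized exactly as `C^{1/2} Q` with `Q` having orthonormal rows (a
#' truncated eigen-embedding is used otherwise). The clean embedding is
#' then mixed with independent Gaussian noise at a mixing angle
#' calibrated (by root-finding on the generator's own stratified pair
#' sample) so the pair-level Pearson correlation between metabolic
#' distance and embedding correlation-distance matches the config's
#' `rho`. `rho = 0` yields pure noise; `rho` at or above the clean
#' embedding's own ceiling yields the clean embedding.
#'
#' @param met a `synthetic_metabolome`.
#' @param cfg a [generator_config()]; defaults to the metabolome's own.
#' @return a `representation_table` named `"pom_synthetic"` with metric
#'   `correlation_centered` and attributes `theta` (calibrated mixing
#'   angle) and `achieved_r` (correlation measured on the calibration
#'   sample).
#' @export
make_embedding_table <- function(met, cfg = met$cfg) {
  stopifnot(inherits(met, "synthetic_metabolome"))
  net <- met$network
  keys <- net$nodes
  n <- length(keys)
  d_undir <- igraph::distances(net$graph, mode = "all",
                               algorithm = "unweighted")[keys, keys]
  gram <- exp(-d_undir / cfg$corr_length)
  eig <- eigen(gram, symmetric = TRUE)
  vals <- pmax(eig$values, 0)

  res <- .with_seed(cfg$seed + 7, {
    if (n <= cfg$embed_dim) {
      # exact realization: rows of C^{1/2} Q have Gram exactly C
      gram_half <- eig$vectors %*% (sqrt(vals) * t(eig$vectors))
      q <- qr.Q(qr(matrix(stats::rnorm(cfg$embed_dim^2), cfg$embed_dim)))
      z <- gram_half %*% q[seq_len(n), , drop = FALSE]
    } else {
      z <- eig$vectors[, seq_len(cfg$embed_dim), drop = FALSE] %*%
        diag(sqrt(vals[seq_len(cfg$embed_dim)]), cfg$embed_dim)
    }
    z <- z / sqrt(mean(z^2))
    noise <- matrix(stats::rnorm(n * cfg$embed_dim,
                                 sd = max(cfg$noise_sd, 0)),
                    n, cfg$embed_dim)
    noise_norm <- sqrt(mean(noise^2))
    if (noise_norm > 0) noise <- noise / noise_norm

    d_max <- min(12, max(d_undir))
    calib_pairs <- suppressWarnings(sample_pairs(
      net, keys, sampling_config(pairs_per_distance = 50, d_min = 1,
                                 d_max = d_max, seed = cfg$seed + 11)))
    measure <- function(theta) {
      e <- cos(theta) * z + sin(theta) * noise
      rownames(e) <- keys
      tab <- representation_table("calib", "correlation_centered", e)
      uk <- unique(c(calib_pairs$key_a, calib_pairs$key_b))
      dm <- distance_matrix(tab, uk)
      pd <- dm$values[cbind(match(calib_pairs$key_a, uk),
                            match(calib_pairs$key_b, uk))]
      pearson_r(calib_pairs$metabolic_distance, pd)
    }
    theta <- if (noise_norm == 0) {
      0  # no noise to mix in: the clean embedding is the only option
    } else if (cfg$rho <= 0) {
      pi / 2
    } else if (measure(0) <= cfg$rho) {
      0
    } else if (measure(pi / 2) >= cfg$rho) {
      pi / 2
    } else {
      stats::uniroot(function(th) measure(th) - cfg$rho,
                     interval = c(0, pi / 2), tol = 1e-3)$root
    }
    e <- cos(theta) * z + sin(theta) * noise
    rownames(e) <- keys
    list(e = e, theta = theta, achieved = measure(theta))
  })
  tab <- representation_table("pom_synthetic", "correlation_centered",
                              res$e)
  attr(tab, "theta") <- res$theta
  attr(tab, "achieved_r") <- res$achieved
  tab
}

#' Generate essential oils as metabolic neighborhoods
#'
#' Each oil collects the metabolites within undirected graph distance
#' `radius` of a randomly drawn anchor; oils with fewer than two members
#' are redrawn. With `ensure_cover` (default), extra oils anchored at any
#' uncovered metabolite are appended so the oil universe spans the whole
#' metabolome, emulating a compound list compiled *from* the oils.
#'
#' @param met a `synthetic_metabolome`.
#' @param n_oils number of random-anchor oils (default 303).
#' @param radius neighborhood radius in reaction steps (default 2).
#' @param seed RNG seed.
#' @param ensure_cover append oils anchored at uncovered metabolites.
#' @return an `oil_dataset`.
#' @export
make_oils <- function(met, n_oils = 303, radius = 2, seed = 1,
                      ensure_cover = TRUE) {
  stopifnot(inherits(met, "synthetic_metabolome"), radius >= 1)
  g <- met$network$graph
  keys <- met$network$nodes
  d_undir <- igraph::distances(g, mode = "all", algorithm = "unweighted")
  d_undir <- d_undir[keys, keys]
  ball <- function(anchor) keys[d_undir[anchor, ] <= radius]
  oils <- .with_seed(seed, {
    out <- vector("list", n_oils)
    for (i in seq_len(n_oils)) {
      for (try in seq_len(100)) {
        members <- ball(sample(keys, 1))
        if (length(members) >= 2) break
      }
      if (length(members) < 2) {
        stop("could not draw an oil with >= 2 members after 100 tries")
      }
      out[[i]] <- members
    }
    out
  })
  names(oils) <- sprintf("oil_%04d", seq_along(oils))
  if (ensure_cover) {
    uncovered <- setdiff(keys, unique(unlist(oils)))
    for (anchor in uncovered) {
      members <- ball(anchor)
      if (length(members) >= 2) {
        oils[[sprintf("oil_%04d", length(oils) + 1)]] <- members
      }
    }
  }
  oil_dataset(oils)
}

#' Generate trial-resolved neural traces with planted responders
#'
#' Gaussian baseline noise everywhere; responder cells additionally get a
#' post-onset response that ramps over three frames to a plateau of the
#' given amplitude. The signal-to-noise ratio of a responder is
#' `amplitude / noise_sd`.
#'
#' @param responders logical odorant x neuron matrix (dimnames name the
#'   odorants and neurons) marking planted responder cells.
#' @param n_trials trials per cell (default 6).
#' @param frames trace length in frames (default 90).
#' @param onset 1-based first post-onset frame (default 41).
#' @param amplitude plateau response height (default 5).
#' @param noise_sd baseline noise SD (default 1).
#' @param seed RNG seed.
#' @return list of cells (`odorant`, `neuron`, `traces`, `responder`)
#'   consumable by [elicitation_matrix()], with attribute `responders`.
#' @export
make_neural <- function(responders, n_trials = 6, frames = 90, onset = 41,
                        amplitude = 5, noise_sd = 1, seed = 1) {
  responders <- as.matrix(responders)
  stopifnot(is.logical(responders), !is.null(dimnames(responders)),
            onset > 1, frames >= onset)
  odorants <- rownames(responders)
  neurons <- colnames(responders)
  profile <- numeric(frames)
  post <- onset:frames
  ramp <- pmin(1, seq_along(post) / 3)
  profile[post] <- amplitude * ramp
  cells <- .with_seed(seed, {
    out <- list()
    for (od in odorants) {
      for (ne in neurons) {
        tr <- matrix(stats::rnorm(n_trials * frames, sd = noise_sd),
                     n_trials, frames)
        if (responders[od, ne]) {
          tr <- sweep(tr, 2, profile, "+")
        }
        out[[length(out) + 1]] <- list(
          odorant = od, neuron = ne,
          traces = trial_traces(tr, onset),
          responder = responders[od, ne])
      }
    }
    out
  })
  attr(cells, "responders") <- responders
  cells
}

#' Generate a feature/label evaluation dataset
#'
#' Features are either taken from a supplied representation table or drawn
#' as standard Gaussian vectors. Informative targets are a (thresholded)
#' linear readout of a few feature coordinates plus optional noise;
#' uninformative targets are independent of the features.
#'
#' @param n number of molecules.
#' @param informative logical; labels depend on the features or not.
#' @param task `"classification"` or `"regression"`.
#' @param table optional `representation_table` supplying features (must
#'   hold at least `n` keys); when `NULL` a Gaussian feature table of
#'   width `feature_dim` is generated.
#' @param seed RNG seed.
#' @param feature_dim width of the generated feature table (default 16).
#' @param n_signal_dims feature coordinates carrying signal (default 1).
#' @param noise_sd label noise SD for informative targets (default 0,
#'   i.e. noiseless).
#' @return list with `dataset` (an [eval_dataset()]) and `table` (the
#'   featurizing `representation_table`).
#' @export
make_eval_dataset <- function(n, informative = TRUE,
                              task = c("classification", "regression"),
                              table = NULL, seed = 1, feature_dim = 16,
                              n_signal_dims = 1, noise_sd = 0) {
  task <- match.arg(task)
  stopifnot(n >= 10)
  .with_seed(seed, {
    if (is.null(table)) {
      x <- matrix(stats::rnorm(n * feature_dim), n, feature_dim,
                  dimnames = list(sprintf("E%04d", seq_len(n)), NULL))
      table <- representation_table("features", "correlation_centered", x)
      keys <- rownames(x)
    } else {
      if (nrow(table$vectors) < n) stop("table holds fewer than n keys")
      keys <- sample(rownames(table$vectors), n)
      x <- table$vectors[keys, , drop = FALSE]
    }
    if (informative) {
      dims <- sample.int(ncol(x), min(n_signal_dims, ncol(x)))
      w <- stats::rnorm(length(dims), sd = 1) + 0.5
      score <- as.vector(x[, dims, drop = FALSE] %*% w)
      if (noise_sd > 0) score <- score + stats::rnorm(n, sd = noise_sd)
      y <- if (task == "classification") {
        as.integer(score > stats::median(score))
      } else {
        as.vector(scale(score))
      }
    } else {
      y <- if (task == "classification") {
        sample(rep(c(0L, 1L), length.out = n))
      } else {
        stats::rnorm(n)
      }
    }
    targets <- matrix(y, ncol = 1, dimnames = list(keys, "target_1"))
    list(dataset = eval_dataset(keys, targets, task,
                                name = if (informative) "informative"
                                       else "uninformative"),
         table = table)
  })
}
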