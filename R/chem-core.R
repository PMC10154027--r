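# Molecule parsing, standardization filter, circular fingerprints and the
# three pairwise distance metrics used throughout the pipeline.

# -- internal: element bookkeeping -------------------------------------------

.atomic_weights <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("atomprop", package = "ChemmineR", envir = e)
      ap <- get("atomprop", envir = e)
      w <- ap$Atomic_weight
      names(w) <- ap$Symbol
      n <- ap$Number
      names(n) <- ap$Symbol
      cache <<- list(weight = w, number = n)
    }
    cache
  }
})

# default valences used to assign implicit hydrogens; sufficient for the
# HCNOS molecules the standardization filter admits
.default_valence <- c(H = 1, C = 4, N = 3, O = 2, S = 2, P = 3,
                      F = 1, Cl = 1, Br = 1, I = 1)

.parse_formula <- function(mf) {
  m <- regmatches(mf, gregexpr("([A-Z][a-z]?)(\\d*)", mf))[[1]]
  m <- m[nzchar(m)]
  sym <- sub("\\d+$", "", m)
  cnt <- as.integer(sub("^[A-Za-z]+", "", m))
  cnt[is.na(cnt)] <- 1L
  stats::setNames(cnt, sym)
}

# Parse one SMILES into heavy-atom graph + bookkeeping; NULL when OpenBabel
# cannot produce at least one atom.
.parse_smiles <- function(smiles) {
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e) NULL)
  if (is.null(sdf) || length(sdf) == 0) return(NULL)
  mol <- sdf[[1]]
  counts_line <- ChemmineR::header(mol)[["Counts_Line"]]
  natoms <- suppressWarnings(as.integer(substr(counts_line, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts_line, 4, 6)))
  if (is.na(natoms) || natoms < 1) return(NULL)

  if (natoms == 1L) {
    # ChemmineR's block accessors (and sdf2str) misbehave on single-atom
    # molecules; with one atom the SMILES is a single atom token, so take
    # the element symbol from it directly
    symbols <- sub("^\\[?([A-Z][a-z]?).*$", "\\1", trimws(smiles))
    bonds <- matrix(numeric(0), ncol = 3,
                    dimnames = list(NULL, c("a", "b", "order")))
  } else {
    ab <- ChemmineR::atomblock(mol)
    symbols <- sub("_\\d+$", "", rownames(ab))
    if (is.na(nbonds) || nbonds == 0L) {
      bonds <- matrix(numeric(0), ncol = 3,
                      dimnames = list(NULL, c("a", "b", "order")))
    } else {
      bb <- ChemmineR::bondblock(mol)
      bonds <- cbind(a = bb[, 1], b = bb[, 2], order = bb[, 3])
    }
  }

  # per-atom bond-order sum (aromatic code 4 counts 1.5) -> implicit H
  order_val <- ifelse(bonds[, "order"] == 4, 1.5, bonds[, "order"])
  bond_sum <- numeric(natoms)
  if (nrow(bonds)) {
    for (i in seq_len(nrow(bonds))) {
      bond_sum[bonds[i, "a"]] <- bond_sum[bonds[i, "a"]] + order_val[i]
      bond_sum[bonds[i, "b"]] <- bond_sum[bonds[i, "b"]] + order_val[i]
    }
  }
  val <- .default_valence[symbols]
  n_h <- pmax(0, round(ifelse(is.na(val), 0, val) - bond_sum))

  formula <- tryCatch(ChemmineR::MF(sdf, addH = TRUE),
                      error = function(e) NA_character_)
  if (is.na(formula)) {
    comp <- table(symbols)
    hn <- sum(n_h)
    formula_counts <- stats::setNames(as.integer(comp), names(comp))
    if (hn > 0) {
      formula_counts["H"] <- sum(formula_counts["H"], hn, na.rm = TRUE)
    }
  } else {
    formula_counts <- .parse_formula(formula)
  }

  wt <- .atomic_weights()$weight[names(formula_counts)]
  mol_weight <- if (anyNA(wt)) NA_real_ else sum(wt * formula_counts)

  g <- igraph::make_empty_graph(n = natoms, directed = FALSE)
  if (nrow(bonds)) {
    g <- igraph::add_edges(g, as.vector(t(bonds[, c("a", "b"), drop = FALSE])))
  }
  n_frag <- igraph::components(g)$no

  canonical <- tryCatch(
    as.character(ChemmineR::sdf2smiles(sdf)),
    error = function(e) smiles)
  if (length(canonical) != 1 || is.na(canonical) || !nzchar(canonical)) {
    canonical <- smiles
  }

  element_set <- sort(unique(c(symbols,
                               if (sum(formula_counts["H"], na.rm = TRUE) > 0) "H")))
  list(natoms = natoms, symbols = symbols, bonds = bonds, n_h = n_h,
       n_frag = n_frag, mol_weight = mol_weight, element_set = element_set,
       canonical = trimws(canonical))
}

# -- standardization ---------------------------------------------------------

#' Parse a SMILES string and apply the odorant standardization filter
#'
#' Parses one SMILES and applies, in order, the four rejection rules used to
#' standardize olfactory datasets: (1) unparseable input, (2) mixtures (more
#' than one disconnected fragment), (3) single-heavy-atom molecules, (4)
#' molecules containing elements outside the allowed set, (5) molecules
#' heavier than `max_weight` daltons (strict inequality, so a molecule at
#' exactly 500 Da is kept). The first failing rule is reported.
#'
#' @param smiles single SMILES string.
#' @param key identifier carried through the pipeline; defaults to the input
#'   SMILES.
#' @param allowed_elements element symbols permitted in an odorant
#'   (implicit hydrogens count); default `c("H","C","N","O","S")`.
#' @param max_weight rejection threshold in daltons; molecules strictly
#'   heavier are rejected.
#' @return A `molecule_record`: a list with fields `key`, `smiles`
#'   (canonical form when parseable), `input_smiles`, `element_set`,
#'   `heavy_atom_count`, `mol_weight` (Da), `passed`, and `reject_reason`
#'   (`NA` when passed; otherwise one of `"unparseable"`, `"mixture"`,
#'   `"single_atom"`, `"disallowed_element"`, `"too_heavy"`).
#' @examples
#' rec <- parse_and_standardize("CCO")
#' rec$passed
#' rec$mol_weight
#' @export
parse_and_standardize <- function(smiles, key = smiles,
                                  allowed_elements = c("H", "C", "N", "O", "S"),
                                  max_weight = 500) {
  stopifnot(is.character(smiles), length(smiles) == 1, nzchar(smiles))
  p <- .parse_smiles(smiles)
  rec <- list(key = key, smiles = smiles, input_smiles = smiles,
              element_set = character(0), heavy_atom_count = NA_integer_,
              mol_weight = NA_real_, passed = FALSE,
              reject_reason = NA_character_, graph = NULL)
  class(rec) <- "molecule_record"
  if (is.null(p)) {
    rec$reject_reason <- "unparseable"
    return(rec)
  }
  rec$smiles <- p$canonical
  rec$element_set <- p$element_set
  rec$heavy_atom_count <- p$natoms
  rec$mol_weight <- p$mol_weight
  rec$graph <- list(symbols = p$symbols, bonds = p$bonds, n_h = p$n_h)
  if (p$n_frag > 1) {
    rec$reject_reason <- "mixture"
  } else if (p$natoms == 1L) {
    rec$reject_reason <- "single_atom"
  } else if (!all(p$element_set %in% allowed_elements)) {
    rec$reject_reason <- "disallowed_element"
  } else if (!is.na(p$mol_weight) && p$mol_weight > max_weight) {
    rec$reject_reason <- "too_heavy"
  } else {
    rec$passed <- TRUE
  }
  rec
}

#' @export
print.molecule_record <- function(x, ...) {
  status <- if (x$passed) "passed" else paste0("rejected (", x$reject_reason, ")")
  cat(sprintf("<molecule_record> %s: %s [%s, %d heavy atoms, %.2f Da]\n",
              x$key, status, x$smiles,
              ifelse(is.na(x$heavy_atom_count), 0L, x$heavy_atom_count),
              ifelse(is.na(x$mol_weight), 0, x$mol_weight)))
  invisible(x)
}

#' Standardize a dataset of SMILES strings
#'
#' Applies [parse_and_standardize()] to every entry, preserving order and
#' duplicates, and partitions the records into kept and rejected sets.
#'
#' @param smiles_list character vector of SMILES.
#' @param keys optional identifiers, recycled checks apply; defaults to the
#'   SMILES themselves.
#' @inheritParams parse_and_standardize
#' @return list with elements `kept` and `rejected`, each a list of
#'   `molecule_record`s; `c(kept, rejected)` is a permutation-free partition
#'   of the input.
#' @seealso [molecule_table()] for a data-frame view.
#' @export
standardize_dataset <- function(smiles_list, keys = smiles_list,
                                allowed_elements = c("H", "C", "N", "O", "S"),
                                max_weight = 500) {
  stopifnot(length(keys) == length(smiles_list))
  recs <- mapply(function(s, k) parse_and_standardize(
    s, key = k, allowed_elements = allowed_elements, max_weight = max_weight),
    smiles_list, keys, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  passed <- vapply(recs, `[[`, logical(1), "passed")
  list(kept = recs[passed], rejected = recs[!passed])
}

#' Tabulate molecule records
#'
#' @param records list of `molecule_record`s.
#' @return data.frame with columns `key`, `smiles`, `passed`,
#'   `reject_reason`, `mol_weight`, `heavy_atom_count`, `element_set`
#'   (`;`-joined).
#' @export
molecule_table <- function(records) {
  data.frame(
    key = vapply(records, function(r) as.character(r$key), character(1)),
    smiles = vapply(records, `[[`, character(1), "smiles"),
    passed = vapply(records, `[[`, logical(1), "passed"),
    reject_reason = vapply(records, `[[`, character(1), "reject_reason"),
    mol_weight = vapply(records, `[[`, numeric(1), "mol_weight"),
    heavy_atom_count = vapply(records, function(r)
      as.integer(r$heavy_atom_count), integer(1)),
    element_set = vapply(records, function(r)
      paste(r$element_set, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
}

#' Read SMILES from a plain-text or CSV file
#'
#' @param path file path. Plain text is read one SMILES per line; with
#'   `column` set, the file is read as CSV and that column extracted.
#' @param column optional CSV column name holding SMILES.
#' @return character vector of SMILES.
#' @export
read_smiles <- function(path, column = NULL) {
  if (is.null(column)) {
    x <- readLines(path, warn = FALSE)
    x[nzchar(trimws(x))]
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!column %in% names(df)) {
      stop("column '", column, "' not found in ", path)
    }
    as.character(df[[column]])
  }
}

# -- circular fingerprints ---------------------------------------------------

# deterministic integer hash over a tuple, folded modulo 2^31 - 1 (exact in
# double arithmetic: 1000003 * (2^31 - 2) < 2^53)
.hash_tuple <- function(xs) {
  h <- 17
  for (x in xs) h <- (h * 1000003 + (x %% 2147483647)) %% 2147483647
  h
}

# hashed identifier of every circular atom environment at radii 0..radius
.morgan_env_ids <- function(graph, radius) {
  symbols <- graph$symbols
  bonds <- graph$bonds
  n <- length(symbols)
  num <- .atomic_weights()$number[symbols]
  num[is.na(num)] <- 0
  deg <- numeric(n)
  nb <- vector("list", n)
  if (nrow(bonds)) {
    for (i in seq_len(nrow(bonds))) {
      a <- bonds[i, "a"]; b <- bonds[i, "b"]; o <- bonds[i, "order"]
      deg[a] <- deg[a] + 1; deg[b] <- deg[b] + 1
      nb[[a]] <- rbind(nb[[a]], c(b, o))
      nb[[b]] <- rbind(nb[[b]], c(a, o))
    }
  }
  inv <- vapply(seq_len(n), function(i)
    .hash_tuple(c(num[i], deg[i], graph$n_h[i])), numeric(1))
  ids <- list(inv)
  if (radius >= 1) {
    for (k in seq_len(radius)) {
      inv_new <- vapply(seq_len(n), function(i) {
        if (is.null(nb[[i]])) return(.hash_tuple(c(k, inv[i])))
        pairs <- cbind(nb[[i]][, 2], inv[nb[[i]][, 1]])
        ord <- order(pairs[, 1], pairs[, 2])
        .hash_tuple(c(k, inv[i], as.vector(t(pairs[ord, , drop = FALSE]))))
      }, numeric(1))
      ids[[k + 1]] <- inv_new
      inv <- inv_new
    }
  }
  unlist(ids)
}

.check_fp_input <- function(mol) {
  if (!inherits(mol, "molecule_record")) {
    stop("expected a molecule_record")
  }
  if (!isTRUE(mol$passed) || is.null(mol$graph)) {
    stop("fingerprints require a molecule that passed standardization: ",
         mol$key)
  }
}

#' Circular count fingerprint
#'
#' Hashed Morgan-style count fingerprint: every atom contributes one
#' environment identifier per radius `0..radius` (so counts sum to
#' `heavy_atoms * (radius + 1)`), folded into `dim` buckets.
#'
#' @param mol a passed `molecule_record`.
#' @param radius neighborhood radius (bond hops); default 2.
#' @param dim fingerprint length; default 2048.
#' @return object of class `count_fp`: list with integer vector `counts`,
#'   `dim`, `radius`.
#' @export
count_fingerprint <- function(mol, radius = 2, dim = 2048) {
  .check_fp_input(mol)
  stopifnot(radius >= 0, dim >= 1)
  ids <- .morgan_env_ids(mol$graph, radius)
  idx <- (ids %% dim) + 1
  structure(list(counts = tabulate(idx, nbins = dim), dim = dim,
                 radius = radius), class = "count_fp")
}

#' Circular bit fingerprint
#'
#' Binary-support analogue of [count_fingerprint()]: a bit is set when at
#' least one hashed environment falls in its bucket, so at equal `radius`
#' and width the bit vector is the support indicator of the count vector.
#'
#' @inheritParams count_fingerprint
#' @param n_bits fingerprint length; default 2048.
#' @return object of class `bit_fp`: list with logical vector `bits`,
#'   `n_bits`, `radius`.
#' @export
bit_fingerprint <- function(mol, radius = 2, n_bits = 2048) {
  .check_fp_input(mol)
  stopifnot(radius >= 0, n_bits >= 1)
  ids <- .morgan_env_ids(mol$graph, radius)
  idx <- (ids %% n_bits) + 1
  bits <- logical(n_bits)
  bits[idx] <- TRUE
  structure(list(bits = bits, n_bits = n_bits, radius = radius),
            class = "bit_fp")
}

# -- distances ---------------------------------------------------------------

.as_bits <- function(x) {
  if (inherits(x, "bit_fp")) x$bits else as.logical(x)
}

#' Tanimoto distance between bit fingerprints
#'
#' One minus the Jaccard similarity of the two supports. Two all-zero
#' fingerprints are identical objects and get distance 0 (the case cannot
#' arise for standardized molecules but keeps the function total).
#'
#' @param a,b `bit_fp` objects or logical/0-1 vectors of equal length.
#' @return distance in `[0, 1]`.
#' @export
tanimoto_distance <- function(a, b) {
  av <- .as_bits(a); bv <- .as_bits(b)
  if (length(av) != length(bv)) {
    stop("bit fingerprints have mismatched lengths: ",
         length(av), " vs ", length(bv))
  }
  uni <- sum(av | bv)
  if (uni == 0) return(0)
  1 - sum(av & bv) / uni
}

.as_counts <- function(x) {
  if (inherits(x, "count_fp")) x$counts else as.numeric(x)
}

#' L1 (edit) distance between count fingerprints
#'
#' Sum of absolute coordinate differences between two count fingerprints;
#' a proxy for the number of substructure-environment edits separating two
#' molecules.
#'
#' @param a,b `count_fp` objects or numeric vectors of equal length.
#' @return non-negative real, integer-valued on integer inputs.
#' @export
cfp_edit_distance <- function(a, b) {
  av <- .as_counts(a); bv <- .as_counts(b)
  if (length(av) != length(bv)) {
    stop("count fingerprints have mismatched dims: ",
         length(av), " vs ", length(bv))
  }
  sum(abs(av - bv))
}

#' Correlation distance between two vectors
#'
#' `1 - cor(u, v)` across coordinates. Callers comparing embedding rows are
#' expected to have centered each dimension across the analysis population
#' first (see [center_rows()]); the population defines the metric.
#'
#' @param u,v numeric vectors of equal length `>= 2`, neither constant.
#' @return distance in `[0, 2]`.
#' @export
correlation_distance <- function(u, v) {
  stopifnot(is.numeric(u), is.numeric(v))
  if (length(u) != length(v)) stop("vectors have mismatched widths")
  if (length(u) < 2) stop("correlation distance needs width >= 2")
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    stop("correlation distance undefined for a constant vector")
  }
  1 - stats::cor(u, v)
}

#' Center a molecule-by-dimension matrix across the population
#'
#' Subtracts each column's mean so every dimension has mean zero over the
#' given population of molecules. Idempotent; row order preserved.
#'
#' @param table numeric matrix, one row per molecule (`>= 2` rows).
#' @return centered matrix of identical shape.
#' @export
center_rows <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2) stop("centering needs at least 2 rows")
  sweep(table, 2, colMeans(table), "-")
}
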