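# Essential-oil co-occurrence labels, global distance ranks and the
# rank-shift statistic compared across representations.

.pair_id <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Construct an oil-composition dataset
#'
#' @param oils named list: oil name -> character vector of molecule keys.
#' @param molecules optional ordered molecule universe; defaults to (and
#'   must be a superset of) the union of all oil member sets.
#' @return object of class `oil_dataset` with fields `oils` and
#'   `molecules`.
#' @export
oil_dataset <- function(oils, molecules = NULL) {
  if (is.null(names(oils)) || any(!nzchar(names(oils)))) {
    stop("every oil needs a name")
  }
  empty <- names(oils)[lengths(oils) == 0]
  if (length(empty)) {
    stop("empty oil(s): ", paste(empty, collapse = ", "))
  }
  union_keys <- sort(unique(unlist(oils)))
  if (is.null(molecules)) {
    molecules <- union_keys
  } else if (!all(union_keys %in% molecules)) {
    stop("oil member(s) outside the molecule universe")
  }
  structure(list(oils = lapply(oils, unique), molecules = molecules),
            class = "oil_dataset")
}

#' @export
print.oil_dataset <- function(x, ...) {
  cat(sprintf("<oil_dataset> %d oils over %d molecules\n",
              length(x$oils), length(x$molecules)))
  invisible(x)
}

#' Read an oil-composition file
#'
#' Accepts JSON (`{"oil": ["key", ...], ...}`) or two-column CSV with
#' columns `oil`, `key`.
#'
#' @param path file path; format chosen by `.json` extension.
#' @return an `oil_dataset`.
#' @export
read_oils <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    oils <- jsonlite::read_json(path, simplifyVector = TRUE)
    oils <- lapply(oils, as.character)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("oil", "key") %in% names(df))) {
      stop("oil CSV needs columns oil, key")
    }
    oils <- split(df$key, df$oil)
  }
  oil_dataset(oils)
}

#' Label every molecule pair by essential-oil co-occurrence
#'
#' Enumerates all `N (N - 1) / 2` unordered pairs of the dataset's
#' molecule universe and labels a pair `TRUE` when the two molecules
#' appear together in at least one oil.
#'
#' @param oils an `oil_dataset` with `>= 2` molecules.
#' @return data.frame `key_a`, `key_b`, `cooccur` covering the full pair
#'   universe.
#' @export
cooccurrence_labels <- function(oils) {
  stopifnot(inherits(oils, "oil_dataset"))
  mols <- oils$molecules
  n <- length(mols)
  if (n < 2) stop("need at least 2 molecules")
  idx <- utils::combn(n, 2)
  pairs <- data.frame(key_a = mols[idx[1, ]], key_b = mols[idx[2, ]],
                      stringsAsFactors = FALSE)
  seen <- new.env(hash = TRUE, size = nrow(pairs))
  for (members in oils$oils) {
    pos <- match(members, mols)
    if (length(pos) < 2) next
    mi <- utils::combn(sort(pos), 2)
    ids <- .pair_id(mols[mi[1, ]], mols[mi[2, ]])
    for (id in ids) assign(id, TRUE, envir = seen)
  }
  pairs$cooccur <- vapply(.pair_id(pairs$key_a, pairs$key_b),
                          function(id) exists(id, envir = seen,
                                              inherits = FALSE),
                          logical(1), USE.NAMES = FALSE)
  pairs
}

#' Rank all pairwise distances from small to large
#'
#' Assigns ranks `1..P` over the unordered pair universe of a distance
#' matrix, ascending by distance, with tied distances receiving the
#' average of their rank positions (keeping rank-sum identities exact).
#'
#' @param dm a `distance_matrix`.
#' @return data.frame `key_a`, `key_b`, `distance`, `rank`, with the
#'   source representation name in attribute `representation`.
#' @export
ranked_distances <- function(dm) {
  stopifnot(inherits(dm, "distance_matrix"))
  keys <- dm$keys
  n <- length(keys)
  if (n < 2) stop("need at least 2 keys")
  idx <- utils::combn(n, 2)
  d <- dm$values[cbind(idx[1, ], idx[2, ])]
  out <- data.frame(key_a = keys[idx[1, ]], key_b = keys[idx[2, ]],
                    distance = d, rank = rank(d, ties.method = "average"),
                    stringsAsFactors = FALSE)
  attr(out, "representation") <- dm$representation
  out
}

.align_pairs <- function(a, b, what = "pair universes") {
  ia <- .pair_id(a$key_a, a$key_b)
  ib <- .pair_id(b$key_a, b$key_b)
  m <- match(ia, ib)
  if (anyNA(m) || length(ia) != length(ib)) {
    stop("mismatched ", what)
  }
  m
}

#' Rank shift of co-occurring and non-co-occurring pairs
#'
#' Average shift in distance rank relative to the expected rank
#' `(P + 1) / 2` of a uniformly random pair, per label group; negative
#' values mean the group sits nearer than chance. 95% CIs use the normal
#' approximation over the group.
#'
#' @param ranks data.frame from [ranked_distances()].
#' @param labels data.frame from [cooccurrence_labels()] over the same
#'   pair universe.
#' @param representation name reported in the result; defaults to the
#'   `representation` attribute of `ranks`.
#' @param normalize also report shifts divided by `P` (fraction of the
#'   rank range) for cross-dataset comparability.
#' @return object of class `rank_shift_result`.
#' @export
rank_shift <- function(ranks, labels, representation = NULL,
                       normalize = FALSE) {
  m <- .align_pairs(ranks, labels)
  lab <- labels$cooccur[m]
  if (!any(lab) || all(lab)) stop("both label classes must be non-empty")
  p_total <- nrow(ranks)
  expected <- (p_total + 1) / 2
  grp <- function(r) {
    list(shift = mean(r) - expected,
         ci95 = mean(r) - expected +
           c(-1, 1) * 1.96 * stats::sd(r) / sqrt(length(r)))
  }
  co <- grp(ranks$rank[lab])
  non <- grp(ranks$rank[!lab])
  if (is.null(representation)) {
    representation <- attr(ranks, "representation")
    if (is.null(representation)) representation <- "unnamed"
  }
  out <- list(representation = representation, n_pairs = p_total,
              n_cooccurring = sum(lab),
              shift_cooccurring = co$shift, ci95_cooccurring = co$ci95,
              shift_non = non$shift, ci95_non = non$ci95)
  if (normalize) {
    out$shift_cooccurring_frac <- co$shift / p_total
    out$shift_non_frac <- non$shift / p_total
  }
  structure(out, class = "rank_shift_result")
}

#' @export
print.rank_shift_result <- function(x, ...) {
  cat(sprintf(
    paste0("<rank_shift_result> %s: co-occurring %.1f ",
           "[%.1f, %.1f] (n=%d), non %.2f [%.2f, %.2f] (P=%d)\n"),
    x$representation, x$shift_cooccurring, x$ci95_cooccurring[1],
    x$ci95_cooccurring[2], x$n_cooccurring, x$shift_non, x$ci95_non[1],
    x$ci95_non[2], x$n_pairs))
  invisible(x)
}

#' Compare rank shifts between representations
#'
#' Paired t-tests of per-pair rank differences between every pair of
#' representations, computed separately over co-occurring and
#' non-co-occurring pairs.
#'
#' @param rank_list named list of [ranked_distances()] outputs over one
#'   identical pair universe.
#' @param labels [cooccurrence_labels()] output for the same universe.
#' @return named list (one entry per representation pair, `"A_vs_B"`) of
#'   lists with elements `cooccurring` and `non_cooccurring`, each a
#'   `paired_test_result` on rank differences `A - B`.
#' @export
compare_rank_shifts <- function(rank_list, labels) {
  stopifnot(length(rank_list) >= 2, !is.null(names(rank_list)))
  nms <- names(rank_list)
  ref <- rank_list[[1]]
  aligned <- lapply(rank_list, function(r) r$rank[.align_pairs(ref, r)])
  lab <- labels$cooccur[.align_pairs(ref, labels)]
  out <- list()
  for (i in seq_len(length(nms) - 1)) {
    for (j in seq(i + 1, length(nms))) {
      key <- paste0(nms[i], "_vs_", nms[j])
      out[[key]] <- list(
        cooccurring = paired_t_test(aligned[[i]][lab], aligned[[j]][lab]),
        non_cooccurring = paired_t_test(aligned[[i]][!lab],
                                        aligned[[j]][!lab]))
    }
  }
  out
}
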