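# Pathway smoothness: PCA projection, per-intermediate smoothness ratios,
# 2D trajectory coordinates and the paired comparison between
# representations.

#' PCA configuration
#'
#' @param n_components dimensionality of the compressed space (default 64);
#'   capped at run time by the data rank.
#' @param n_view leading components used for 2D visualization (default 2).
#' @return object of class `pca_config`.
#' @export
pca_config <- function(n_components = 64, n_view = 2) {
  stopifnot(n_components >= 1, n_view >= 1, n_view <= n_components)
  structure(list(n_components = n_components, n_view = n_view),
            class = "pca_config")
}

#' Project representation vectors onto principal components
#'
#' Fits PCA on the centered matrix of the given key population and returns
#' scores on the top `min(n_components, n_keys - 1, width)` components,
#' ordered by decreasing explained variance.
#'
#' @param table a `representation_table`.
#' @param keys ordered molecule keys (`>= 3`).
#' @param cfg a [pca_config()].
#' @return numeric matrix (key x component) with attribute
#'   `explained_variance`, the per-component variance fractions.
#' @export
pca_project <- function(table, keys, cfg = pca_config()) {
  stopifnot(inherits(table, "representation_table"))
  if (length(keys) < 3) stop("PCA projection needs at least 3 keys")
  absent <- setdiff(keys, rownames(table$vectors))
  if (length(absent)) {
    stop("key(s) missing from table '", table$name, "': ",
         paste(absent, collapse = ", "))
  }
  x <- table$vectors[keys, , drop = FALSE]
  k <- min(cfg$n_components, length(keys) - 1, ncol(x))
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  scores <- p$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- keys
  attr(scores, "explained_variance") <- (p$sdev^2 / sum(p$sdev^2))[seq_len(k)]
  scores
}

#' Smoothness ratio of an intermediate point
#'
#' Direct Euclidean distance between the start and end coordinates divided
#' by the path length through the intermediate:
#' `d(start, end) / (d(start, intermediate) + d(intermediate, end))`.
#' By the triangle inequality the ratio lies in `(0, 1]`, reaching 1
#' exactly when the intermediate sits on the closed segment.
#'
#' @param start,intermediate,end numeric coordinate vectors of equal width.
#' @return ratio in `(0, 1]`.
#' @export
smoothness_ratio <- function(start, intermediate, end) {
  stopifnot(length(start) == length(end),
            length(intermediate) == length(start))
  d_dir <- sqrt(sum((start - end)^2))
  if (d_dir == 0) stop("smoothness undefined: start and end coincide")
  d_path <- sqrt(sum((start - intermediate)^2)) +
    sqrt(sum((intermediate - end)^2))
  if (d_path == 0) stop("smoothness undefined: degenerate path")
  d_dir / d_path
}

#' Score the smoothness of metabolic pathways in a representation
#'
#' Fits PCA once on the union of all pathway members, then computes one
#' smoothness ratio per (pathway, intermediate). In `endpoint` mode (the
#' default) each intermediate `X` of pathway `A..Z` is scored as
#' `d(A,Z) / (d(A,X) + d(X,Z))`; in `consecutive` mode triplets of
#' consecutive members `(X[i-1], X[i], X[i+1])` are scored instead.
#'
#' @param pathways named list of ordered molecule-key vectors, each of
#'   length `>= 3`.
#' @param table a `representation_table`.
#' @param cfg a [pca_config()].
#' @param mode `"endpoint"` or `"consecutive"`.
#' @return data.frame of smoothness records: `pathway_id`, `intermediate`,
#'   `start`, `end`, `smoothness`.
#' @export
score_pathways <- function(pathways, table, cfg = pca_config(),
                           mode = c("endpoint", "consecutive")) {
  mode <- match.arg(mode)
  if (is.null(names(pathways))) {
    names(pathways) <- paste0("pathway_", seq_along(pathways))
  }
  lens <- lengths(pathways)
  if (any(lens < 3)) {
    stop("pathway(s) with fewer than 3 members: ",
         paste(names(pathways)[lens < 3], collapse = ", "))
  }
  members <- unique(unlist(pathways))
  absent <- setdiff(members, rownames(table$vectors))
  if (length(absent)) {
    stop("pathway member(s) missing from table '", table$name, "': ",
         paste(absent, collapse = ", "))
  }
  proj <- pca_project(table, members, cfg)
  rows <- list()
  for (pid in names(pathways)) {
    p <- pathways[[pid]]
    for (i in seq(2, length(p) - 1)) {
      ends <- if (mode == "endpoint") c(p[1], p[length(p)])
              else c(p[i - 1], p[i + 1])
      rows[[length(rows) + 1]] <- data.frame(
        pathway_id = pid, intermediate = p[i],
        start = ends[1], end = ends[2],
        smoothness = smoothness_ratio(proj[ends[1], ], proj[p[i], ],
                                      proj[ends[2], ]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired t-test
#'
#' Closed-form paired t-test on two aligned samples:
#' `t = mean(a - b) / (sd(a - b) / sqrt(n))` with `n - 1` degrees of
#' freedom.
#'
#' @param a,b numeric vectors of equal length `n >= 2`; the differences
#'   must not all be zero.
#' @param sided `"two_sided"` or `"greater"` (tests `mean(a - b) > 0`).
#' @return object of class `paired_test_result`: `n`, `mean_diff`,
#'   `t_statistic`, `p_value`, `sided`.
#' @export
paired_t_test <- function(a, b, sided = c("two_sided", "greater")) {
  sided <- match.arg(sided)
  if (length(a) != length(b)) stop("paired samples differ in length")
  n <- length(a)
  if (n < 2) stop("paired t-test needs n >= 2")
  d <- a - b
  s <- stats::sd(d)
  if (s <= 1e-12 * max(1, abs(mean(d)))) {
    stop("paired differences are zero or constant: ",
         "t statistic undefined")
  }
  t_stat <- mean(d) / (s / sqrt(n))
  p <- if (sided == "two_sided") {
    2 * stats::pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  } else {
    stats::pt(t_stat, df = n - 1, lower.tail = FALSE)
  }
  structure(list(n = n, mean_diff = mean(d), t_statistic = t_stat,
                 p_value = p, sided = sided),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf(
    "<paired_test_result> n = %d, mean diff = %.4g, t = %.3f, p = %.3g (%s)\n",
    x$n, x$mean_diff, x$t_statistic, x$p_value, x$sided))
  invisible(x)
}

#' First-two-component view coordinates
#'
#' @param projection matrix from [pca_project()] with `>= 2` components.
#' @param keys keys to extract (default: all rows, in projection order).
#' @return data.frame `key`, `pc1`, `pc2` for trajectory plotting.
#' @export
view_coordinates <- function(projection, keys = rownames(projection)) {
  if (ncol(projection) < 2) stop("projection has fewer than 2 components")
  data.frame(key = keys, pc1 = projection[keys, 1], pc2 = projection[keys, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Plot a pathway trajectory in the first two principal components
#'
#' Convenience plot of one pathway's ordered members in PCA view
#' coordinates; written to `path` as PNG when given.
#'
#' @param projection matrix from [pca_project()].
#' @param pathway ordered key vector.
#' @param path optional PNG output path.
#' @param main plot title.
#' @export
plot_pathway_trajectory <- function(projection, pathway, path = NULL,
                                    main = "pathway trajectory") {
  vc <- view_coordinates(projection, pathway)
  draw <- function() {
    graphics::plot(vc$pc1, vc$pc2, type = "o", pch = 19,
                   xlab = "PC1", ylab = "PC2", main = main)
    graphics::text(vc$pc1, vc$pc2, labels = vc$key, pos = 3, cex = 0.7)
    graphics::arrows(vc$pc1[-nrow(vc)], vc$pc2[-nrow(vc)],
                     vc$pc1[-1], vc$pc2[-1], length = 0.08)
  }
  if (!is.null(path)) {
    grDevices::png(path, width = 700, height = 600)
    on.exit(grDevices::dev.off())
    draw()
    return(invisible(path))
  }
  draw()
  invisible(NULL)
}
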