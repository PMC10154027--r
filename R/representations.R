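# Named representation tables (embeddings, count/bit fingerprints) and the
# pairwise distance matrices induced by each table's metric.

.rep_metrics <- c("correlation_centered", "tanimoto", "l1")

#' Construct a representation table
#'
#' A named mapping from molecule key to a fixed-width real vector, tagged
#' with the distance metric under which the table is compared:
#' `correlation_centered` for embeddings (POM-style), `tanimoto` for bit
#' fingerprints, `l1` for count fingerprints.
#'
#' @param name table name used in result objects.
#' @param metric one of `"correlation_centered"`, `"tanimoto"`, `"l1"`.
#' @param vectors numeric matrix with molecule keys as row names.
#' @return object of class `representation_table`.
#' @export
representation_table <- function(name, metric, vectors) {
  metric <- match.arg(metric, .rep_metrics)
  vectors <- as.matrix(vectors)
  if (is.logical(vectors)) vectors <- vectors * 1
  if (is.null(rownames(vectors))) {
    stop("representation vectors need molecule keys as row names")
  }
  if (anyDuplicated(rownames(vectors))) {
    stop("duplicate molecule key(s): ",
         paste(unique(rownames(vectors)[duplicated(rownames(vectors))]),
               collapse = ", "))
  }
  if (!is.numeric(vectors)) stop("representation vectors must be numeric")
  structure(list(name = name, metric = metric, vectors = vectors),
            class = "representation_table")
}

#' @export
print.representation_table <- function(x, ...) {
  cat(sprintf("<representation_table> %s: %d molecules x %d dims (%s)\n",
              x$name, nrow(x$vectors), ncol(x$vectors), x$metric))
  invisible(x)
}

#' Load a representation table from CSV
#'
#' Expects a `key` column (or the first column) followed by numeric columns
#' `v0..v{d-1}`. Ragged rows, duplicate keys and non-numeric cells are
#' rejected with the offending row named.
#'
#' @param path CSV path.
#' @param name table name.
#' @param metric distance metric tag (see [representation_table()]).
#' @return a `representation_table`.
#' @export
load_table <- function(path, name, metric) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("representation CSV needs a key column plus values")
  key_col <- if ("key" %in% names(df)) "key" else names(df)[1]
  keys <- df[[key_col]]
  dup <- keys[duplicated(keys)]
  if (length(dup)) {
    stop("duplicate key(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  val_cols <- setdiff(names(df), key_col)
  vals <- suppressWarnings(
    vapply(df[val_cols], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(keys, val_cols))
  bad <- which(apply(vals, 1, anyNA))
  if (length(bad)) {
    stop("non-numeric or missing cell(s) in ", path, " at row(s) keyed: ",
         paste(keys[utils::head(bad, 5)], collapse = ", "))
  }
  representation_table(name, metric, vals)
}

#' Write a representation table to CSV
#'
#' Full-precision round-trip counterpart of [load_table()].
#'
#' @param table a `representation_table`.
#' @param path output CSV path.
#' @export
write_table <- function(table, path) {
  stopifnot(inherits(table, "representation_table"))
  df <- data.frame(key = rownames(table$vectors), stringsAsFactors = FALSE)
  vals <- table$vectors
  colnames(vals) <- paste0("v", seq_len(ncol(vals)) - 1)
  df <- cbind(df, as.data.frame(format(vals, digits = 17, trim = TRUE,
                                       scientific = TRUE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pairwise distance matrix under a table's metric
#'
#' For `correlation_centered` tables the requested keys define the
#' centering population: each dimension is centered over exactly those
#' molecules before pairwise correlation distances are taken, so the same
#' pair can legitimately get different distances under different
#' populations. Fingerprint metrics (`tanimoto`, `l1`) are
#' population-independent.
#'
#' @param table a `representation_table`.
#' @param keys ordered molecule keys (`>= 2`, all present in the table).
#' @return object of class `distance_matrix`: list with `keys` and the
#'   symmetric zero-diagonal matrix `values`.
#' @export
distance_matrix <- function(table, keys) {
  stopifnot(inherits(table, "representation_table"))
  if (length(keys) < 2) stop("need at least 2 keys")
  if (anyDuplicated(keys)) stop("duplicate keys in request")
  absent <- setdiff(keys, rownames(table$vectors))
  if (length(absent)) {
    stop("key(s) missing from table '", table$name, "': ",
         paste(absent, collapse = ", "))
  }
  x <- table$vectors[keys, , drop = FALSE]
  vals <- switch(table$metric,
    correlation_centered = {
      xc <- center_rows(x)
      sds <- apply(xc, 1, stats::sd)
      if (any(sds == 0)) {
        stop("constant vector(s) after centering: ",
             paste(keys[sds == 0], collapse = ", "))
      }
      1 - stats::cor(t(xc))
    },
    l1 = as.matrix(stats::dist(x, method = "manhattan")),
    tanimoto = {
      b <- x > 0
      inter <- tcrossprod(b * 1)
      ones <- rowSums(b)
      uni <- outer(ones, ones, "+") - inter
      d <- ifelse(uni == 0, 0, 1 - inter / uni)
      d
    })
  vals <- (vals + t(vals)) / 2
  diag(vals) <- 0
  dimnames(vals) <- list(keys, keys)
  structure(list(keys = keys, values = vals, representation = table$name),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d molecules, range [%.4g, %.4g]\n",
              length(x$keys), min(x$values), max(x$values[x$values > 0], 0)))
  invisible(x)
}

#' Write a distance matrix as CSV with key header row/column
#' @param dm a `distance_matrix`.
#' @param path output path.
#' @export
write_distance_matrix <- function(dm, path) {
  utils::write.csv(as.data.frame(dm$values), path, row.names = TRUE)
  invisible(path)
}
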