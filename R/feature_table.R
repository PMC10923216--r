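#' Feature (ASV) activity table
#'
#' The pipeline's central object: a features x samples matrix of nonnegative
#' counts (raw tables) or per-sample proportions (after
#' [to_relative_activity()]). Feature and sample identifiers live in the
#' matrix dimnames and must be unique.
#'
#' @param counts numeric matrix, features in rows, samples in columns, with
#'   unique non-empty dimnames.
#' @param is_relative logical; `TRUE` when each sample column sums to 1.
#' @return An object of class `feature_table` with elements `counts` and
#'   `is_relative`.
#' @examples
#' ft <- feature_table(matrix(1:4, 2, 2,
#'   dimnames = list(c("asv1", "asv2"), c("s1", "s2"))))
#' feature_ids(ft)
#' @export
feature_table <- function(counts, is_relative = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix (features x samples)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    stop("duplicate feature identifier(s): ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- unique(colnames(counts)[duplicated(colnames(counts))])
    stop("duplicate sample identifier(s): ", paste(dup, collapse = ", "))
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be nonnegative and non-missing")
  }
  if (isTRUE(is_relative)) {
    tot <- colSums(counts)
    bad <- which(tot > 0 & abs(tot - 1) > 1e-9)
    if (length(bad)) {
      stop("relative table columns must sum to 1: ",
           paste(colnames(counts)[bad], collapse = ", "))
    }
  }
  structure(list(counts = counts, is_relative = isTRUE(is_relative)),
            class = "feature_table")
}

#' @rdname feature_table
#' @param x a `feature_table`.
#' @export
feature_ids <- function(x) rownames(x$counts)

#' @rdname feature_table
#' @export
sample_ids <- function(x) colnames(x$counts)

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$is_relative) "relative activity" else "raw counts"))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' Subset a feature table by feature and/or sample identifiers
#'
#' @param x a `feature_table`.
#' @param features,samples character vectors of identifiers to keep
#'   (default: all, in current order).
#' @return a `feature_table`. Relative tables are re-flagged raw if columns
#'   no longer sum to one (e.g. after dropping features).
#' @export
subset_table <- function(x, features = feature_ids(x), samples = sample_ids(x)) {
  stopifnot(inherits(x, "feature_table"))
  missing_f <- setdiff(features, feature_ids(x))
  if (length(missing_f)) stop("unknown feature(s): ", paste(missing_f, collapse = ", "))
  missing_s <- setdiff(samples, sample_ids(x))
  if (length(missing_s)) stop("unknown sample(s): ", paste(missing_s, collapse = ", "))
  m <- x$counts[features, samples, drop = FALSE]
  rel <- x$is_relative && all(abs(colSums(m) - 1) <= 1e-9 | colSums(m) == 0)
  feature_table(m, is_relative = rel)
}

# canonical lineage ranks, most to least inclusive
TAXONOMIC_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                     "genus", "species")

UNASSIGNED <- "unassigned"
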