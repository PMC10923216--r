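#' Read a feature count table from TSV
#'
#' Tab-separated with a header row; the first column holds identifiers.
#' Both orientations circulate in amplicon work, so the orientation is an
#' explicit argument; internally tables are always features x samples.
#'
#' @param path file path.
#' @param orientation `"features-in-rows"` (default) or `"samples-in-rows"`.
#' @param is_relative logical, passed to [feature_table()].
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path,
                               orientation = c("features-in-rows",
                                               "samples-in-rows"),
                               is_relative = FALSE) {
  orientation <- match.arg(orientation)
  df <- read_tsv_strict(path)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(sprintf("%s: duplicate identifier(s) in column 1: %s",
                 path, paste(dup, collapse = ", ")))
  }
  num <- df[-1L]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) & !is.na(num[[j]]))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric cell at row %d, column '%s'",
                   path, bad[1L], names(num)[j]))
    }
    num[[j]] <- v
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  if (orientation == "samples-in-rows") m <- t(m)
  feature_table(m, is_relative = is_relative)
}

#' Write a feature table to TSV
#'
#' @param x a `feature_table`.
#' @param path output path.
#' @param id_column header for the identifier column.
#' @export
write_feature_table <- function(x, path, id_column = "feature_id") {
  stopifnot(inherits(x, "feature_table"))
  df <- data.frame(id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table from TSV
#'
#' One row per feature; columns are the canonical ranks
#' kingdom...species. Missing or empty rank cells become `"unassigned"`.
#'
#' @param path file path.
#' @return data.frame with columns `feature_id` and the seven canonical ranks.
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv_strict(path)
  names(df)[1L] <- "feature_id"
  names(df) <- tolower(names(df))
  unknown <- setdiff(names(df), c("feature_id", TAXONOMIC_RANKS))
  if (length(unknown)) {
    stop(sprintf("%s: unknown rank header(s): %s", path,
                 paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(df$feature_id)) {
    dup <- unique(df$feature_id[duplicated(df$feature_id)])
    stop(sprintf("%s: feature listed twice: %s", path,
                 paste(dup, collapse = ", ")))
  }
  for (r in TAXONOMIC_RANKS) {
    if (is.null(df[[r]])) df[[r]] <- UNASSIGNED
    v <- as.character(df[[r]])
    v[is.na(v) | !nzchar(trimws(v)) | v == "NA"] <- UNASSIGNED
    df[[r]] <- v
  }
  df[c("feature_id", TAXONOMIC_RANKS)]
}

#' @rdname read_taxonomy
#' @param taxonomy taxonomy data.frame as returned by `read_taxonomy()`.
#' @param path output path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' First column is the sample identifier; a `community` column (site label)
#' is required for group-based statistics. `water_type`, when present, must
#' be `Freshwater` or `Saltwater`. Missing values (`NA` or empty cells) are
#' kept as `NA`, never imputed; analyses that need a variable drop incomplete
#' samples and report how many.
#'
#' @param path file path.
#' @return data.frame with column `sample_id` first.
#' @export
read_metadata <- function(path) {
  df <- read_tsv_strict(path, na = c("NA", ""))
  names(df)[1L] <- "sample_id"
  if (anyDuplicated(df$sample_id)) {
    dup <- unique(df$sample_id[duplicated(df$sample_id)])
    stop(sprintf("%s: duplicate sample id(s): %s", path,
                 paste(dup, collapse = ", ")))
  }
  if (!is.null(df$water_type)) {
    ok <- is.na(df$water_type) | df$water_type %in% c("Freshwater", "Saltwater")
    if (!all(ok)) {
      stop(sprintf("%s: water_type must be Freshwater or Saltwater (got: %s)",
                   path, paste(unique(df$water_type[!ok]), collapse = ", ")))
    }
  }
  df
}

#' @rdname read_metadata
#' @param metadata metadata data.frame.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write a rooted phylogenetic tree (Newick)
#'
#' Thin wrappers over \pkg{ape} that enforce the pipeline's invariants:
#' unique leaf labels, finite nonnegative branch lengths.
#'
#' @param path Newick file.
#' @return an `ape::phylo` tree.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop(sprintf("%s: not a parseable Newick tree", path))
  validate_tree(tree, where = path)
  tree
}

#' @rdname read_tree
#' @param tree an `ape::phylo` object.
#' @export
write_tree <- function(tree, path) {
  validate_tree(tree)
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

validate_tree <- function(tree, where = "tree") {
  if (!inherits(tree, "phylo")) stop(where, ": not a phylo object")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop(sprintf("%s: duplicate leaf label(s): %s", where,
                 paste(dup, collapse = ", ")))
  }
  if (is.null(tree$edge.length)) stop(where, ": tree has no branch lengths")
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    stop(where, ": non-finite branch length")
  }
  if (any(tree$edge.length < 0)) stop(where, ": negative branch length")
  invisible(tree)
}

#' Read / write a distance matrix as TSV
#'
#' Square symmetric layout with identifiers as both header and first column.
#'
#' @param path file path.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
read_distance_matrix <- function(path) {
  ft <- read_feature_table(path)
  m <- ft$counts
  validate_distance_matrix(m, where = path)
  m
}

#' @rdname read_distance_matrix
#' @param d symmetric matrix or `dist`.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  validate_distance_matrix(m)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_distance_matrix <- function(m, where = "distance matrix") {
  if (nrow(m) != ncol(m) || is.null(rownames(m)) ||
      !identical(rownames(m), colnames(m))) {
    stop(where, ": must be square with matching row/column identifiers")
  }
  if (any(m < 0)) stop(where, ": negative distances")
  if (max(abs(m - t(m))) > 1e-12) stop(where, ": asymmetric beyond 1e-12")
  if (any(abs(diag(m)) > 1e-12)) stop(where, ": nonzero diagonal")
  invisible(m)
}

#' Cross-validate the four pipeline inputs
#'
#' Checks that table features are covered by taxonomy and tree, and table
#' samples by metadata (and conversely reports unused entries). In strict
#' mode any table feature/sample lacking annotation is an error; in
#' permissive mode the table (and companions) are subset to the consistent
#' intersection and the dropped identifiers are reported.
#'
#' @param table a `feature_table`.
#' @param taxonomy taxonomy data.frame ([read_taxonomy()]).
#' @param metadata metadata data.frame ([read_metadata()]).
#' @param tree `phylo` tree over features, or `NULL` when no phylogenetic
#'   method will be run.
#' @param strict logical.
#' @return list with `table`, `taxonomy`, `metadata`, `tree` (subset in
#'   permissive mode) and `report`, a list of dropped/unused identifier sets.
#' @export
validate_dataset <- function(table, taxonomy, metadata, tree = NULL,
                             strict = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  f <- feature_ids(table)
  s <- sample_ids(table)
  report <- list(
    features_missing_taxonomy = setdiff(f, taxonomy$feature_id),
    features_missing_tree = if (is.null(tree)) character(0) else
      setdiff(f, tree$tip.label),
    samples_missing_metadata = setdiff(s, metadata$sample_id),
    taxonomy_unused = setdiff(taxonomy$feature_id, f),
    tree_unused = if (is.null(tree)) character(0) else
      setdiff(tree$tip.label, f),
    metadata_unused = setdiff(metadata$sample_id, s)
  )
  bad <- c(report$features_missing_taxonomy, report$features_missing_tree,
           report$samples_missing_metadata)
  if (strict && length(bad)) {
    stop("dataset inconsistency (strict mode): ",
         paste(utils::head(unique(bad), 10), collapse = ", "))
  }
  keep_f <- setdiff(f, c(report$features_missing_taxonomy,
                         report$features_missing_tree))
  keep_s <- setdiff(s, report$samples_missing_metadata)
  if (length(bad)) {
    message(sprintf("validate_dataset: dropped %d feature(s) and %d sample(s)",
                    length(f) - length(keep_f), length(s) - length(keep_s)))
  }
  out_table <- subset_table(table, keep_f, keep_s)
  out_tree <- tree
  if (!is.null(tree) && length(report$tree_unused)) {
    out_tree <- ape::keep.tip(tree, keep_f)
  }
  list(table = out_table,
       taxonomy = taxonomy[taxonomy$feature_id %in% keep_f, , drop = FALSE],
       metadata = metadata[metadata$sample_id %in% keep_s, , drop = FALSE],
       tree = out_tree,
       report = report)
}

# strict TSV reader shared by the readers above: header + >= 1 column,
# ragged rows rejected with their position
read_tsv_strict <- function(path, na = "NA") {
  lines <- readLines(path)
  if (!length(lines)) stop(path, ": empty file")
  # field count = tab count + 1 (strsplit would drop trailing empties)
  widths <- nchar(gsub("[^\t]", "", lines)) + 1L
  if (length(unique(widths)) > 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("%s: ragged row %d (%d fields, expected %d)",
                 path, bad, widths[bad], widths[1L]))
  }
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", check.names = FALSE,
                    na.strings = na, colClasses = "character",
                    stringsAsFactors = FALSE) -> df
  # re-type columns that are fully numeric (identifiers stay character)
  for (j in seq_along(df)[-1L]) {
    v <- df[[j]]
    vn <- suppressWarnings(as.numeric(v))
    if (!any(is.na(vn) & !is.na(v))) df[[j]] <- vn
  }
  df
}
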