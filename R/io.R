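# Readers / writers for every plain-text format the tool touches.
# All files are UTF-8, tab-delimited; lines starting with "#" are comments.

.read_tsv <- function(path, ...) {
  utils::read.table(path,
    header = TRUE, sep = "\t", comment.char = "#",
    check.names = FALSE, stringsAsFactors = FALSE, quote = "", ...
  )
}

#' Read a feature (OTU/ASV/species) abundance table
#'
#' Reads a tab-delimited table whose first column holds feature identifiers
#' and whose header row holds sample identifiers, validates it, and
#' renormalizes every sample (column) to relative abundances summing to 1.
#' Tables may arrive as raw counts or as fractions; both are accepted and
#' renormalized, so all downstream distances are scale-free.
#'
#' @param path path to a TSV file.
#' @param features_as_rows logical; `TRUE` (default, the QIIME/Greengenes
#'   convention) means rows are features and columns are samples. Set to
#'   `FALSE` for the transposed layout.
#' @return a numeric matrix (features x samples) with unique row and column
#'   names; every column sums to 1.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("#OTU ID\ts1\ts2", "f1\t30\t2", "f2\t20\t8"), tf)
#' tab <- read_feature_table(tf)
#' colSums(tab) # both 1
#' @export
read_feature_table <- function(path, features_as_rows = TRUE) {
  lines <- readLines(path, warn = FALSE)
  is_comment <- startsWith(lines, "#")
  # QIIME convention: the header line itself may start with "#OTU ID"
  hdr <- which(is_comment & grepl("^#OTU ID\t", lines))
  keep <- !is_comment & nzchar(lines)
  if (length(hdr) > 0L) keep[hdr[1L]] <- TRUE
  df <- utils::read.table(
    text = lines[keep], header = TRUE, sep = "\t", comment.char = "",
    check.names = FALSE, stringsAsFactors = FALSE, quote = ""
  )
  if (ncol(df) < 2L) fms_validation_stop("feature table needs an ID column and at least one sample column")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!features_as_rows) m <- t(m)
  validate_feature_table(m)
}

#' Validate and column-normalize an abundance matrix
#'
#' @param m numeric matrix, features as rows, samples as columns.
#' @return the validated matrix with each column renormalized to sum 1.
#' @export
validate_feature_table <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) fms_validation_stop("feature table must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    fms_validation_stop("feature table must carry feature (row) and sample (column) names")
  }
  if (anyDuplicated(rownames(m))) {
    fms_validation_stop(paste0(
      "duplicate feature IDs: ",
      paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", ")
    ))
  }
  if (anyDuplicated(colnames(m))) {
    fms_validation_stop(paste0(
      "duplicate sample IDs: ",
      paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", ")
    ))
  }
  if (anyNA(m)) fms_validation_stop("feature table contains missing values")
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    fms_validation_stop(sprintf(
      "negative abundance at feature '%s', sample '%s'",
      rownames(m)[neg[1L, 1L]], colnames(m)[neg[1L, 2L]]
    ))
  }
  cs <- colSums(m)
  if (any(cs == 0)) {
    fms_validation_stop(paste0(
      "sample(s) with zero total abundance: ",
      paste(colnames(m)[cs == 0], collapse = ", ")
    ))
  }
  sweep(m, 2L, cs, "/")
}

#' Read sample metadata
#'
#' @param path TSV with header; first column is the sample ID.
#' @return data.frame with row names set to sample IDs; all other columns
#'   preserved as-is.
#' @export
read_metadata <- function(path) {
  df <- .read_tsv(path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) fms_validation_stop("duplicate sample IDs in metadata")
  out <- df[, -1L, drop = FALSE]
  rownames(out) <- ids
  out
}

#' Extract group labels for the samples of a feature table
#'
#' @param meta metadata data.frame from [read_metadata()].
#' @param samples character vector of sample IDs (typically
#'   `colnames(table)`).
#' @param group_col name of the metadata column holding the group label.
#' @return factor of group labels, one per sample, in `samples` order.
#' @export
group_labels <- function(meta, samples, group_col) {
  if (!group_col %in% colnames(meta)) {
    fms_validation_stop(sprintf("metadata has no column '%s'", group_col))
  }
  missing <- setdiff(samples, rownames(meta))
  if (length(missing) > 0L) {
    fms_stop(paste0("samples without metadata: ", paste(missing, collapse = ", ")))
  }
  factor(meta[samples, group_col])
}

#' Read a rooted Newick tree
#'
#' Parses a Newick file with [ape::read.tree()], then validates it for use
#' with the consistency-score recursion: the tree must be rooted, leaf labels
#' must be unique, and branch lengths must be non-negative (missing branch
#' lengths default to 0; multifurcations are preserved).
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] object.
#' @export
read_newick_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
    error = function(e) fms_validation_stop(paste0("cannot parse Newick: ", conditionMessage(e)))
  )
  if (is.null(tree)) fms_validation_stop("cannot parse Newick file")
  validate_tree(tree)
}

#' @rdname read_newick_tree
#' @param tree an [ape::phylo] object to validate in place of a file.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) fms_validation_stop("tree must be an ape 'phylo' object")
  if (anyDuplicated(tree$tip.label)) {
    fms_validation_stop(paste0(
      "duplicate leaf labels: ",
      paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", ")
    ))
  }
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  if (anyNA(tree$edge.length)) tree$edge.length[is.na(tree$edge.length)] <- 0
  if (any(tree$edge.length < 0)) fms_validation_stop("negative branch length in tree")
  # the basal node of the Newick string is taken as the root; a basal
  # multifurcation (which ape reports as "unrooted") is therefore accepted
  tree
}

#' Read / write a square distance matrix
#'
#' The file format is a full square TSV (not condensed): header row and first
#' column carry the sample IDs, entries are written with 6 decimal places.
#'
#' @param dm symmetric numeric matrix with zero diagonal and matching
#'   row/column names.
#' @param path file path.
#' @return `read_distance_matrix` returns the validated matrix;
#'   `write_distance_matrix` returns `path` invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  dm <- validate_distance_matrix(dm)
  ids <- colnames(dm)
  lines <- c(
    paste(c("sample", ids), collapse = "\t"),
    vapply(seq_along(ids), function(i) {
      paste(c(ids[i], sprintf("%.6f", dm[i, ])), collapse = "\t")
    }, character(1L))
  )
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- .read_tsv(path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  validate_distance_matrix(m)
}

#' @rdname write_distance_matrix
#' @export
validate_distance_matrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) fms_validation_stop("distance matrix must be square")
  if (is.null(colnames(dm))) fms_validation_stop("distance matrix must carry sample IDs")
  if (!isTRUE(all.equal(unname(dm), unname(t(dm)), tolerance = 1e-6))) {
    fms_validation_stop("distance matrix is not symmetric")
  }
  if (any(abs(diag(dm)) > 1e-9)) fms_validation_stop("distance matrix diagonal is not zero")
  if (any(dm < -1e-9) || any(dm > 1 + 1e-9)) {
    fms_validation_stop("distance matrix entries must lie in [0, 1]")
  }
  rownames(dm) <- colnames(dm)
  dm
}

#' Read a taxonomy lineage map
#'
#' @param path TSV with two columns: feature ID and a Greengenes-style
#'   lineage string (`k__...;p__...;...`). A header line is optional.
#' @return named character vector, feature ID -> lineage string.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path,
    header = FALSE, sep = "\t", comment.char = "#",
    stringsAsFactors = FALSE, quote = ""
  )
  if (identical(tolower(df[1L, 1L]), "feature_id")) df <- df[-1L, , drop = FALSE]
  if (ncol(df) < 2L) fms_validation_stop("taxonomy file needs feature_id and lineage columns")
  tax <- as.character(df[[2L]])
  names(tax) <- as.character(df[[1L]])
  if (anyDuplicated(names(tax))) fms_validation_stop("duplicate feature IDs in taxonomy")
  tax
}

#' Read per-feature function (KO) profiles
#'
#' @param path TSV, first column feature IDs, remaining columns KO
#'   identifiers with non-negative abundances.
#' @return numeric matrix, features x KOs.
#' @export
read_function_profiles <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  if (any(m < 0)) fms_validation_stop("negative KO abundance in function profiles")
  m
}

#' Read a KO hierarchy map
#'
#' @param path TSV with columns `ko`, `level2`, `level1` (header required):
#'   each KO's level-2 and level-1 functional category.
#' @return data.frame with those three character columns.
#' @export
read_ko_hierarchy <- function(path) {
  df <- .read_tsv(path)
  need <- c("ko", "level2", "level1")
  if (!all(need %in% colnames(df))) {
    fms_validation_stop("KO hierarchy needs columns: ko, level2, level1")
  }
  df[need]
}

#' Read a user-supplied exact-marker list
#'
#' One feature ID per line; `#` comments and blank lines are ignored.
#' Duplicated IDs are dropped with a warning.
#'
#' @param path file path.
#' @param table optional feature table; when given, IDs are validated
#'   against its row names.
#' @return object of class `fms_markers` (see [select_exact_markers()]),
#'   without p-values.
#' @export
load_marker_list <- function(path, table = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) fms_validation_stop("no markers in marker list file")
  if (anyDuplicated(lines)) {
    warning("duplicate marker IDs de-duplicated")
    lines <- unique(lines)
  }
  if (!is.null(table)) {
    unknown <- setdiff(lines, rownames(table))
    if (length(unknown) > 0L) {
      fms_stop(paste0("marker IDs absent from feature table: ", paste(unknown, collapse = ", ")))
    }
  }
  structure(
    list(exact = lines, p_values = NULL, alpha = NA_real_, test = "manual"),
    class = "fms_markers"
  )
}

#' Read reference sequences from FASTA
#'
#' @param path FASTA file; sequence IDs must match feature-table IDs.
#' @return named character vector of uppercase DNA strings.
#' @export
read_fasta_sequences <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), function(x) toupper(paste(x, collapse = "")), character(1L))
  names(seqs) <- names(dna)
  if (anyDuplicated(names(seqs))) fms_validation_stop("duplicate sequence IDs in FASTA")
  seqs
}
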