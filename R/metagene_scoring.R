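#' Compute metagene scores for every sample and cell type
#'
#' The metagene score of sample s for cell type c is the mean of the
#' standardized expression of that cell type's marker panel:
#' \deqn{\mathrm{score}(s, c) = \frac{1}{n_P} \sum_{i \in P_c} x_{is},}
#' where x is z-standardized expression (see
#' \code{\link{standardize_genes}}), P_c the marker set and n_P its size.
#' Scores are comparable across samples within one standardized dataset, not
#' across datasets.
#'
#' Panel genes absent from the matrix (a routine cross-platform loss, e.g.
#' scoring a mouse dataset with human-derived panels) are dropped under the
#' default policy and the effective panel sizes are recorded in the
#' \code{"n_genes"} attribute; \code{missing = "error"} demands full panels.
#' A panel with no genes present is always an error.
#'
#' @param m standardized expression matrix (every gene row mean within 1e-6
#'   of 0; violated input is rejected).
#' @param panels \code{marker_panel} or named list class -> gene IDs.
#' @param missing \code{"drop"} (default) or \code{"error"}.
#' @return numeric matrix samples x cell types with attribute
#'   \code{"n_genes"} (effective panel size per cell type). The input's
#'   sample labels, if any, are carried in the \code{"labels"} attribute.
#' @export
score_metagenes <- function(m, panels, missing = c("drop", "error")) {
  missing <- match.arg(missing)
  if (max(abs(rowMeans(m))) > 1e-6) {
    stop("matrix does not look standardized (a gene row mean exceeds 1e-6); ",
         "call standardize_genes() first")
  }
  genes <- rownames(m)
  scores <- matrix(NA_real_, nrow = ncol(m), ncol = length(panels),
                   dimnames = list(colnames(m), names(panels)))
  n_eff <- stats::setNames(integer(length(panels)), names(panels))
  for (cl in names(panels)) {
    present <- intersect(panels[[cl]], genes)
    absent <- setdiff(panels[[cl]], genes)
    if (length(present) == 0L) {
      stop("no genes of panel '", cl, "' are present in the matrix")
    }
    if (missing == "error" && length(absent) > 0L) {
      stop("panel '", cl, "' genes absent from matrix: ",
           paste(absent, collapse = ", "))
    }
    scores[, cl] <- colMeans(m[present, , drop = FALSE])
    n_eff[cl] <- length(present)
  }
  attr(scores, "n_genes") <- n_eff
  attr(scores, "labels") <- attr(m, "labels")
  scores
}

#' Check that each metagene peaks in its own purified population
#'
#' Validation on a purified reference: for each cell type c, the mean score
#' of metagene c over samples of class c must strictly exceed the mean score
#' of metagene c in every other class's samples. The margin is the gap to the
#' best competing class (positive = pass).
#'
#' @param scores samples x cell types score matrix
#'   (\code{\link{score_metagenes}} on the reference).
#' @param labels named character vector sample -> class; defaults to the
#'   score matrix's \code{"labels"} attribute.
#' @return data.frame with one row per cell type: \code{cell_type},
#'   \code{own_mean}, \code{best_other} (that class label),
#'   \code{best_other_mean}, \code{margin}, \code{pass}; the number of
#'   passing classes is in attribute \code{"n_pass"}.
#' @export
self_recovery <- function(scores, labels = attr(scores, "labels")) {
  if (is.null(labels)) stop("sample class labels are required")
  samples <- rownames(scores)
  cls <- unname(labels[samples])
  types <- colnames(scores)
  missing_cls <- setdiff(types, cls)
  if (length(missing_cls) > 0L) {
    stop("no labeled samples for metagene class(es): ",
         paste(missing_cls, collapse = ", "))
  }
  rows <- lapply(types, function(ct) {
    by_class <- tapply(scores[, ct], cls, mean)
    own <- by_class[[ct]]
    others <- by_class[setdiff(names(by_class), ct)]
    best <- which.max(others)
    data.frame(cell_type = ct, own_mean = own,
               best_other = names(others)[best],
               best_other_mean = unname(others[best]),
               margin = own - unname(others[best]),
               pass = own > unname(others[best]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_pass") <- sum(out$pass)
  out
}

#' Write a score matrix as TSV
#'
#' Rows are samples, columns cell types; a \code{group} column is appended
#' when labels are supplied (or carried on the matrix). A \code{dataset_id}
#' comment line records provenance, because scores standardized within
#' different datasets are not comparable.
#'
#' @param scores samples x cell types matrix.
#' @param path output file path.
#' @param labels optional named character vector sample -> group.
#' @param dataset_id identifier recorded in the file header comment.
#' @return \code{path}, invisibly.
#' @export
write_scores <- function(scores, path, labels = attr(scores, "labels"),
                         dataset_id = "unspecified") {
  df <- data.frame(sample_id = rownames(scores), scores,
                   check.names = FALSE)
  if (!is.null(labels)) df$group <- unname(labels[rownames(scores)])
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# dataset_id=", dataset_id), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score matrix written by \code{\link{write_scores}}
#'
#' @param path path to the score TSV.
#' @return samples x cell types matrix; group labels, if present, in the
#'   \code{"labels"} attribute and the dataset ID in \code{"dataset_id"}.
#' @export
read_scores <- function(path) {
  first <- readLines(path, n = 1L)
  dataset_id <- if (startsWith(first, "# dataset_id=")) {
    sub("^# dataset_id=", "", first)
  } else NA_character_
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  labels <- NULL
  if ("group" %in% names(df)) {
    labels <- stats::setNames(df$group, df$sample_id)
    df$group <- NULL
  }
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  rownames(m) <- df$sample_id
  attr(m, "labels") <- labels
  attr(m, "dataset_id") <- dataset_id
  m
}
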