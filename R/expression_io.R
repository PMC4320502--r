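#' Read an expression matrix from a tab-delimited file
#'
#' Expression matrices are plain TSV: the first column holds gene (or probe)
#' identifiers under the header \code{gene_id}, remaining columns one sample
#' each, named in the header row. An optional second header row, whose first
#' field is \code{label}, carries a per-sample label (cell type or group).
#' Values are normalized log-scale expression.
#'
#' Duplicate row identifiers are permitted at this stage: probe-level data
#' carry several probes per gene until \code{\link{collapse_to_genes}}.
#'
#' @param path path to a TSV file (UTF-8, "." decimal separator).
#' @param label_row logical; if \code{TRUE}, the second line is read as a
#'   per-sample label row.
#' @return a numeric matrix (genes x samples) with row and column names.
#'   When a label row is present, a named character vector of labels is
#'   attached as attribute \code{"labels"}.
#' @seealso \code{\link{write_expression}}, \code{\link{collapse_to_genes}},
#'   \code{\link{standardize_genes}}
#' @export
read_expression <- function(path, label_row = FALSE) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("expression file must have a header row and at least one data row")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  n_col <- length(header)
  if (n_col < 2L) stop("header row must name at least one sample")
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs in header")

  labels <- NULL
  first_data <- 2L
  if (isTRUE(label_row)) {
    lab <- fields[[2L]]
    if (length(lab) != n_col) {
      stop("label row (line 2) has ", length(lab), " fields, expected ", n_col)
    }
    labels <- stats::setNames(lab[-1L], sample_ids)
    first_data <- 3L
  }

  data_idx <- seq(first_data, length(fields))
  if (length(data_idx) < 1L) stop("no data rows found")
  bad <- data_idx[vapply(fields[data_idx], length, 1L) != n_col]
  if (length(bad) > 0L) {
    stop("ragged row: line ", bad[1L], " has ",
         length(fields[[bad[1L]]]), " fields, expected ", n_col)
  }

  ids <- vapply(fields[data_idx], `[[`, "", 1L)
  vals <- matrix(NA_real_, nrow = length(data_idx), ncol = n_col - 1L,
                 dimnames = list(ids, sample_ids))
  for (r in seq_along(data_idx)) {
    raw <- fields[[data_idx[r]]][-1L]
    num <- suppressWarnings(as.numeric(raw))
    if (anyNA(num)) {
      j <- which(is.na(num))[1L]
      stop("non-numeric value '", raw[j], "' at line ", data_idx[r],
           ", sample '", sample_ids[j], "'")
    }
    vals[r, ] <- num
  }
  if (!all(is.finite(vals))) stop("non-finite values in expression matrix")
  if (!is.null(labels)) attr(vals, "labels") <- labels
  vals
}

#' Write an expression matrix to a tab-delimited file
#'
#' Inverse of \code{\link{read_expression}}; values are written with 15
#' significant digits so a read/write round trip preserves them.
#'
#' @param m numeric matrix with row (gene) and column (sample) names.
#' @param path output file path.
#' @param labels optional named character vector of per-sample labels; when
#'   omitted, the \code{"labels"} attribute of \code{m} is used if present.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(m, path, labels = attr(m, "labels")) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(m)), collapse = "\t"), con)
  if (!is.null(labels)) {
    lab <- unname(labels[colnames(m)])
    if (anyNA(lab)) stop("labels missing for some samples")
    writeLines(paste(c("label", lab), collapse = "\t"), con)
  }
  body <- vapply(seq_len(nrow(m)), function(r) {
    paste(c(rownames(m)[r], sprintf("%.15g", m[r, ])), collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' Read a probe-to-gene map
#'
#' Two-column TSV (header required): \code{probe_id}, \code{gene_id}. The map
#' must be many-to-one: each probe maps to exactly one gene. Gene identifiers
#' are opaque strings; any orthology or annotation resolution happens before
#' this file is produced.
#'
#' @param path path to the map file.
#' @return named character vector: names are probe IDs, values gene IDs.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(df) < 2L) stop("probe map must have two columns (probe_id, gene_id)")
  if (anyDuplicated(df[[1L]])) {
    stop("probes mapped more than once: ",
         paste(unique(df[[1L]][duplicated(df[[1L]])]), collapse = ", "))
  }
  stats::setNames(df[[2L]], df[[1L]])
}

#' Collapse probe-level rows to one row per gene
#'
#' For each gene, the retained row is the probe with the highest mean
#' expression across all samples; ties are broken by input order (the earlier
#' probe wins), so the result is deterministic. Output rows are named by gene
#' and ordered by first appearance of each gene among the input probes.
#'
#' @param m probe-level expression matrix (rows named by probe ID).
#' @param map named character vector probe -> gene
#'   (see \code{\link{read_probe_map}}).
#' @return gene-level expression matrix, one row per distinct gene.
#' @export
collapse_to_genes <- function(m, map) {
  probes <- rownames(m)
  missing <- setdiff(probes, names(map))
  if (length(missing) > 0L) {
    stop("probes absent from map: ", paste(missing, collapse = ", "))
  }
  genes <- unname(map[probes])
  means <- rowMeans(m)
  keep <- integer(0)
  for (idx in split(seq_along(probes), factor(genes, levels = unique(genes)))) {
    keep <- c(keep, idx[which.max(means[idx])])  # which.max: first max wins
  }
  out <- m[keep, , drop = FALSE]
  rownames(out) <- genes[keep]
  attr(out, "labels") <- attr(m, "labels")
  out
}

#' Standardize each gene to mean 0, SD 1
#'
#' Transforms every gene row so its mean is 0 and its sample standard
#' deviation (n-1 denominator) is 1 across all samples of the dataset,
#' controls and disease together. This is the transform under which metagene
#' scores are averages of z-scores, comparable across samples within one
#' dataset but not across datasets.
#'
#' Zero-variance genes cannot be standardized; they are set to all-zero rows
#' (contributing 0 to any metagene score) and reported via a warning.
#'
#' @param m gene-level expression matrix with at least 2 samples.
#' @return matrix of the same shape, rows standardized.
#' @export
standardize_genes <- function(m) {
  if (ncol(m) < 2L) stop("standardization undefined for a single-sample matrix")
  mu <- rowMeans(m)
  sdev <- apply(m, 1L, stats::sd)
  flat <- sdev == 0
  if (any(flat)) {
    warning("zero-variance genes set to all-zero rows: ",
            paste(rownames(m)[flat], collapse = ", "))
    sdev[flat] <- 1
  }
  out <- (m - mu) / sdev
  out[flat, ] <- 0
  attr(out, "labels") <- attr(m, "labels")
  out
}

#' Restrict two matrices to their shared genes
#'
#' Cross-platform comparison joins datasets on the intersection of their
#' (collapsed) gene identifiers. Both outputs carry the shared genes in the
#' same row order (order of appearance in \code{a}).
#'
#' @param a,b gene-level expression matrices.
#' @return list with elements \code{a} and \code{b}, row-aligned.
#' @export
align_genes <- function(a, b) {
  common <- intersect(rownames(a), rownames(b))
  if (length(common) == 0L) stop("no genes shared between the two matrices")
  out_a <- a[common, , drop = FALSE]
  out_b <- b[common, , drop = FALSE]
  attr(out_a, "labels") <- attr(a, "labels")
  attr(out_b, "labels") <- attr(b, "labels")
  list(a = out_a, b = out_b)
}

#' Read gene-set panels from a GMT file
#'
#' GMT: one set per line — set name, description, then member genes, all
#' tab-separated.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (class \code{marker_panel}).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad) > 0L) {
    stop("GMT line ", bad[1L], " has fewer than 3 fields")
  }
  panels <- lapply(fields, function(f) f[-(1:2)])
  names(panels) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(panels))) stop("duplicate set names in GMT")
  structure(panels, class = "marker_panel")
}

#' Write gene-set panels to a GMT file
#'
#' @param panels named list of character vectors (gene sets).
#' @param path output file path.
#' @param description description field per set (recycled).
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(panels, path, description = "leukocyte metagene") {
  stopifnot(length(names(panels)) == length(panels))
  description <- rep_len(description, length(panels))
  lines <- vapply(seq_along(panels), function(i) {
    paste(c(names(panels)[i], description[i], panels[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
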