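#' Fit nearest-shrunken-centroid statistics
#'
#' Computes the classical NSC (PAM) statistics on a labeled reference of
#' purified cell populations, with each population an independent class. For
#' gene i and class k, with class centroid \eqn{\bar x_{ik}}, overall centroid
#' \eqn{\bar x_i}, pooled within-class standard deviation \eqn{s_i}
#' (denominator n - K), offset \eqn{s_0 = \mathrm{median}_i(s_i)} and
#' \eqn{m_k = \sqrt{1/n_k - 1/n}}, the d-statistic is
#' \deqn{d_{ik} = \frac{\bar x_{ik} - \bar x_i}{m_k (s_i + s_0)}.}
#'
#' Degenerate-small designs (e.g. 6 classes of 2 replicates, so n - K = 6)
#' are supported; every class needs at least 2 samples so \eqn{s_i} is
#' defined.
#'
#' @param m expression matrix (genes x samples).
#' @param labels named character vector sample -> class covering all columns
#'   of \code{m}; defaults to the matrix's \code{"labels"} attribute.
#' @return object of class \code{centroid_model}: classes, class sizes
#'   \code{n_k}, priors (empirical frequencies), \code{overall} centroid,
#'   \code{centroids} (genes x classes), pooled \code{s}, \code{s0},
#'   \code{m_k}, d-statistics \code{d}, shrinkage \code{delta} (0 at fit
#'   time), shrunken \code{d_shrunk} and \code{centroids_shrunk}.
#' @export
fit_centroids <- function(m, labels = attr(m, "labels")) {
  if (is.null(labels)) stop("sample class labels are required")
  samples <- colnames(m)
  unlabeled <- setdiff(samples, names(labels))
  if (length(unlabeled) > 0L) {
    stop("unlabeled samples: ", paste(unlabeled, collapse = ", "))
  }
  cls <- unname(labels[samples])
  classes <- unique(cls)
  if (length(classes) < 2L) stop("need at least 2 classes")
  n_k <- vapply(classes, function(k) sum(cls == k), 1L)
  if (any(n_k < 2L)) {
    stop("classes with fewer than 2 samples: ",
         paste(classes[n_k < 2L], collapse = ", "))
  }
  n <- length(cls)
  K <- length(classes)

  centroids <- matrix(
    unlist(lapply(classes, function(k) rowMeans(m[, cls == k, drop = FALSE]))),
    nrow = nrow(m), dimnames = list(rownames(m), classes))
  overall <- rowMeans(m)

  # pooled within-class variance, denominator n - K
  ss <- numeric(nrow(m))
  for (k in classes) {
    dev <- m[, cls == k, drop = FALSE] - centroids[, k]
    ss <- ss + rowSums(dev^2)
  }
  s <- sqrt(ss / (n - K))
  s0 <- stats::median(s)
  m_k <- stats::setNames(sqrt(1 / n_k - 1 / n), classes)

  # d[i,k] = (centroids[i,k] - overall[i]) / (m_k[k] * (s[i] + s0))
  d <- sweep(centroids - overall, 1L, s + s0, "/")
  d <- sweep(d, 2L, m_k, "/")

  model <- list(
    classes = classes, n_k = n_k, n = n, priors = n_k / n,
    gene_ids = rownames(m), overall = overall, centroids = centroids,
    s = stats::setNames(s, rownames(m)), s0 = s0, m_k = m_k, d = d,
    delta = 0, d_shrunk = d, centroids_shrunk = centroids
  )
  class(model) <- "centroid_model"
  model
}

#' Soft-threshold the centroid model
#'
#' Applies the NSC shrinkage: \eqn{d'_{ik} = \mathrm{sign}(d_{ik})
#' \max(|d_{ik}| - \Delta, 0)} and reconstructs shrunken class centroids
#' \eqn{\bar x'_{ik} = \bar x_i + m_k (s_i + s_0) d'_{ik}}. With
#' \code{delta = 0} the model is returned unshrunk.
#'
#' @param model a \code{centroid_model}.
#' @param delta non-negative shrinkage threshold.
#' @return the model with \code{delta}, \code{d_shrunk} and
#'   \code{centroids_shrunk} updated.
#' @export
shrink <- function(model, delta) {
  stopifnot(inherits(model, "centroid_model"))
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0) {
    stop("delta must be a single non-negative number")
  }
  d_shrunk <- sign(model$d) * pmax(abs(model$d) - delta, 0)
  scale <- model$s + model$s0
  shift <- sweep(sweep(d_shrunk, 1L, scale, "*"), 2L, model$m_k, "*")
  model$delta <- delta
  model$d_shrunk <- d_shrunk
  model$centroids_shrunk <- model$overall + shift
  model
}

#' Select top-k marker genes per class
#'
#' Ranks genes within each class by the (shrunken) d-statistic — by default
#' signed and descending, so markers are genes elevated in their class — and
#' assigns genes to class panels by greedy round-robin: in class order, each
#' class claims its best still-unclaimed gene, repeating rounds until every
#' panel holds \code{k} genes. Panels are therefore disjoint, and k panels
#' over K classes contain exactly k*K distinct genes. Rank ties break by
#' lexicographic gene ID.
#'
#' @param model a \code{centroid_model} (shrunken or not; the current
#'   \code{d_shrunk} is used).
#' @param k panel size per class.
#' @param rank \code{"signed"} (default; elevation in the class) or
#'   \code{"abs"} (magnitude of the d-statistic).
#' @return \code{marker_panel}: named list class -> ordered character vector
#'   of k gene IDs, with attributes \code{k} and \code{rank}.
#' @export
select_markers <- function(model, k, rank = c("signed", "abs")) {
  stopifnot(inherits(model, "centroid_model"))
  rank <- match.arg(rank)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("k must be a positive integer")
  }
  K <- length(model$classes)
  n_genes <- length(model$gene_ids)
  if (k * K > n_genes) {
    stop("cannot form disjoint panels: need ", k * K, " genes, have ",
         n_genes, " (short by ", k * K - n_genes, ")")
  }
  stat <- if (rank == "abs") abs(model$d_shrunk) else model$d_shrunk
  # per class, gene indices best-first; ties by lexicographic gene ID
  ranking <- lapply(model$classes, function(cl) {
    order(-stat[, cl], model$gene_ids)
  })
  names(ranking) <- model$classes

  claimed <- logical(n_genes)
  panels <- stats::setNames(
    rep(list(character(0)), K), model$classes)
  cursor <- stats::setNames(rep(1L, K), model$classes)
  for (round in seq_len(k)) {
    for (cl in model$classes) {
      i <- cursor[cl]
      while (i <= n_genes && claimed[ranking[[cl]][i]]) i <- i + 1L
      if (i > n_genes) {
        stop("cannot form disjoint panels: class '", cl,
             "' ran out of unclaimed genes")
      }
      g <- ranking[[cl]][i]
      claimed[g] <- TRUE
      panels[[cl]] <- c(panels[[cl]], model$gene_ids[g])
      cursor[cl] <- i + 1L
    }
  }
  structure(panels, k = as.integer(k), rank = rank, class = "marker_panel")
}

#' Classify a sample with the shrunken-centroid discriminant
#'
#' Discriminant score for class k:
#' \deqn{\delta_k(x) = \sum_i \frac{(x_i - \bar x'_{ik})^2}{(s_i + s_0)^2}
#'   - 2 \log \pi_k,}
#' predicted class is the minimizer; ties break by class order.
#'
#' @param model a \code{centroid_model}.
#' @param x numeric vector, one value per model gene, in model gene order.
#' @return list with \code{class} (predicted label) and \code{scores}
#'   (named discriminant values, smaller is closer).
#' @export
classify <- function(model, x) {
  stopifnot(inherits(model, "centroid_model"))
  if (length(x) != length(model$gene_ids)) {
    stop("sample has ", length(x), " genes, model expects ",
         length(model$gene_ids))
  }
  denom <- (model$s + model$s0)^2
  scores <- vapply(model$classes, function(cl) {
    sum((x - model$centroids_shrunk[, cl])^2 / denom) -
      2 * log(model$priors[[cl]])
  }, 0)
  list(class = model$classes[which.min(scores)], scores = scores)
}

#' Classify every column of an expression matrix
#'
#' @param model a \code{centroid_model}.
#' @param m matrix whose rows match the model's genes (by name if named).
#' @return named character vector of predicted classes per sample.
#' @export
classify_samples <- function(model, m) {
  if (!is.null(rownames(m))) {
    if (!all(model$gene_ids %in% rownames(m))) {
      stop("matrix is missing model genes")
    }
    m <- m[model$gene_ids, , drop = FALSE]
  }
  vapply(seq_len(ncol(m)), function(j) classify(model, m[, j])$class, "",
         USE.NAMES = FALSE) |> stats::setNames(colnames(m))
}

#' Serialize a centroid model to versioned JSON
#'
#' @param model a \code{centroid_model}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_centroid_model <- function(model, path) {
  stopifnot(inherits(model, "centroid_model"))
  doc <- list(
    format = "leukomet-centroid-model", version = 1L,
    classes = model$classes, n_k = as.list(model$n_k), n = model$n,
    priors = as.list(model$priors), gene_ids = model$gene_ids,
    overall = unname(model$overall),
    centroids = apply(model$centroids, 2L, identity, simplify = FALSE),
    s = unname(model$s), s0 = model$s0, m_k = as.list(model$m_k),
    d = apply(model$d, 2L, identity, simplify = FALSE),
    delta = model$delta
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a centroid model from JSON
#'
#' @param path path written by \code{\link{write_centroid_model}}.
#' @return a \code{centroid_model}.
#' @export
read_centroid_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "leukomet-centroid-model")) {
    stop("not a centroid model file")
  }
  to_mat <- function(lst) {
    mat <- do.call(cbind, lapply(doc$classes, function(cl) lst[[cl]]))
    dimnames(mat) <- list(doc$gene_ids, doc$classes)
    mat
  }
  model <- list(
    classes = doc$classes,
    n_k = stats::setNames(unlist(doc$n_k), doc$classes),
    n = doc$n,
    priors = stats::setNames(unlist(doc$priors), doc$classes),
    gene_ids = doc$gene_ids,
    overall = stats::setNames(doc$overall, doc$gene_ids),
    centroids = to_mat(doc$centroids),
    s = stats::setNames(doc$s, doc$gene_ids),
    s0 = doc$s0,
    m_k = stats::setNames(unlist(doc$m_k), doc$classes),
    d = to_mat(doc$d),
    delta = 0, d_shrunk = NULL, centroids_shrunk = NULL
  )
  model$d_shrunk <- model$d
  model$centroids_shrunk <- model$centroids
  class(model) <- "centroid_model"
  if (doc$delta > 0) model <- shrink(model, doc$delta)
  model
}

#' @export
print.centroid_model <- function(x, ...) {
  cat("Nearest-shrunken-centroid model\n")
  cat("  genes:", length(x$gene_ids), " classes:",
      paste(x$classes, collapse = ", "), "\n")
  cat("  class sizes:", paste(x$n_k, collapse = ", "),
      " s0:", signif(x$s0, 4), " delta:", x$delta, "\n")
  invisible(x)
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Marker panels (", length(x), " classes, k = ",
      attr(x, "k") %||% "?", ")\n", sep = "")
  for (cl in names(x)) {
    g <- x[[cl]]
    shown <- paste(utils::head(g, 5L), collapse = ", ")
    if (length(g) > 5L) shown <- paste0(shown, ", ...")
    cat("  ", cl, " [", length(g), "]: ", shown, "\n", sep = "")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
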