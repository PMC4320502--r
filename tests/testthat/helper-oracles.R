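# Independent, loop-based oracles. Deliberately naive: these recompute the
# same statistics element by element, with no shared code with R/.

# NSC statistics by explicit loops
nsc_oracle <- function(m, labels) {
  cls <- unname(labels[colnames(m)])
  classes <- unique(cls)
  n <- ncol(m)
  K <- length(classes)
  n_k <- sapply(classes, function(k) sum(cls == k))
  centroids <- matrix(NA_real_, nrow(m), K,
                      dimnames = list(rownames(m), classes))
  overall <- numeric(nrow(m))
  s <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    overall[i] <- mean(m[i, ])
    ss <- 0
    for (k in classes) {
      xi <- m[i, cls == k]
      centroids[i, k] <- mean(xi)
      ss <- ss + sum((xi - mean(xi))^2)
    }
    s[i] <- sqrt(ss / (n - K))
  }
  s0 <- median(s)
  m_k <- sapply(classes, function(k) sqrt(1 / n_k[classes == k] - 1 / n))
  d <- matrix(NA_real_, nrow(m), K, dimnames = list(rownames(m), classes))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(K)) {
      d[i, j] <- (centroids[i, j] - overall[i]) / (m_k[j] * (s[i] + s0))
    }
  }
  list(classes = classes, n_k = n_k, overall = overall,
       centroids = centroids, s = s, s0 = s0, m_k = m_k, d = d,
       priors = n_k / n)
}

# shrunken centroids by loops, given oracle state and delta
shrunken_centroids_oracle <- function(o, delta) {
  out <- o$centroids
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      dd <- sign(o$d[i, j]) * max(abs(o$d[i, j]) - delta, 0)
      out[i, j] <- o$overall[i] + o$m_k[j] * (o$s[i] + o$s0) * dd
    }
  }
  out
}

# discriminant classification by loops
classify_oracle <- function(o, centroids_shrunk, x) {
  best <- NULL
  best_score <- Inf
  for (j in seq_along(o$classes)) {
    sc <- 0
    for (i in seq_along(x)) {
      sc <- sc + (x[i] - centroids_shrunk[i, j])^2 / (o$s[i] + o$s0)^2
    }
    sc <- sc - 2 * log(o$priors[j])
    if (sc < best_score) {
      best_score <- sc
      best <- o$classes[j]
    }
  }
  best
}

# metagene scores by per-sample loops
score_oracle <- function(m, panels) {
  out <- matrix(NA_real_, ncol(m), length(panels),
                dimnames = list(colnames(m), names(panels)))
  for (s in seq_len(ncol(m))) {
    for (cl in names(panels)) {
      genes <- intersect(panels[[cl]], rownames(m))
      acc <- 0
      for (g in genes) acc <- acc + m[g, s]
      out[s, cl] <- acc / length(genes)
    }
  }
  out
}

# pooled-variance two-sample t and two-sided p from first principles
student_t_oracle <- function(ctrl, dis) {
  n1 <- length(ctrl)
  n2 <- length(dis)
  sp2 <- (sum((ctrl - mean(ctrl))^2) + sum((dis - mean(dis))^2)) /
    (n1 + n2 - 2)
  t <- (mean(dis) - mean(ctrl)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# a labeled random reference matrix for oracle comparisons
random_labeled_matrix <- function(n_genes, classes, reps) {
  ids <- paste(rep(classes, each = reps), seq_len(reps), sep = "_")
  m <- matrix(rnorm(n_genes * length(ids)), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)), ids))
  attr(m, "labels") <- setNames(rep(classes, each = reps), ids)
  m
}
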