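test_that("centroid statistics reproduce the hand-worked two-class case", {
  m <- matrix(c(0, 2, 4, 6), nrow = 1,
              dimnames = list("g1", c("a1", "a2", "b1", "b2")))
  labels <- setNames(c("A", "A", "B", "B"), colnames(m))
  mod <- fit_centroids(m, labels)
  expect_equal(unname(mod$centroids[1, ]), c(1, 5))
  expect_equal(unname(mod$overall), 3)
  expect_equal(unname(mod$s), sqrt(2))
  expect_equal(mod$s0, sqrt(2))
  expect_equal(unname(mod$m_k), c(0.5, 0.5))
  expect_equal(unname(mod$d[1, ]), c(-sqrt(2), sqrt(2)), tolerance = 1e-10)
})

test_that("a gene constant across all samples has d = 0 everywhere", {
  set.seed(3)
  m <- random_labeled_matrix(10, c("A", "B", "C"), 3)
  m["g001", ] <- 7
  mod <- fit_centroids(m)
  expect_equal(unname(mod$d["g001", ]), c(0, 0, 0))
})

test_that("d-statistics, shrinkage and classification match loop oracles", {
  set.seed(100)
  for (rep in 1:20) {
    n_genes <- sample(20:200, 1)
    K <- sample(2:6, 1)
    reps <- sample(2:4, 1)
    m <- random_labeled_matrix(n_genes, LETTERS[1:K], reps)
    mod <- fit_centroids(m)
    o <- nsc_oracle(m, attr(m, "labels"))
    expect_equal(mod$d, o$d, tolerance = 1e-10)
    expect_equal(unname(mod$s), o$s, tolerance = 1e-10)
    expect_equal(mod$s0, o$s0, tolerance = 1e-10)

    delta <- runif(1, 0, 2)
    sh <- shrink(mod, delta)
    expect_equal(sh$centroids_shrunk, shrunken_centroids_oracle(o, delta),
                 tolerance = 1e-10)

    oc <- shrunken_centroids_oracle(o, 0)
    pred <- classify_samples(mod, m)
    pred_oracle <- sapply(seq_len(ncol(m)),
                          function(j) classify_oracle(o, oc, m[, j]))
    expect_identical(unname(pred), pred_oracle)
  }
})

test_that("centroid consistency: class sizes weight centroids to the mean", {
  set.seed(8)
  m <- random_labeled_matrix(50, c("A", "B", "C"), 2)
  mod <- fit_centroids(m)
  recon <- as.vector(mod$centroids %*% mod$n_k) / mod$n
  expect_lt(max(abs(recon - mod$overall)), 1e-8)
})

test_that("soft-thresholding shrinks as specified", {
  m <- matrix(c(0, 2, 4, 6), nrow = 1,
              dimnames = list("g1", c("a1", "a2", "b1", "b2")))
  mod <- fit_centroids(m, setNames(c("A", "A", "B", "B"), colnames(m)))

  expect_equal(shrink(mod, 0)$d_shrunk, mod$d)
  expect_equal(unname(shrink(mod, 1)$d_shrunk[1, "B"]), sqrt(2) - 1,
               tolerance = 1e-10)

  full <- shrink(mod, max(abs(mod$d)) + 0.1)
  expect_true(all(full$d_shrunk == 0))
  expect_equal(unname(full$centroids_shrunk[, "A"]), unname(mod$overall))
  expect_equal(unname(full$centroids_shrunk[, "B"]), unname(mod$overall))

  expect_error(shrink(mod, -1), "non-negative")
})

test_that("shrinkage magnitude is monotone in delta", {
  set.seed(21)
  m <- random_labeled_matrix(40, c("A", "B", "C"), 2)
  mod <- fit_centroids(m)
  deltas <- sort(runif(5, 0, 3))
  prev <- abs(shrink(mod, deltas[1])$d_shrunk)
  for (d in deltas[-1]) {
    cur <- abs(shrink(mod, d)$d_shrunk)
    expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
})

test_that("adding a constant to one gene leaves its d-statistics unchanged", {
  set.seed(22)
  m <- random_labeled_matrix(30, c("A", "B"), 3)
  d_before <- fit_centroids(m)$d["g005", ]
  m2 <- m
  m2["g005", ] <- m2["g005", ] + 11.3
  d_after <- fit_centroids(m2)$d["g005", ]
  expect_equal(d_after, d_before, tolerance = 1e-10)
})

test_that("marker selection ranks by signed d with lexicographic ties", {
  # 3 genes, g2 uniquely largest for class A
  m <- matrix(c(1, 1, 0, 0,
                5, 5, 0, 0,
                0, 0, 5, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"),
                              c("a1", "a2", "b1", "b2")))
  m <- m + matrix(c(0.01, -0.01), nrow = 3, ncol = 4, byrow = TRUE)
  mod <- fit_centroids(m, setNames(c("A", "A", "B", "B"), colnames(m)))
  pan <- select_markers(mod, 1)
  expect_identical(pan$A, "g2")

  # exact tie between two genes for class A -> smaller gene ID first
  tied <- matrix(c(2, 4, 0, 0,
                   2, 4, 0, 0,
                   0, 0, 2, 4), nrow = 3, byrow = TRUE,
                 dimnames = list(c("gB", "gA", "gC"),
                                 c("a1", "a2", "b1", "b2")))
  mod2 <- fit_centroids(tied, setNames(c("A", "A", "B", "B"), colnames(tied)))
  expect_equal(unname(mod2$d["gA", "A"]), unname(mod2$d["gB", "A"]))
  expect_identical(select_markers(mod2, 1)$A, "gA")
})

test_that("panels are disjoint and k per class; deficits are errors", {
  cfg <- sim_config()
  ref <- simulate_reference(cfg, seed = 5)
  mod <- fit_centroids(ref$expression, ref$labels)
  pan <- select_markers(mod, 25)
  expect_true(all(lengths(pan) == 25))
  expect_identical(length(unique(unlist(pan))), 150L)

  small <- random_labeled_matrix(5, c("A", "B"), 2)
  expect_error(select_markers(fit_centroids(small), 3), "disjoint")
})

test_that("selection at strong effect recovers the planted markers", {
  cfg <- sim_config()
  set.seed(60)
  precision <- recall <- numeric(0)
  for (r in 1:40) {
    ref <- simulate_reference(cfg)
    mod <- fit_centroids(ref$expression, ref$labels)
    p25 <- select_markers(mod, 25)
    p30 <- select_markers(mod, 30)
    precision <- c(precision, sapply(cfg$classes, function(cl) {
      mean(p25[[cl]] %in% ref$markers[[cl]])
    }))
    recall <- c(recall, sapply(cfg$classes, function(cl) {
      mean(ref$markers[[cl]] %in% p30[[cl]])
    }))
  }
  expect_gte(mean(precision), 0.90)  # selected genes are true markers
  expect_gte(mean(recall), 0.85)     # planted markers are found
})

test_that("classification returns the nearest shrunken centroid", {
  set.seed(33)
  m <- random_labeled_matrix(20, c("A", "B", "C"), 2)
  mod <- fit_centroids(m)

  hit <- classify(mod, mod$centroids_shrunk[, "B"])
  expect_identical(hit$class, "B")

  all_shrunk <- shrink(mod, max(abs(mod$d)) + 1)
  # equalize priors so the degenerate case is a pure tie
  all_shrunk$priors[] <- 1 / 3
  tie <- classify(all_shrunk, mod$overall)
  expect_identical(tie$class, mod$classes[1])

  expect_error(classify(mod, c(1, 2, 3)), "genes")
})

test_that("fit rejects invalid designs", {
  m <- random_labeled_matrix(10, c("A", "B"), 2)
  lab <- attr(m, "labels")
  lab[2] <- "B"  # class A left with one sample
  expect_error(fit_centroids(m, lab), "fewer than 2")
  expect_error(fit_centroids(m, lab[-1]), "unlabeled")
  expect_error(fit_centroids(m, setNames(rep("A", 4), colnames(m))),
               "2 classes")
})

test_that("centroid models survive a JSON round trip", {
  set.seed(44)
  m <- random_labeled_matrix(15, c("A", "B", "C"), 2)
  mod <- shrink(fit_centroids(m), 0.4)
  path <- tempfile(fileext = ".json")
  write_centroid_model(mod, path)
  back <- read_centroid_model(path)
  expect_equal(back$d, mod$d, tolerance = 1e-12)
  expect_equal(back$centroids_shrunk, mod$centroids_shrunk, tolerance = 1e-12)
  expect_equal(back$s0, mod$s0)
  expect_equal(back$m_k, mod$m_k)
  expect_identical(back$classes, mod$classes)
})
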