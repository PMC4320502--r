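#' Configuration for synthetic reference and cohort generation
#'
#' The defaults emulate the study layout the pipeline is designed for: a
#' purified-leukocyte reference of 6 cell types (monocytes, dendritic cells,
#' NK cells, CD4+ T cells, CD8+ T cells, B cells) with 2 replicate arrays
#' each, and a human-style biopsy cohort of 7 control vs 8 disease samples
#' (use \code{n_control = 4, n_disease = 4} for the mouse-style layout).
#' Expression is on a log-like normalized scale.
#'
#' Bulk samples are convex mixtures: each leukocyte type contributes its
#' signature in proportion to its cell fraction, the remainder is a stromal
#' background signature, and disease shifts named cell-type fractions by
#' \code{fraction_shift}, displacing stroma.
#'
#' @param classes cell-type names (reference classes and mixture components).
#' @param replicates_per_class purified replicates per class in the
#'   reference.
#' @param n_genes number of genes.
#' @param markers_per_class number of disjoint true marker genes per class.
#' @param marker_effect marker elevation in units of \code{noise_sd}
#'   (mean log-expression elevation in the marker's own class).
#' @param noise_sd Gaussian noise SD on the expression scale.
#' @param baseline_expr baseline log-expression level (location only; the
#'   analysis is invariant to it).
#' @param n_control,n_disease cohort group sizes.
#' @param stromal_fraction mean stromal (non-leukocyte) fraction in control
#'   tissue; the leukocyte baseline fractions share the remainder equally
#'   unless \code{baseline_fractions} is given.
#' @param baseline_fractions optional named vector of control-mean cell
#'   fractions per class (must be >= 0 and sum to <= 1; stroma takes the
#'   remainder).
#' @param fraction_shift named numeric vector, additive change of the mean
#'   fraction of selected cell types in disease (e.g.
#'   \code{c(DC = 0.15, CD4T = 0.15)}).
#' @param dirichlet_conc Dirichlet concentration for per-sample fraction
#'   variability around the group means (larger = less variable; 50 gives
#'   mild biological variability).
#' @param mixing \code{"linear"} (default): mixtures formed on the log-like
#'   scale itself; \code{"lognormal"}: signatures are exponentiated (base 2),
#'   mixed, and re-logged before noise.
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(classes = c("Monocyte", "DC", "NK", "CD4T", "CD8T", "B"),
                       replicates_per_class = 2L,
                       n_genes = 500L,
                       markers_per_class = 30L,
                       marker_effect = 3,
                       noise_sd = 1,
                       baseline_expr = 6,
                       n_control = 7L,
                       n_disease = 8L,
                       stromal_fraction = 0.5,
                       baseline_fractions = NULL,
                       fraction_shift = numeric(0),
                       dirichlet_conc = 50,
                       mixing = c("linear", "lognormal")) {
  mixing <- match.arg(mixing)
  K <- length(classes)
  if (K < 2L) stop("need at least 2 classes")
  if (markers_per_class * K > n_genes) {
    stop("marker capacity exceeded: ", markers_per_class, " x ", K,
         " > ", n_genes, " genes")
  }
  if (is.null(baseline_fractions)) {
    baseline_fractions <- stats::setNames(
      rep((1 - stromal_fraction) / K, K), classes)
  }
  if (!setequal(names(baseline_fractions), classes)) {
    stop("baseline_fractions must be named by the classes")
  }
  baseline_fractions <- baseline_fractions[classes]
  if (any(baseline_fractions < 0) || sum(baseline_fractions) > 1 + 1e-12) {
    stop("baseline fractions must be >= 0 and sum to at most 1")
  }
  if (length(fraction_shift) > 0L &&
      !all(names(fraction_shift) %in% classes)) {
    stop("fraction_shift names must be cell-type classes")
  }
  cfg <- list(classes = classes,
              replicates_per_class = as.integer(replicates_per_class),
              n_genes = as.integer(n_genes),
              markers_per_class = as.integer(markers_per_class),
              marker_effect = marker_effect, noise_sd = noise_sd,
              baseline_expr = baseline_expr,
              n_control = as.integer(n_control),
              n_disease = as.integer(n_disease),
              baseline_fractions = baseline_fractions,
              fraction_shift = fraction_shift,
              dirichlet_conc = dirichlet_conc, mixing = mixing)
  class(cfg) <- "sim_config"
  cfg
}

#' Group-mean cell fractions implied by a configuration
#'
#' Control means are the baseline leukocyte fractions with stroma taking the
#' remainder. Disease means add \code{fraction_shift} to the named leukocyte
#' types; the shift displaces stroma (infiltrating cells replace resident
#' tissue), so unshifted leukocyte fractions stay at baseline. If the shifts
#' exceed the available stromal fraction, stroma is clipped to 0 and the
#' leukocyte fractions renormalized; a shift driving any fraction negative is
#' an error.
#'
#' @param cfg a \code{sim_config}.
#' @return list with numeric vectors \code{control} and \code{disease} over
#'   \code{c(classes, "stroma")}, each summing to 1.
#' @export
group_fractions <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ctrl <- c(cfg$baseline_fractions,
            stroma = 1 - sum(cfg$baseline_fractions))
  dis_leuko <- cfg$baseline_fractions
  if (length(cfg$fraction_shift) > 0L) {
    dis_leuko[names(cfg$fraction_shift)] <-
      dis_leuko[names(cfg$fraction_shift)] + cfg$fraction_shift
  }
  if (any(dis_leuko < 0)) {
    stop("fraction_shift drives a cell fraction below 0: infeasible")
  }
  stroma_d <- 1 - sum(dis_leuko)
  if (stroma_d < 0) {
    dis_leuko <- dis_leuko / sum(dis_leuko)
    stroma_d <- 0
  }
  dis <- c(dis_leuko, stroma = stroma_d)
  list(control = ctrl, disease = dis)
}

#' Simulate a purified-leukocyte reference
#'
#' Gene i in class c's marker set has mean
#' \code{baseline_expr + marker_effect * noise_sd} in class-c samples and
#' \code{baseline_expr} everywhere else; all values get i.i.d. Gaussian noise
#' with SD \code{noise_sd}. Marker sets are disjoint across classes and
#' sampled uniformly from the gene universe. The noiseless class mean
#' profiles are returned as \code{signatures} for downstream cohort mixing,
#' together with the flat stromal background signature.
#'
#' @param cfg a \code{sim_config}.
#' @param seed optional integer; when given, \code{set.seed(seed)} is called
#'   first so identical seed + config gives bit-identical output. When NULL
#'   the current RNG stream is used (callers managing their own seed).
#' @return list: \code{expression} (genes x samples matrix, class labels in
#'   the \code{"labels"} attribute), \code{labels}, \code{markers} (named
#'   list class -> true marker gene IDs), \code{signatures} (genes x classes
#'   noiseless means), \code{stromal_signature}.
#' @export
simulate_reference <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  K <- length(cfg$classes)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))

  marker_pool <- sample(genes, cfg$markers_per_class * K)
  markers <- split(marker_pool,
                   rep(cfg$classes, each = cfg$markers_per_class))
  markers <- markers[cfg$classes]

  signatures <- matrix(cfg$baseline_expr, nrow = cfg$n_genes, ncol = K,
                       dimnames = list(genes, cfg$classes))
  for (cl in cfg$classes) {
    signatures[markers[[cl]], cl] <-
      cfg$baseline_expr + cfg$marker_effect * cfg$noise_sd
  }

  reps <- cfg$replicates_per_class
  sample_ids <- paste(rep(cfg$classes, each = reps),
                      rep(seq_len(reps), times = K), sep = "_")
  labels <- stats::setNames(rep(cfg$classes, each = reps), sample_ids)
  expr <- signatures[, rep(cfg$classes, each = reps), drop = FALSE] +
    matrix(stats::rnorm(cfg$n_genes * K * reps, sd = cfg$noise_sd),
           nrow = cfg$n_genes)
  dimnames(expr) <- list(genes, sample_ids)
  attr(expr, "labels") <- labels

  list(expression = expr, labels = labels, markers = markers,
       signatures = signatures,
       stromal_signature = stats::setNames(
         rep(cfg$baseline_expr, cfg$n_genes), genes))
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a bulk-tissue cohort as mixtures of cell-type signatures
#'
#' Each sample's expression is
#' \eqn{\sum_c f_c \cdot \mathrm{signature}_c + f_{stroma} \cdot
#' \mathrm{stroma} + \varepsilon}, with per-sample fractions f drawn from a
#' Dirichlet distribution centered on the group means (see
#' \code{\link{group_fractions}}) with concentration
#' \code{dirichlet_conc}, and i.i.d. Gaussian noise with SD \code{noise_sd}.
#' Under \code{mixing = "lognormal"} signatures are mixed on the linear
#' (anti-log, base 2) scale and re-logged before noise.
#'
#' @param cfg a \code{sim_config} (cohort sizes, fractions, shifts, noise).
#' @param signatures genes x classes matrix of noiseless mean profiles,
#'   covering all of \code{cfg$classes} (typically from
#'   \code{\link{simulate_reference}}).
#' @param seed optional integer seed (see \code{\link{simulate_reference}}).
#' @param stromal_signature background profile for the non-leukocyte
#'   remainder; defaults to a flat \code{baseline_expr} profile.
#' @return list: \code{expression} (genes x samples, group labels in the
#'   \code{"labels"} attribute), \code{groups} (sample -> control/disease),
#'   \code{fractions} (samples x components true fractions, summing to 1 per
#'   sample, including \code{stroma}).
#' @export
simulate_cohort <- function(cfg, signatures, seed = NULL,
                            stromal_signature = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!all(cfg$classes %in% colnames(signatures))) {
    stop("signatures must cover all configured cell types")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(stromal_signature)) {
    stromal_signature <- rep(cfg$baseline_expr, nrow(signatures))
  }
  S <- cbind(signatures[, cfg$classes, drop = FALSE],
             stroma = stromal_signature)
  fr <- group_fractions(cfg)

  n_c <- cfg$n_control
  n_d <- cfg$n_disease
  sample_ids <- c(paste0("ctrl_", seq_len(n_c)),
                  paste0("dis_", seq_len(n_d)))
  groups <- stats::setNames(rep(c("control", "disease"), c(n_c, n_d)),
                            sample_ids)
  mean_f <- rbind(
    matrix(fr$control, nrow = n_c, ncol = ncol(S), byrow = TRUE),
    matrix(fr$disease, nrow = n_d, ncol = ncol(S), byrow = TRUE))
  fractions <- t(apply(mean_f, 1L, function(p) {
    rdirichlet1(cfg$dirichlet_conc * p)
  }))
  dimnames(fractions) <- list(sample_ids, colnames(S))

  clean <- if (cfg$mixing == "lognormal") {
    log2((2^S) %*% t(fractions))
  } else {
    S %*% t(fractions)
  }
  expr <- clean + matrix(stats::rnorm(length(clean), sd = cfg$noise_sd),
                         nrow = nrow(clean))
  dimnames(expr) <- list(rownames(signatures), sample_ids)
  attr(expr, "labels") <- groups

  list(expression = expr, groups = groups, fractions = fractions)
}
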