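#' Compare metagene scores between control and disease groups
#'
#' Per cell type, a two-sided two-sample t-test on the metagene scores.
#' The difference and t statistic follow the disease - control convention,
#' so increased infiltration in disease is positive. Significance is declared
#' at \code{p <= alpha} with no multiple-testing correction (per-cell-type
#' calls); a Benjamini-Hochberg adjusted column \code{bh_q} is emitted as
#' supplementary output.
#'
#' @param scores samples x cell types metagene score matrix.
#' @param groups named character vector sample -> group, values
#'   \code{"control"} or \code{"disease"}; defaults to the matrix's
#'   \code{"labels"} attribute. Both groups need >= 2 samples.
#' @param variant \code{"student"} (default; pooled variance,
#'   df = n1 + n2 - 2) or \code{"welch"} (Satterthwaite df).
#' @param alpha significance level (default 0.05).
#' @return data.frame, one row per cell type: \code{cell_type},
#'   \code{mean_control}, \code{mean_disease}, \code{diff}, \code{t},
#'   \code{df}, \code{p}, \code{significant}, \code{bh_q}.
#' @export
compare_groups <- function(scores, groups = attr(scores, "labels"),
                           variant = c("student", "welch"), alpha = 0.05) {
  variant <- match.arg(variant)
  if (is.null(groups)) stop("sample group labels are required")
  samples <- rownames(scores)
  unlabeled <- setdiff(samples, names(groups))
  if (length(unlabeled) > 0L) {
    stop("unlabeled samples: ", paste(unlabeled, collapse = ", "))
  }
  g <- unname(groups[samples])
  unknown <- setdiff(unique(g), c("control", "disease"))
  if (length(unknown) > 0L) {
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         " (expected 'control' or 'disease')")
  }
  is_ctrl <- g == "control"
  is_dis <- g == "disease"
  if (sum(is_ctrl) < 2L || sum(is_dis) < 2L) {
    stop("both groups need at least 2 samples (control: ", sum(is_ctrl),
         ", disease: ", sum(is_dis), ")")
  }

  rows <- lapply(colnames(scores), function(ct) {
    ctrl <- scores[is_ctrl, ct]
    dis <- scores[is_dis, ct]
    tt <- stats::t.test(dis, ctrl, var.equal = (variant == "student"),
                        alternative = "two.sided")
    data.frame(cell_type = ct,
               mean_control = mean(ctrl), mean_disease = mean(dis),
               diff = mean(dis) - mean(ctrl),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p <= alpha
  out$bh_q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Write a comparison table as TSV
#'
#' @param comparison data.frame from \code{\link{compare_groups}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  utils::write.table(comparison, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
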