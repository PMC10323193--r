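#' Reference-gene (delta-Ct) normalization
#'
#' For every sample, subtracts the arithmetic mean Ct of the panel's
#' reference genes from each target gene's Ct. Averaging on the Ct scale is
#' the geometric mean on the linear scale, the standard multi-reference
#' normalization. Reference genes are dropped from the output.
#'
#' @param ct A [ct_matrix()].
#' @param panel A [panel_spec()]; every reference gene must be measured
#'   (non-missing) in every sample.
#' @return An `expr_matrix` on the `delta_ct` scale (cycles; may be
#'   negative). Lower delta-Ct means higher expression.
#' @export
normalize_delta_ct <- function(ct, panel) {
  stopifnot(inherits(ct, "ct_matrix"), inherits(panel, "panel_spec"))
  miss <- setdiff(panel$all_genes, ct$genes)
  if (length(miss)) stop("panel genes absent from Ct matrix: ",
                         paste(miss, collapse = ", "))
  refs <- ct$values[, panel$reference_genes, drop = FALSE]
  if (anyNA(refs)) {
    idx <- which(is.na(refs), arr.ind = TRUE)[1, ]
    stop(sprintf("missing reference-gene measurement: sample '%s', gene '%s'",
                 rownames(refs)[idx[1]], colnames(refs)[idx[2]]))
  }
  ref_mean <- rowMeans(refs)
  targets <- setdiff(ct$genes, panel$reference_genes)
  vals <- ct$values[, targets, drop = FALSE] - ref_mean
  structure(
    list(values = vals,
         group = ct$group,
         genes = targets,
         sample_ids = ct$sample_ids,
         scale = "delta_ct"),
    class = "expr_matrix"
  )
}

#' Convert delta-Ct values to linear relative expression
#'
#' Elementwise `2^(-delta Ct)`; the resulting values are strictly positive
#' relative expression levels on which the per-gene t-tests run.
#'
#' @param expr An `expr_matrix` with scale `delta_ct`.
#' @return The same matrix on the `linear` scale.
#' @export
linearize <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$scale != "delta_ct") {
    stop("linearize() expects a delta_ct-scale matrix, got scale '",
         expr$scale, "'")
  }
  expr$values <- 2^(-expr$values)
  expr$scale <- "linear"
  expr
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("Expression matrix (", x$scale, "): ", nrow(x$values), " samples x ",
      ncol(x$values), " genes\n", sep = "")
  invisible(x)
}

#' High-Ct quality-control flag
#'
#' Category "A": the mean Ct is relatively high (> 30 cycles) in exactly one
#' of test/control and reasonably low (< 30) in the other — the fold value
#' rests on one weakly detected side. Category "B": mean Ct is high (> 30)
#' in both groups — expression is low everywhere and the fold value is
#' unreliable regardless of its p-value. Inequalities are strict; a mean of
#' exactly 30 cycles counts as low.
#'
#' @param mean_ct_test,mean_ct_control Group-mean raw Ct values (cycles).
#' @param ct_high Threshold, default 30 cycles.
#' @return One of `"none"`, `"A"`, `"B"` (vectorized).
#' @export
qc_flag <- function(mean_ct_test, mean_ct_control, ct_high = 30) {
  stopifnot(length(mean_ct_test) == length(mean_ct_control))
  hi_t <- mean_ct_test > ct_high
  hi_c <- mean_ct_control > ct_high
  out <- rep("none", length(hi_t))
  out[xor(hi_t, hi_c)] <- "A"
  out[hi_t & hi_c] <- "B"
  out
}

# Signed fold regulation from a fold change: FC itself when FC >= 1, else
# -1/FC, so that |FR| >= 1 always and up/down are symmetric around +-1.
fold_regulation <- function(fc) ifelse(fc >= 1, fc, -1 / fc)

#' Per-gene group comparison (fold change, fold regulation, t-test, QC)
#'
#' For each gene, computes the fold change of `test_group` over
#' `control_group` as `2^(-ddCt)` where `ddCt` is the difference of
#' group-mean delta-Ct values (equivalently the ratio of geometric means of
#' the linear replicates), the signed fold regulation, a two-sided pooled-
#' variance Student's t-test on the linear `2^(-dCt)` replicate values, and
#' the high-Ct QC flag from group-mean raw Ct.
#'
#' Genes whose Ct was undetermined (ceiling-substituted) in more than half
#' of either group's samples are excluded from the comparison with a
#' warning. If both groups are constant with equal values the p-value is 1
#' by convention.
#'
#' @param expr A linear-scale `expr_matrix` from [linearize()].
#' @param ct The source [ct_matrix()] (raw Ct, used for QC means).
#' @param test_group,control_group Group labels; each needs >= 2 samples.
#' @param ct_high QC threshold in cycles, default 30.
#' @return A data frame of class `ct_comparison` with columns `gene`,
#'   `p_value`, `fold_change`, `fold_regulation`, `qc_flag`,
#'   `mean_ct_test`, `mean_ct_control`.
#' @export
compare_groups <- function(expr, ct, test_group, control_group, ct_high = 30) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(ct, "ct_matrix"))
  if (expr$scale != "linear") {
    stop("compare_groups() expects linear-scale expression; run linearize()")
  }
  for (g in c(test_group, control_group)) {
    n <- sum(expr$group == g)
    if (n == 0L) stop("group '", g, "' absent from expression matrix")
    if (n < 2L) stop("group '", g, "' has a single sample; >= 2 required")
  }
  it <- expr$group == test_group
  ic <- expr$group == control_group

  genes <- expr$genes
  # drop genes undetermined in > 50% of either group's wells
  sub <- ct$substituted[, genes, drop = FALSE]
  frac_t <- colMeans(sub[it, , drop = FALSE])
  frac_c <- colMeans(sub[ic, , drop = FALSE])
  dropped <- genes[frac_t > 0.5 | frac_c > 0.5]
  if (length(dropped)) {
    warning("excluded from comparison (undetermined in > 50% of a group): ",
            paste(dropped, collapse = ", "))
    genes <- setdiff(genes, dropped)
  }

  res <- lapply(genes, function(g) {
    xt <- expr$values[it, g]
    xc <- expr$values[ic, g]
    fc <- 2^(mean(log2(xt)) - mean(log2(xc)))   # geometric-mean ratio
    if (stats::sd(xt) == 0 && stats::sd(xc) == 0) {
      p <- if (isTRUE(all.equal(mean(xt), mean(xc)))) 1 else 0
    } else {
      p <- stats::t.test(xt, xc, var.equal = TRUE)$p.value
    }
    data.frame(gene = g,
               p_value = p,
               fold_change = fc,
               fold_regulation = fold_regulation(fc),
               qc_flag = qc_flag(mean(ct$values[it, g]), mean(ct$values[ic, g]),
                                 ct_high),
               mean_ct_test = mean(ct$values[it, g]),
               mean_ct_control = mean(ct$values[ic, g]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("ct_comparison", "data.frame")
  attr(out, "test_group") <- test_group
  attr(out, "control_group") <- control_group
  out
}

#' @export
print.ct_comparison <- function(x, digits = 3, ...) {
  cat("Comparison:", attr(x, "test_group"), "vs.", attr(x, "control_group"),
      "(", nrow(x), "genes )\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Significance filter configuration
#'
#' @param alpha Significance level for the per-gene p-value, default 0.05.
#' @param fr_cutoff Absolute fold-regulation threshold, default 2.0. Both
#'   comparisons are strict.
#' @return A `filter_config` list.
#' @export
filter_config <- function(alpha = 0.05, fr_cutoff = 2.0) {
  stopifnot(alpha > 0, alpha < 1, fr_cutoff >= 1)
  structure(list(alpha = alpha, fr_cutoff = fr_cutoff),
            class = "filter_config")
}

#' Filter a comparison for significantly regulated genes
#'
#' A gene is called up-regulated when `p_value < alpha` and
#' `fold_regulation > fr_cutoff`, down-regulated when `p_value < alpha` and
#' `fold_regulation < -fr_cutoff`. Input row order is preserved.
#'
#' @param results A `ct_comparison` or any data frame with `gene`,
#'   `p_value` and `fold_regulation` columns (the packaged reference
#'   differential-expression tables qualify).
#' @param cfg A [filter_config()].
#' @return A list of class `deg_filter` with character vectors `up` and
#'   `down`.
#' @export
significance_filter <- function(results, cfg = filter_config()) {
  stopifnot(is.data.frame(results), nrow(results) > 0,
            all(c("gene", "p_value", "fold_regulation") %in% names(results)))
  sig <- results$p_value < cfg$alpha
  structure(
    list(up = results$gene[sig & results$fold_regulation > cfg$fr_cutoff],
         down = results$gene[sig & results$fold_regulation < -cfg$fr_cutoff]),
    class = "deg_filter"
  )
}

#' @export
print.deg_filter <- function(x, ...) {
  cat(length(x$up) + length(x$down), "significantly regulated genes\n")
  cat("  up  (", length(x$up), "):",
      if (length(x$up)) paste(x$up, collapse = ", ") else "-", "\n")
  cat("  down(", length(x$down), "):",
      if (length(x$down)) paste(x$down, collapse = ", ") else "-", "\n")
  invisible(x)
}

#' Write a comparison table to CSV
#'
#' @param results A `ct_comparison`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}

#' Packaged reference differential-expression tables
#'
#' Returns one of four packaged per-contrast tables (gene, p-value, fold
#' regulation, QC flag) reported for the rat cardiac-graft 88-gene array:
#' prolonged (5 h) vs. short (1 h) cold ischemia, and the alpha-1-
#' antitrypsin (AAT)-supplemented arms against their controls. These tables
#' list every gene printed with p < 0.05 in the source experiment; running
#' [significance_filter()] on them reproduces the reported counts of
#' up/down-regulated genes per contrast.
#'
#' @param contrast One of `"5h_vs_1h"`, `"1hAAT_vs_1h"`, `"5hAAT_vs_5h"`,
#'   `"5hAAT_vs_1hAAT"`.
#' @return A data frame with columns `gene`, `p_value`, `fold_regulation`,
#'   `qc_flag`.
#' @export
read_deg_table <- function(contrast = c("5h_vs_1h", "1hAAT_vs_1h",
                                        "5hAAT_vs_5h", "5hAAT_vs_1hAAT")) {
  contrast <- match.arg(contrast)
  path <- system.file("extdata", paste0("deg_", contrast, ".csv"),
                      package = "crossboruta", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "numeric", "numeric",
                                       "character"))
  df$qc_flag[is.na(df$qc_flag) | df$qc_flag == ""] <- "none"
  df
}
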