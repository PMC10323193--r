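#' Boruta configuration
#'
#' Tuning parameters of the all-relevant feature selector. Defaults follow
#' the canonical Boruta algorithm: 100 iterations maximum, a two-sided
#' binomial hit test at alpha = 0.01 with Bonferroni correction, and a
#' randomized regression forest of 200 trees per iteration.
#'
#' @param n_trees Trees per forest, >= 10.
#' @param max_iterations Maximum shadow iterations, >= 10.
#' @param alpha Two-sided binomial test level.
#' @param importance_kind `"impurity"` (variance-reduction, fast) or
#'   `"permutation"` (out-of-bag permutation importance).
#' @param multiple_test `"bonferroni"` (over the number of features) or
#'   `"none"`.
#' @param rng_seed Master seed; every forest and every shadow permutation is
#'   derived from it, so runs are reproducible.
#' @param tentative_resolution `"median_vs_shadow"` resolves leftover
#'   Tentative features by comparing their median importance with the
#'   median of the per-iteration shadow maxima (the usual rough fix);
#'   `"leave_tentative"` keeps them Tentative.
#' @return A `boruta_config` list.
#' @export
boruta_config <- function(n_trees = 200,
                          max_iterations = 100,
                          alpha = 0.01,
                          importance_kind = c("impurity", "permutation"),
                          multiple_test = c("bonferroni", "none"),
                          rng_seed = 1L,
                          tentative_resolution = c("median_vs_shadow",
                                                   "leave_tentative")) {
  stopifnot(n_trees >= 10, max_iterations >= 10, alpha > 0, alpha < 1)
  structure(
    list(n_trees = as.integer(n_trees),
         max_iterations = as.integer(max_iterations),
         alpha = alpha,
         importance_kind = match.arg(importance_kind),
         multiple_test = match.arg(multiple_test),
         rng_seed = as.integer(rng_seed),
         tentative_resolution = match.arg(tentative_resolution)),
    class = "boruta_config"
  )
}

#' Randomized-forest feature importance
#'
#' Fits a regression ensemble of randomized decision trees and returns one
#' non-negative importance score per feature: total variance-reduction
#' (impurity) importance by default, or out-of-bag permutation importance
#' (negative permutation scores are clamped at zero). Deterministic given
#' the configuration seed.
#'
#' @param X Numeric matrix, samples x features (>= 5 rows).
#' @param y Numeric target vector; must not be constant.
#' @param cfg A [boruta_config()].
#' @return Named numeric vector of importances.
#' @export
ensemble_importance <- function(X, y, cfg = boruta_config()) {
  X <- as.matrix(X)
  if (nrow(X) < 5) stop("ensemble_importance() needs >= 5 samples")
  if (ncol(X) < 1) stop("ensemble_importance() needs >= 1 feature")
  if (length(y) != nrow(X)) stop("y length must match nrow(X)")
  if (stats::sd(y) == 0) stop("constant target: no splits definable")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  fit <- ranger::ranger(
    x = as.data.frame(X), y = y,
    num.trees = cfg$n_trees,
    importance = cfg$importance_kind,
    num.threads = 1,
    seed = cfg$rng_seed,
    write.forest = FALSE
  )
  imp <- fit$variable.importance
  pmax(imp, 0)
}

#' Append shadow features
#'
#' Duplicates every column of `X` and independently permutes each copy's
#' rows, producing the empirical null against which real-feature
#' importances are judged.
#'
#' @param X Numeric matrix, samples x features.
#' @param rng_seed Seed controlling the permutations.
#' @return A list with `X_aug` (2m columns; shadows named `shadow_<gene>`),
#'   `is_shadow` (logical per column), and `shadow_of` (source column name
#'   per shadow).
#' @export
add_shadows <- function(X, rng_seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) < 1) stop("add_shadows() needs >= 1 feature")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  shadows <- with_seed(rng_seed, {
    apply(X, 2, function(col) col[sample.int(length(col))])
  })
  if (nrow(X) == 1L) shadows <- matrix(shadows, nrow = 1L)
  colnames(shadows) <- paste0("shadow_", colnames(X))
  list(X_aug = cbind(X, shadows),
       is_shadow = rep(c(FALSE, TRUE), each = ncol(X)),
       shadow_of = stats::setNames(colnames(X), colnames(shadows)))
}

# Two-sided binomial decision at level alpha2 (already multiplicity
# corrected and halved): +1 confirm, -1 reject, 0 undecided.
binomial_decision <- function(hits, n, alpha2) {
  p_hi <- stats::pbinom(hits - 1, n, 0.5, lower.tail = FALSE)
  p_lo <- stats::pbinom(hits, n, 0.5)
  ifelse(p_hi < alpha2, 1L, ifelse(p_lo < alpha2, -1L, 0L))
}

#' Run Boruta all-relevant feature selection (regression mode)
#'
#' Iteratively augments the feature matrix with fresh shadow copies, fits a
#' randomized regression forest, and scores a "hit" for every undecided
#' feature whose importance exceeds the maximum shadow importance of that
#' iteration. After each iteration every undecided feature's hit count is
#' tested against Binomial(iterations, 1/2), two-sided at `cfg$alpha` with
#' the configured multiplicity correction: significantly above chance
#' confirms the feature, significantly below rejects it. Iteration stops
#' when no feature is undecided or `cfg$max_iterations` is reached;
#' leftover Tentative features are resolved per
#' `cfg$tentative_resolution`.
#'
#' @param X Numeric matrix, samples x features (>= 5 rows).
#' @param y Numeric target.
#' @param cfg A [boruta_config()].
#' @return An object of class `boruta_fit`: `decisions` (named factor
#'   Confirmed/Tentative/Rejected), `hit_counts`, `median_importance`,
#'   `shadow_max_history`, `iterations_run`, and the pre-resolution
#'   `raw_decisions`.
#' @export
boruta_run <- function(X, y, cfg = boruta_config()) {
  X <- as.matrix(X)
  if (nrow(X) < 5) stop("boruta_run() needs >= 5 samples")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  m <- ncol(X)
  feats <- colnames(X)

  status <- stats::setNames(rep(0L, m), feats)   # 0 undecided, 1 conf, -1 rej
  hits <- stats::setNames(rep(0L, m), feats)
  imp_hist <- matrix(NA_real_, nrow = cfg$max_iterations, ncol = m,
                     dimnames = list(NULL, feats))
  shadow_max_hist <- numeric(0)

  denom <- if (cfg$multiple_test == "bonferroni") m else 1
  alpha2 <- cfg$alpha / denom / 2

  iter <- 0L
  while (iter < cfg$max_iterations && any(status == 0L)) {
    iter <- iter + 1L
    it_seed <- derive_seed(cfg$rng_seed, "iter", iter)
    sh <- add_shadows(X, rng_seed = it_seed)
    aug <- sh$X_aug
    is_shadow <- sh$is_shadow
    if (m < 5L) {
      # keep at least 5 shadow attributes so the max-shadow hit threshold
      # is a stable empirical null even for tiny panels
      pad <- with_seed(derive_seed(it_seed, "pad"), {
        src <- rep_len(seq_len(m), 5L - m)
        vapply(src, function(j) X[sample.int(nrow(X)), j],
               numeric(nrow(X)))
      })
      if (nrow(X) == 1L) pad <- matrix(pad, nrow = 1L)
      colnames(pad) <- paste0("shadow_pad_", seq_len(ncol(pad)))
      aug <- cbind(aug, pad)
      is_shadow <- c(is_shadow, rep(TRUE, ncol(pad)))
    }
    it_cfg <- cfg
    it_cfg$rng_seed <- derive_seed(it_seed, "forest")
    imp <- ensemble_importance(aug, y, it_cfg)
    real_imp <- imp[seq_len(m)]
    shadow_max <- max(imp[is_shadow])
    shadow_max_hist[iter] <- shadow_max
    imp_hist[iter, ] <- real_imp

    und <- status == 0L
    hits[und] <- hits[und] + as.integer(real_imp[und] > shadow_max)
    status[und] <- binomial_decision(hits[und], iter, alpha2)
  }

  raw <- factor(ifelse(status == 1L, "Confirmed",
                       ifelse(status == -1L, "Rejected", "Tentative")),
                levels = c("Confirmed", "Tentative", "Rejected"))
  names(raw) <- feats
  med_imp <- apply(imp_hist[seq_len(iter), , drop = FALSE], 2, stats::median)

  final <- raw
  if (cfg$tentative_resolution == "median_vs_shadow" && any(raw == "Tentative")) {
    shadow_med <- stats::median(shadow_max_hist)
    tent <- raw == "Tentative"
    final[tent] <- ifelse(med_imp[tent] > shadow_med, "Confirmed", "Rejected")
  }

  structure(
    list(decisions = final,
         raw_decisions = raw,
         hit_counts = hits,
         median_importance = med_imp,
         shadow_max_history = shadow_max_hist,
         iterations_run = iter,
         config = cfg),
    class = "boruta_fit"
  )
}

#' @export
print.boruta_fit <- function(x, ...) {
  cat("Boruta (regression mode):", length(x$decisions), "features,",
      x$iterations_run, "iterations\n")
  print(table(x$decisions))
  conf <- names(x$decisions)[x$decisions == "Confirmed"]
  if (length(conf)) cat("confirmed:", paste(conf, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.boruta_fit <- function(object, ...) {
  data.frame(feature = names(object$decisions),
             decision = as.character(object$decisions),
             hits = as.integer(object$hit_counts),
             hit_fraction = as.numeric(object$hit_counts) /
               object$iterations_run,
             median_importance = as.numeric(object$median_importance),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Serialize a Boruta fit to JSON
#'
#' @param fit A `boruta_fit`.
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
boruta_to_json <- function(fit, path = NULL) {
  obj <- list(decisions = as.list(stats::setNames(as.character(fit$decisions),
                                                  names(fit$decisions))),
              hit_counts = as.list(fit$hit_counts),
              median_importance = as.list(fit$median_importance),
              iterations_run = fit$iterations_run)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
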