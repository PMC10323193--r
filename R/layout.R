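#' Importance-derived target distances for network layout
#'
#' Converts edge weights into layout distances so that strongly associated
#' genes are drawn close together: an adjacent pair at normalized weight w
#' gets length `1 / (w + eps)`; non-adjacent pairs in the same connected
#' component get the graph shortest-path distance over those edge lengths;
#' pairs in different components are separated by `pad` times the largest
#' finite distance (the network diameter).
#'
#' @param net A `gene_network` with >= 2 nodes.
#' @param eps Regularizer keeping edge lengths finite at weight 0
#'   (default 0.05).
#' @param pad Disconnected-component padding factor (default 1.5).
#' @return Symmetric numeric matrix of target distances with zero diagonal.
#' @export
target_distances <- function(net, eps = 0.05, pad = 1.5) {
  stopifnot(inherits(net, "gene_network"), length(net$nodes) >= 2)
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$nodes)
  if (nrow(net$edges)) {
    g <- igraph::add_edges(
      g, rbind(net$edges$gene_a, net$edges$gene_b),
      weight = 1 / (net$edges$weight + eps))
  }
  D <- igraph::distances(g, weights = igraph::E(g)$weight)
  finite <- D[is.finite(D) & D > 0]
  sep <- if (length(finite)) pad * max(finite) else 1
  D[!is.finite(D)] <- sep
  D[net$nodes, net$nodes]
}

raw_stress <- function(X, D) {
  E <- as.matrix(stats::dist(X))
  sum(((E - D)[upper.tri(D)])^2)
}

guttman_step <- function(X, D) {
  n <- nrow(X)
  E <- as.matrix(stats::dist(X))
  ratio <- matrix(0, n, n)
  nz <- E > 0
  ratio[nz] <- D[nz] / E[nz]
  diag(ratio) <- 0
  B <- -ratio
  diag(B) <- rowSums(ratio)
  (B %*% X) / n
}

#' Stress-majorization (SMACOF) 2-D embedding
#'
#' Minimizes the raw stress `sum_(i<j) (||x_i - x_j|| - D_ij)^2` by
#' iterating the Guttman transform from a seeded random initialization.
#' Raw stress is non-increasing across iterations; the run stops when the
#' relative stress decrease falls below `tol` or at `max_iter`. Several
#' random restarts are performed and the lowest-stress solution kept.
#' Coordinates are arbitrary up to rotation/translation/reflection — the
#' inter-point distances, not the coordinates, are the contract.
#'
#' @param D Symmetric matrix with zero diagonal and positive off-diagonal
#'   entries.
#' @param rng_seed Seed for the random initializations.
#' @param tol Relative stress-decrease tolerance (default 1e-6).
#' @param max_iter Iteration cap per restart (default 500).
#' @param n_restarts Random restarts (default 5).
#' @return An object of class `network_layout`: `coordinates` (n x 2,
#'   row-named), `stress`, `stress_history`, `iterations_run`,
#'   `converged`.
#' @export
stress_majorization <- function(D, rng_seed = 1L, tol = 1e-6,
                                max_iter = 500L, n_restarts = 5L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || max(abs(D - t(D))) > 1e-12) {
    stop("D must be a symmetric square matrix")
  }
  if (any(diag(D) != 0)) stop("D must have a zero diagonal")
  if (any(D[upper.tri(D)] <= 0)) stop("off-diagonal target distances must be positive")

  best <- NULL
  scale0 <- max(D)
  for (r in seq_len(n_restarts)) {
    X <- with_seed(derive_seed(rng_seed, "restart", r), {
      repeat {
        X0 <- matrix(stats::rnorm(n * 2, sd = scale0 / 2), n, 2)
        if (n == 1 || min(stats::dist(X0)) > 1e-9) break  # reject coincident draw
      }
      X0
    })
    hist <- raw_stress(X, D)
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      X <- guttman_step(X, D)
      s <- raw_stress(X, D)
      hist[it + 1L] <- s
      prev <- hist[it]
      if (prev <= 0 || (prev - s) / prev < tol) {
        converged <- TRUE
        break
      }
    }
    cand <- list(coordinates = X, stress = hist[length(hist)],
                 stress_history = hist, iterations_run = it,
                 converged = converged)
    if (is.null(best) || cand$stress < best$stress) best <- cand
  }
  rownames(best$coordinates) <- rownames(D)
  colnames(best$coordinates) <- c("x", "y")
  structure(best, class = "network_layout")
}

#' @export
print.network_layout <- function(x, ...) {
  cat("SMACOF layout:", nrow(x$coordinates), "nodes, stress",
      format(x$stress, digits = 6), "after", x$iterations_run,
      "iterations", if (x$converged) "(converged)" else "(iteration cap)",
      "\n")
  invisible(x)
}

#' Lay out a gene network in 2-D
#'
#' Convenience wrapper: [target_distances()] followed by
#' [stress_majorization()].
#'
#' @param net A `gene_network`.
#' @param rng_seed Seed for the embedding restarts.
#' @param ... Passed to [stress_majorization()].
#' @return A `network_layout`.
#' @export
layout_network <- function(net, rng_seed = 1L, ...) {
  stress_majorization(target_distances(net), rng_seed = rng_seed, ...)
}

#' Write layout coordinates to CSV
#'
#' @param layout A `network_layout`.
#' @param path Output path (columns gene, x, y).
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  utils::write.csv(
    data.frame(gene = rownames(layout$coordinates),
               x = layout$coordinates[, "x"],
               y = layout$coordinates[, "y"], row.names = NULL),
    path, row.names = FALSE)
  invisible(path)
}

#' Plot a gene network
#'
#' Static plot: nodes at SMACOF positions, edges colored by Spearman class
#' (blue positive, red negative, grey otherwise), edge width proportional
#' to the normalized importance weight.
#'
#' @param x A `gene_network`.
#' @param layout Optional `network_layout`; computed via [layout_network()]
#'   when missing.
#' @param label_cex Node label size.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return The layout used, invisibly.
#' @export
plot.gene_network <- function(x, layout = NULL, label_cex = 0.7, ...) {
  if (length(x$nodes) < 2) stop("nothing to plot: fewer than 2 nodes")
  layout <- layout %||% layout_network(x)
  xy <- layout$coordinates
  graphics::plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "",
                 main = x$pool_label, asp = 1, ...)
  if (nrow(x$edges)) {
    cols <- c(positive = "#2166ac", negative = "#b2182b", grey = "grey60")
    graphics::segments(xy[x$edges$gene_a, 1], xy[x$edges$gene_a, 2],
                       xy[x$edges$gene_b, 1], xy[x$edges$gene_b, 2],
                       col = cols[x$edges$color],
                       lwd = 0.5 + 2.5 * x$edges$weight)
  }
  graphics::points(xy, pch = 21, bg = "white", cex = 2)
  graphics::text(xy, labels = rownames(xy), cex = label_cex)
  invisible(layout)
}
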