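#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (average ranks on ties), with a
#' two-sided p-value from the t approximation on n - 2 degrees of freedom.
#' A constant vector makes the coefficient undefined; by convention rho = 0
#' and p = 1 are returned with `degenerate = TRUE`.
#'
#' @param x,y Numeric vectors of equal length n >= 4.
#' @return A list with `rho`, `p`, `degenerate`.
#' @export
spearman_assoc <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4) stop("spearman_assoc() needs n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = 0, p = 1, degenerate = TRUE))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, degenerate = FALSE)
}

new_gene_network <- function(nodes, edges, pool_label, isolated_failures) {
  structure(
    list(nodes = nodes, edges = edges, pool_label = pool_label,
         failed_targets = isolated_failures),
    class = "gene_network"
  )
}

empty_edge_frame <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             weight = numeric(), raw_weight = numeric(),
             rho = numeric(), rho_p = numeric(),
             color = character(), stringsAsFactors = FALSE)
}

#' CrossBoruta gene-gene network inference
#'
#' Runs Boruta once per gene, with that gene's expression as the regression
#' target and every other gene as candidate feature. A candidate directed
#' association i <- j exists when feature j ends Confirmed for target i;
#' undirected edges are kept under the `union` rule (either direction
#' Confirmed, the default) or the stricter `intersection` rule (both).
#' Edge weight is the mean of the confirming directions' median
#' importances, min-max normalized to \[0, 1\] per network (`raw_weight`
#' keeps the unnormalized value). Each edge is annotated with the Spearman
#' correlation of the two genes over the pooled samples and colored
#' `positive`/`negative` when significant at `edge_alpha`, `grey`
#' otherwise.
#'
#' A target for which the forest cannot be grown (e.g. an exactly constant
#' gene) is skipped with a warning and remains an isolated node.
#'
#' @param expr An `expr_matrix` or [ct_matrix()] (>= 5 samples, >= 3
#'   genes). Raw Ct is a valid scale here: Ct-scale correlations carry the
#'   same sign as log-expression correlations.
#' @param cfg A [boruta_config()]; per-target seeds are derived from
#'   `cfg$rng_seed` and the target's gene symbol, so results do not depend
#'   on column order of the input.
#' @param edge_rule `"union"` or `"intersection"`.
#' @param edge_alpha Spearman significance level for edge coloring.
#' @param pool_label Label describing which study arm's samples built the
#'   network.
#' @return An object of class `gene_network` with `nodes`, an edge data
#'   frame (`gene_a`, `gene_b`, `weight`, `raw_weight`, `rho`, `rho_p`,
#'   `color`), and `pool_label`.
#' @export
crossboruta <- function(expr, cfg = boruta_config(),
                        edge_rule = c("union", "intersection"),
                        edge_alpha = 0.05, pool_label = "pooled") {
  edge_rule <- match.arg(edge_rule)
  vals <- if (is.matrix(expr)) expr else expr$values
  if (nrow(vals) < 5) stop("crossboruta() needs >= 5 samples")
  if (ncol(vals) < 2) stop("crossboruta() needs >= 2 genes")
  genes <- colnames(vals)

  confirmed <- vector("list", length(genes))   # per target: named importances
  names(confirmed) <- genes
  failed <- character(0)
  for (g in genes) {
    y <- vals[, g]
    X <- vals[, setdiff(genes, g), drop = FALSE]
    tcfg <- cfg
    tcfg$rng_seed <- derive_seed(cfg$rng_seed, "target", g)
    fit <- tryCatch(boruta_run(X, y, tcfg), error = function(e) e)
    if (inherits(fit, "error")) {
      warning("target '", g, "' failed (", conditionMessage(fit),
              "); left isolated")
      failed <- c(failed, g)
      confirmed[g] <- list(numeric(0))
      next
    }
    keep <- fit$decisions == "Confirmed"
    confirmed[[g]] <- fit$median_importance[names(fit$decisions)[keep]]
  }

  # assemble unordered pairs
  dir_w <- list()   # key -> numeric vector of confirming-direction weights
  for (g in genes) {
    ws <- confirmed[[g]]
    if (is.null(ws) || !length(ws)) next
    for (j in names(ws)) {
      k <- pair_key(g, j)
      dir_w[[k]] <- c(dir_w[[k]], ws[[j]])
    }
  }
  need <- if (edge_rule == "union") 1L else 2L
  keys <- names(dir_w)[vapply(dir_w, length, 1L) >= need]

  if (length(keys)) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    raw_w <- vapply(dir_w[keys], mean, 1)
    sp <- lapply(parts, function(p) spearman_assoc(vals[, p[1]], vals[, p[2]]))
    rho <- vapply(sp, `[[`, 1, "rho")
    rho_p <- vapply(sp, `[[`, 1, "p")
    color <- ifelse(rho_p < edge_alpha & rho > 0, "positive",
                    ifelse(rho_p < edge_alpha & rho < 0, "negative", "grey"))
    wspan <- max(raw_w) - min(raw_w)
    weight <- if (wspan > 0) (raw_w - min(raw_w)) / wspan else rep(1, length(raw_w))
    edges <- data.frame(
      gene_a = vapply(parts, `[[`, "", 1),
      gene_b = vapply(parts, `[[`, "", 2),
      weight = as.numeric(weight),
      raw_weight = as.numeric(raw_w),
      rho = rho, rho_p = rho_p, color = color,
      stringsAsFactors = FALSE)
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- empty_edge_frame()
  }
  new_gene_network(genes, edges, pool_label, failed)
}

#' @export
print.gene_network <- function(x, ...) {
  cat("Gene network [", x$pool_label, "]: ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  if (nrow(x$edges)) print(table(color = x$edges$color))
  invisible(x)
}

node_degrees <- function(net) {
  deg <- stats::setNames(rep(0L, length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    t1 <- table(net$edges$gene_a)
    t2 <- table(net$edges$gene_b)
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  deg
}

#' Summarize a gene network
#'
#' Edge counts by Spearman color class, degree-0 (disconnected) genes, the
#' mean absolute edge correlation, and a homogeneity score defined as
#' `1 - sd(edge rho)` — the sample standard deviation relative to its
#' maximum attainable value (1) for coefficients in \[-1, 1\]. A network
#' with fewer than two edges has homogeneity 1.
#'
#' @param net A `gene_network`.
#' @return An object of class `network_summary`.
#' @export
summarize_network <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  e <- net$edges
  deg <- node_degrees(net)
  homog <- if (nrow(e) < 2) 1 else 1 - stats::sd(e$rho)
  structure(
    list(pool_label = net$pool_label,
         n_nodes = length(net$nodes),
         n_edges = nrow(e),
         n_positive = sum(e$color == "positive"),
         n_negative = sum(e$color == "negative"),
         n_grey = sum(e$color == "grey"),
         disconnected_genes = names(deg)[deg == 0L],
         homogeneity = homog,
         mean_abs_rho = if (nrow(e)) mean(abs(e$rho)) else NA_real_),
    class = "network_summary"
  )
}

#' @export
print.network_summary <- function(x, ...) {
  cat("Network summary [", x$pool_label, "]\n", sep = "")
  cat("  nodes:", x$n_nodes, " edges:", x$n_edges,
      sprintf("(%d positive, %d negative, %d grey)\n",
              x$n_positive, x$n_negative, x$n_grey))
  cat("  homogeneity:", format(x$homogeneity, digits = 4),
      " mean |rho|:", format(x$mean_abs_rho, digits = 4), "\n")
  cat("  disconnected:",
      if (length(x$disconnected_genes))
        paste(x$disconnected_genes, collapse = ", ") else "-", "\n")
  invisible(x)
}

#' @export
summary.gene_network <- function(object, ...) summarize_network(object)

#' Contrast two gene networks over the same node set
#'
#' Reports per-metric differences (`a - b`) for positive/negative edge
#' counts and homogeneity, the Jaccard index of the two edge sets, and the
#' genes disconnected in exactly one of the networks.
#'
#' @param a,b `gene_network` objects sharing a node set.
#' @return An object of class `network_contrast`.
#' @export
compare_networks <- function(a, b) {
  stopifnot(inherits(a, "gene_network"), inherits(b, "gene_network"))
  sym <- c(setdiff(a$nodes, b$nodes), setdiff(b$nodes, a$nodes))
  if (length(sym)) {
    stop("node sets differ; symmetric difference: ",
         paste(sym, collapse = ", "))
  }
  sa <- summarize_network(a)
  sb <- summarize_network(b)
  ka <- pair_key(a$edges$gene_a, a$edges$gene_b)
  kb <- pair_key(b$edges$gene_a, b$edges$gene_b)
  uni <- union(ka, kb)
  jac <- if (length(uni)) length(intersect(ka, kb)) / length(uni) else 1
  structure(
    list(pool_a = a$pool_label, pool_b = b$pool_label,
         d_n_positive = sa$n_positive - sb$n_positive,
         d_n_negative = sa$n_negative - sb$n_negative,
         d_homogeneity = sa$homogeneity - sb$homogeneity,
         jaccard = jac,
         disconnected_only_a = setdiff(sa$disconnected_genes,
                                       sb$disconnected_genes),
         disconnected_only_b = setdiff(sb$disconnected_genes,
                                       sa$disconnected_genes)),
    class = "network_contrast"
  )
}

#' @export
print.network_contrast <- function(x, ...) {
  cat("Network contrast:", x$pool_a, "-", x$pool_b, "\n")
  cat("  d n_positive:", x$d_n_positive,
      " d n_negative:", x$d_n_negative,
      " d homogeneity:", format(x$d_homogeneity, digits = 4), "\n")
  cat("  edge-set Jaccard:", format(x$jaccard, digits = 4), "\n")
  invisible(x)
}

#' Export a gene network as edge/node tables and a summary JSON
#'
#' Writes `<prefix>_edges.tsv` (gene_a, gene_b, weight, rho, rho_p, color),
#' `<prefix>_nodes.tsv` (gene, degree, disconnected flag) and
#' `<prefix>_summary.json`.
#'
#' @param net A `gene_network`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
write_network <- function(net, dir, prefix = net$pool_label) {
  stopifnot(inherits(net, "gene_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- gsub("[^A-Za-z0-9._-]", "_", prefix)
  p_edges <- file.path(dir, paste0(prefix, "_edges.tsv"))
  p_nodes <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  p_sum <- file.path(dir, paste0(prefix, "_summary.json"))
  utils::write.table(
    net$edges[, c("gene_a", "gene_b", "weight", "rho", "rho_p", "color")],
    p_edges, sep = "\t", row.names = FALSE, quote = FALSE)
  deg <- node_degrees(net)
  utils::write.table(
    data.frame(gene = names(deg), degree = as.integer(deg),
               disconnected = deg == 0L),
    p_nodes, sep = "\t", row.names = FALSE, quote = FALSE)
  s <- summarize_network(net)
  writeLines(jsonlite::toJSON(unclass(s), auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), p_sum)
  invisible(c(p_edges, p_nodes, p_sum))
}
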