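#' Decision-tree induction configuration
#'
#' @param min_leaf Minimum samples per leaf, >= 1 (default 2).
#' @param max_depth Optional depth cap (`Inf` = none).
#' @return A `tree_config` list. The split criterion is always the C4.5
#'   information gain ratio; no pruning is applied.
#' @export
tree_config <- function(min_leaf = 2L, max_depth = Inf) {
  stopifnot(min_leaf >= 1)
  structure(list(min_leaf = as.integer(min_leaf), max_depth = max_depth,
                 criterion = "gain_ratio", pruning = "none"),
            class = "tree_config")
}

entropy <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Best gain-ratio split of one feature
#'
#' Evaluates every candidate threshold (midpoints of consecutive distinct
#' sorted values) of a binary `<= / >` split and returns the one maximizing
#' the information gain ratio (information gain divided by split
#' information), subject to both sides holding at least `min_leaf` samples.
#' Ties are broken toward the smaller threshold.
#'
#' @param values Numeric feature vector.
#' @param labels Class label per sample (>= 2 classes for a useful split).
#' @param min_leaf Minimum samples per side.
#' @return A list `(threshold, gain_ratio)`, or `NULL` when no valid split
#'   exists (constant values, one class, or the min-leaf constraint).
#' @export
best_split <- function(values, labels, min_leaf = 2L) {
  n <- length(values)
  stopifnot(length(labels) == n)
  if (length(unique(labels)) < 2L || n < 2L * min_leaf) return(NULL)
  v <- sort(unique(values))
  if (length(v) < 2L) return(NULL)
  cuts <- (v[-1] + v[-length(v)]) / 2
  h0 <- entropy(labels)
  best <- NULL
  for (cut in cuts) {
    left <- values <= cut
    nl <- sum(left)
    nr <- n - nl
    if (nl < min_leaf || nr < min_leaf) next
    gain <- h0 - (nl / n) * entropy(labels[left]) -
      (nr / n) * entropy(labels[!left])
    split_info <- -(nl / n) * log2(nl / n) - (nr / n) * log2(nr / n)
    gr <- gain / split_info
    if (is.null(best) || gr > best$gain_ratio + 1e-12) {
      best <- list(threshold = cut, gain_ratio = gr)
    }
  }
  best
}

leaf_node <- function(labels) {
  tab <- table(labels)
  tab <- tab[tab > 0]
  list(kind = "leaf",
       labels = names(tab),
       counts = as.integer(tab))
}

grow <- function(X, labels, cfg, depth) {
  n <- length(labels)
  if (length(unique(labels)) < 2L || n < 2L * cfg$min_leaf ||
      depth >= cfg$max_depth) {
    return(leaf_node(labels))
  }
  best <- NULL
  for (j in seq_len(ncol(X))) {   # panel order breaks feature ties
    cand <- best_split(X[, j], labels, cfg$min_leaf)
    if (!is.null(cand) &&
        (is.null(best) || cand$gain_ratio > best$gain_ratio + 1e-12)) {
      best <- c(cand, list(feature = colnames(X)[j], j = j))
    }
  }
  if (is.null(best) || best$gain_ratio <= 0) return(leaf_node(labels))
  left <- X[, best$j] <= best$threshold
  list(kind = "split",
       feature = best$feature,
       threshold = best$threshold,
       gain_ratio = best$gain_ratio,
       left = grow(X[left, , drop = FALSE], labels[left], cfg, depth + 1L),
       right = grow(X[!left, , drop = FALSE], labels[!left], cfg, depth + 1L))
}

#' Induce a gain-ratio decision tree
#'
#' Recursive binary partitioning over gene-expression features: at each
#' node the feature/threshold pair with the highest information gain ratio
#' is chosen ([best_split()]; feature ties resolved by column order), with
#' `<=` routed left. Recursion stops at class purity, the min-leaf
#' constraint, the optional depth cap, or when no split improves on zero
#' gain. Leaves record the set of class labels present with their counts —
#' leaves may be impure and carry several labels.
#'
#' @param X Numeric matrix, samples x genes, with column names.
#' @param labels Group label per sample (>= 2 classes).
#' @param cfg A [tree_config()].
#' @return An object of class `decision_tree`.
#' @export
induce_tree <- function(X, labels, cfg = tree_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) stop("one label per sample required")
  if (length(unique(labels)) < 2L) stop("need >= 2 classes")
  if (nrow(X) < 2L * cfg$min_leaf) stop("need >= 2 * min_leaf samples")
  structure(list(root = grow(X, labels, cfg, 0L), config = cfg,
                 features = colnames(X)),
            class = "decision_tree")
}

tree_features <- function(node) {
  if (node$kind == "leaf") return(character(0))
  unique(c(node$feature, tree_features(node$left), tree_features(node$right)))
}

route <- function(node, sample) {
  while (node$kind == "split") {
    v <- sample[[node$feature]]
    if (is.null(v) || is.na(v)) {
      stop("sample is missing tested gene '", node$feature, "'")
    }
    node <- if (v <= node$threshold) node$left else node$right
  }
  node$labels
}

#' Apply a decision tree to one sample
#'
#' Deterministic root-to-leaf routing: a value less than or equal to the
#' node threshold goes left. Returns the leaf's label set (possibly more
#' than one group).
#'
#' @param model A `decision_tree`.
#' @param sample Named numeric vector or single-row data frame covering
#'   every gene the tree tests.
#' @return Character vector of group labels.
#' @export
apply_tree <- function(model, sample) {
  stopifnot(inherits(model, "decision_tree"))
  if (is.data.frame(sample)) sample <- as.list(sample[1, , drop = FALSE])
  if (is.numeric(sample)) sample <- as.list(sample)
  route(model$root, sample)
}

#' Predict group label sets for a sample matrix
#'
#' @param object A `decision_tree`.
#' @param newdata Matrix or data frame, one row per sample, columns named
#'   by gene.
#' @param ... Unused.
#' @return A list of character vectors (one label set per row).
#' @export
predict.decision_tree <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  lapply(seq_len(nrow(newdata)), function(i) {
    apply_tree(object, as.list(newdata[i, , drop = FALSE]))
  })
}

render_node <- function(node, indent) {
  pad <- strrep("  ", indent)
  if (node$kind == "leaf") {
    return(paste0(pad, "-> {", paste(node$labels, collapse = ", "), "} (n=",
                  paste(node$counts, collapse = "/"), ")"))
  }
  c(paste0(pad, node$feature, " <= ", format(node$threshold)),
    render_node(node$left, indent + 1L),
    paste0(pad, node$feature, " > ", format(node$threshold)),
    render_node(node$right, indent + 1L))
}

#' @export
print.decision_tree <- function(x, ...) {
  cat("Gain-ratio decision tree over features:",
      paste(tree_features(x$root), collapse = ", "), "\n")
  cat(render_node(x$root, 0L), sep = "\n")
  invisible(x)
}

node_to_list <- function(node) {
  if (node$kind == "leaf") {
    out <- list(labels = as.list(node$labels))
    if (!anyNA(node$counts)) out$counts <- as.list(node$counts)
    out
  } else {
    list(feature = node$feature, threshold = node$threshold,
         left = node_to_list(node$left), right = node_to_list(node$right))
  }
}

node_from_list <- function(obj) {
  if (!is.null(obj$feature)) {
    list(kind = "split", feature = obj$feature,
         threshold = as.numeric(obj$threshold),
         left = node_from_list(obj$left), right = node_from_list(obj$right))
  } else {
    labels <- unlist(obj$labels)
    counts <- if (is.null(obj$counts)) {
      rep(NA_integer_, length(labels))
    } else {
      as.integer(unlist(obj$counts))
    }
    list(kind = "leaf", labels = labels, counts = counts)
  }
}

#' Serialize / deserialize a decision tree as JSON
#'
#' @param model A `decision_tree`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return `tree_to_json`: the JSON string (invisibly when written);
#'   `tree_from_json`: a `decision_tree`.
#' @export
tree_to_json <- function(model, path = NULL) {
  js <- jsonlite::toJSON(node_to_list(model$root), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname tree_to_json
#' @param json JSON string or path to a JSON file.
#' @export
tree_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  root <- node_from_list(obj)
  structure(list(root = root, config = tree_config(),
                 features = tree_features(root)),
            class = "decision_tree")
}

split_node <- function(feature, threshold, left, right) {
  list(kind = "split", feature = feature, threshold = threshold,
       left = left, right = right)
}

fixed_leaf <- function(labels) {
  list(kind = "leaf", labels = labels, counts = rep(NA_integer_,
                                                    length(labels)))
}

#' Reference inter-group classification tree
#'
#' The fixed decision tree reported for inter-group classification of rat
#' cardiac grafts by myocardial gene expression, encoded exactly as
#' published: root split on Flt1 at 23.029; the low-Flt1 branch splits on
#' Gpx3 at 20.448 (low: 1h or 5h ischemia; high: 5h ischemia+AAT); the
#' high-Flt1 branch splits on Cflar at 21.651 (low: 5h ischemia; high:
#' split on Bcl2 at 21.798, low giving 1h ischemia / 5h ischemia /
#' 5h ischemia+AAT and high giving 1h ischemia / 5h ischemia+AAT).
#' Leaf label sets are multi-valued; leaf sample counts were not reported
#' and are stored as `NA`.
#'
#' @return A `decision_tree` over Flt1, Gpx3, Cflar, Bcl2.
#' @export
reference_tree <- function() {
  root <- split_node(
    "Flt1", 23.029,
    left = split_node(
      "Gpx3", 20.448,
      left = fixed_leaf(c("1h ischemia", "5h ischemia")),
      right = fixed_leaf("5h ischemia+AAT")),
    right = split_node(
      "Cflar", 21.651,
      left = fixed_leaf("5h ischemia"),
      right = split_node(
        "Bcl2", 21.798,
        left = fixed_leaf(c("1h ischemia", "5h ischemia",
                            "5h ischemia+AAT")),
        right = fixed_leaf(c("1h ischemia", "5h ischemia+AAT")))))
  structure(list(root = root, config = tree_config(),
                 features = c("Flt1", "Gpx3", "Cflar", "Bcl2")),
            class = "decision_tree")
}
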