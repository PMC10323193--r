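# Shared fixtures and independent oracles used across test files.

# Tiny panel for fast end-to-end runs.
tiny_panel <- function(n_targets = 4) {
  panel_spec(c(paste0("G", seq_len(n_targets)), "Ref1", "Ref2"),
             reference_genes = c("Ref1", "Ref2"))
}

# Build a ct_matrix whose linear 2^(-dCt) values equal `linear` exactly,
# using a single-valued reference baseline of 20 cycles.
ct_from_linear <- function(linear, group, panel = NULL) {
  linear <- as.matrix(linear)
  genes <- colnames(linear) %||% paste0("G", seq_len(ncol(linear)))
  colnames(linear) <- genes
  panel <- panel %||% panel_spec(c(genes, "Ref1", "Ref2"),
                                 reference_genes = c("Ref1", "Ref2"))
  ct_vals <- cbind(20 - log2(linear),
                   matrix(20, nrow(linear), 2,
                          dimnames = list(NULL, c("Ref1", "Ref2"))))
  list(ct = ct_matrix(ct_vals, group), panel = panel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Generator config with two 4-gene latent modules, four independent noise
# genes and two silent (noise-floor, high-baseline) genes over a pooled
# two-batch design of 32 samples -- the planted-structure recovery setting.
module_recovery_config <- function(master_seed = 1) {
  genes <- c(paste0("M1_", 1:4), paste0("M2_", 1:4), paste0("N", 1:4),
             "S1", "S2")
  panel <- panel_spec(c(genes, "Ref1", "Ref2"),
                      reference_genes = c("Ref1", "Ref2"))
  generator_config(
    panel = panel,
    group_sizes = c(armA = 16, armB = 16),
    modules = list(
      list(genes = paste0("M1_", 1:4), pool = c("armA", "armB"), loading = 1),
      list(genes = paste0("M2_", 1:4), pool = c("armA", "armB"), loading = 1)),
    silent_genes = c("S1", "S2"),
    master_seed = master_seed)
}

# Small two-arm config contrasting a coherent positive module (treated arm)
# with a mixed-sign module (vehicle arm) on a shared 8-gene panel.
arm_contrast_config <- function(master_seed = 1) {
  genes <- c(paste0("P", 1:4), paste0("Q", 1:4))
  panel <- panel_spec(c(genes, "Ref1", "Ref2"),
                      reference_genes = c("Ref1", "Ref2"))
  generator_config(
    panel = panel,
    group_sizes = c(vehicle = 15, treated = 15),
    modules = list(
      list(genes = paste0("P", 1:4), pool = "treated", loading = 1,
           signs = c(1, 1, 1, 1)),
      list(genes = paste0("Q", 1:4), pool = "vehicle", loading = 1,
           signs = c(1, 1, -1, -1))),
    master_seed = master_seed)
}

ml_matrix <- function(sim, cfg) {
  m <- sim$ct
  m$values <- m$values[, cfg$panel$target_genes, drop = FALSE]
  m$genes <- cfg$panel$target_genes
  m
}

# ---- independent oracles ------------------------------------------------

# All-pairs shortest paths by Floyd-Warshall over an explicit length matrix
# (Inf where no edge).
floyd_warshall <- function(L) {
  n <- nrow(L)
  D <- L
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# Exhaustive gain-ratio search over every midpoint cut (independent of
# best_split's internals).
brute_gain_ratio <- function(values, labels, min_leaf) {
  ent <- function(l) {
    p <- table(l) / length(l)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  n <- length(values)
  v <- sort(unique(values))
  if (length(v) < 2 || length(unique(labels)) < 2) return(NULL)
  best <- NULL
  for (cut in (v[-1] + v[-length(v)]) / 2) {
    nl <- sum(values <= cut)
    nr <- n - nl
    if (nl < min_leaf || nr < min_leaf) next
    gain <- ent(labels) - (nl / n) * ent(labels[values <= cut]) -
      (nr / n) * ent(labels[values > cut])
    si <- -(nl / n) * log2(nl / n) - (nr / n) * log2(nr / n)
    gr <- gain / si
    if (is.null(best) || gr > best$gain_ratio + 1e-12) {
      best <- list(threshold = cut, gain_ratio = gr)
    }
  }
  best
}

# Flat re-implementation of the five published classification rules.
rule_oracle <- function(s) {
  if (s[["Flt1"]] <= 23.029) {
    if (s[["Gpx3"]] <= 20.448) c("1h ischemia", "5h ischemia")
    else "5h ischemia+AAT"
  } else {
    if (s[["Cflar"]] <= 21.651) "5h ischemia"
    else if (s[["Bcl2"]] <= 21.798) c("1h ischemia", "5h ischemia",
                                      "5h ischemia+AAT")
    else c("1h ischemia", "5h ischemia+AAT")
  }
}

# Four-group sample matrix following the reference tree's topology with the
# planted thresholds 23.0 / 20.4 / 21.7 / 21.8 and Gaussian noise.
planted_tree_data <- function(seed, n_per_group = 8, noise_sd = 0.5) {
  set.seed(seed)
  groups <- rep(c("A", "B", "C", "D"), each = n_per_group)
  n <- length(groups)
  X <- cbind(
    root = rnorm(n, ifelse(groups %in% c("A", "B"), 22, 24), noise_sd),
    subL = rnorm(n, ifelse(groups == "A", 19.4,
                           ifelse(groups == "B", 21.4, 20.4)), noise_sd),
    subR = rnorm(n, ifelse(groups == "C", 20.7,
                           ifelse(groups == "D", 22.7, 21.7)), noise_sd),
    extra = rnorm(n, 21.8, noise_sd))
  list(X = X, labels = groups,
       planted = c(root = 23.0, subL = 20.4, subR = 21.7, extra = 21.8))
}
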