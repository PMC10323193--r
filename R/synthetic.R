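#' Synthetic-study generator configuration
#'
#' Describes a simulated qPCR array experiment with the four-group rat
#' cardiac-graft design: per-gene baseline Ct levels, Gaussian Ct noise,
#' stable reference genes, planted differential-expression effects
#' (contrast-wise log2 fold changes realized as Ct shifts of the test
#' group), latent-factor co-expression modules restricted to an arm pool,
#' and near-silent (high-Ct, low-variance-signal) genes.
#'
#' @param panel A [panel_spec()]; default [default_panel()] (88 targets +
#'   5 reference genes).
#' @param group_sizes Named integer vector, default the study design:
#'   1h ischemia 7, 1h ischemia+AAT 7, 5h ischemia 7, 5h ischemia+AAT 9.
#'   All sizes >= 2.
#' @param baseline_range Ct range the per-gene baselines are drawn from
#'   (default 18-28 cycles).
#' @param silent_baseline_range Baseline range for `silent_genes`
#'   (default 31-34 cycles, above the QC ceiling of 30).
#' @param baseline_overrides Optional named vector pinning specific genes'
#'   baselines.
#' @param noise_sd Ct noise standard deviation for target genes (cycles,
#'   default 0.5).
#' @param reference_sd Ct noise s.d. for reference genes (default 0.15) —
#'   reference genes carry no planted effects or modules.
#' @param de_effects Data frame with columns `gene`, `test_group`,
#'   `control_group`, `log2fc`: a planted log2 fold change of delta lowers
#'   the test group's Ct by delta cycles on that gene.
#' @param modules List of lists with elements `genes`, `pool` (group
#'   labels sharing the latent factor), `loading` in (0, 1], and optional
#'   `signs` (+-1 per gene). The per-sample latent factor is standard
#'   normal on the Ct scale, so two genes with loading a and noise s have
#'   expected Pearson correlation a^2 / (a^2 + s^2) within the pool.
#' @param silent_genes Target genes given high baselines (degree-0
#'   candidates in downstream networks).
#' @param master_seed Integer master seed; the full draw is deterministic
#'   given it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(panel = default_panel(),
                             group_sizes = c("1h ischemia" = 7,
                                             "1h ischemia+AAT" = 7,
                                             "5h ischemia" = 7,
                                             "5h ischemia+AAT" = 9),
                             baseline_range = c(18, 28),
                             silent_baseline_range = c(31, 34),
                             baseline_overrides = NULL,
                             noise_sd = 0.5,
                             reference_sd = 0.15,
                             de_effects = NULL,
                             modules = list(),
                             silent_genes = character(),
                             master_seed = 1L) {
  stopifnot(inherits(panel, "panel_spec"))
  if (is.null(names(group_sizes)) || any(names(group_sizes) == "")) {
    stop("group_sizes must be a named vector")
  }
  if (any(group_sizes < 2)) stop("every group needs >= 2 samples")
  stopifnot(noise_sd > 0, reference_sd > 0)
  if (is.null(de_effects)) {
    de_effects <- data.frame(gene = character(), test_group = character(),
                             control_group = character(), log2fc = numeric(),
                             stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "test_group", "control_group", "log2fc") %in%
                  names(de_effects)))
  bad <- setdiff(de_effects$gene, panel$target_genes)
  if (length(bad)) {
    stop("de_effects genes must be non-reference panel genes; offending: ",
         paste(unique(bad), collapse = ", "))
  }
  badg <- setdiff(c(de_effects$test_group, de_effects$control_group),
                  names(group_sizes))
  if (length(badg)) stop("de_effects reference undeclared groups: ",
                         paste(unique(badg), collapse = ", "))
  for (m in modules) {
    stopifnot(all(c("genes", "pool", "loading") %in% names(m)))
    if (m$loading <= 0 || m$loading > 1) stop("module loadings must be in (0, 1]")
    if (length(setdiff(m$genes, panel$target_genes))) {
      stop("module genes must be non-reference panel genes")
    }
    if (length(setdiff(m$pool, names(group_sizes)))) {
      stop("module pool references undeclared groups")
    }
    if (!is.null(m$signs) && length(m$signs) != length(m$genes)) {
      stop("module signs must match module genes")
    }
  }
  if (length(setdiff(silent_genes, panel$target_genes))) {
    stop("silent_genes must be non-reference panel genes")
  }
  structure(
    list(panel = panel, group_sizes = group_sizes,
         baseline_range = baseline_range,
         silent_baseline_range = silent_baseline_range,
         baseline_overrides = baseline_overrides,
         noise_sd = noise_sd, reference_sd = reference_sd,
         de_effects = de_effects, modules = modules,
         silent_genes = silent_genes,
         master_seed = as.integer(master_seed)),
    class = "generator_config"
  )
}

#' Simulate a synthetic qPCR study
#'
#' Draws a Ct matrix under the configured design:
#' `Ct(s, g) = baseline(g) + group shift + module latent term + noise`,
#' where a planted log2 fold change of delta lowers the affected group's
#' Ct by delta cycles, each module adds `sign * loading * f_s` with a
#' shared per-sample standard-normal factor inside its arm pool, and noise
#' is Gaussian on the Ct scale (`noise_sd` for targets, `reference_sd` for
#' reference genes, which carry no effects). Bit-identical output for a
#' given seed.
#'
#' @param cfg A [generator_config()].
#' @param master_seed Seed override; defaults to `cfg$master_seed`.
#' @return A list with `ct` (a [ct_matrix()]) and `truth`, the planted
#'   ground truth: per-gene baselines, the gene x group Ct-shift matrix,
#'   the planted DE table with true per-contrast log2 fold changes, the
#'   planted within-module edge list, and expected and realized per-gene
#'   per-group mean delta-Ct.
#' @export
simulate_study <- function(cfg, master_seed = cfg$master_seed) {
  stopifnot(inherits(cfg, "generator_config"))
  panel <- cfg$panel
  genes <- panel$all_genes
  targets <- panel$target_genes
  refs <- panel$reference_genes
  groups <- names(cfg$group_sizes)
  n_total <- sum(cfg$group_sizes)

  group_of <- rep(groups, times = cfg$group_sizes)
  ids <- unlist(lapply(groups, function(g) {
    paste0(gsub("[^A-Za-z0-9]+", "_", g), "_", seq_len(cfg$group_sizes[[g]]))
  }))

  baseline <- with_seed(derive_seed(master_seed, "baseline"), {
    b <- stats::setNames(
      stats::runif(length(genes), cfg$baseline_range[1], cfg$baseline_range[2]),
      genes)
    if (length(cfg$silent_genes)) {
      b[cfg$silent_genes] <- stats::runif(length(cfg$silent_genes),
                                          cfg$silent_baseline_range[1],
                                          cfg$silent_baseline_range[2])
    }
    if (!is.null(cfg$baseline_overrides)) {
      b[names(cfg$baseline_overrides)] <- cfg$baseline_overrides
    }
    b
  })

  # Ct shift per gene x group: a +delta log2 FC lowers Ct by delta cycles.
  shift <- matrix(0, length(genes), length(groups),
                  dimnames = list(genes, groups))
  for (i in seq_len(nrow(cfg$de_effects))) {
    e <- cfg$de_effects[i, ]
    shift[e$gene, e$test_group] <- shift[e$gene, e$test_group] - e$log2fc
  }

  vals <- matrix(0, n_total, length(genes), dimnames = list(ids, genes))
  vals[] <- rep(baseline, each = n_total)
  vals <- vals + t(shift)[group_of, , drop = FALSE]

  if (length(cfg$modules)) {
    factors <- with_seed(derive_seed(master_seed, "modules"), {
      matrix(stats::rnorm(n_total * length(cfg$modules)), n_total)
    })
    for (k in seq_along(cfg$modules)) {
      m <- cfg$modules[[k]]
      signs <- m$signs %||% rep(1, length(m$genes))
      in_pool <- group_of %in% m$pool
      term <- outer(factors[, k] * in_pool, m$loading * signs)
      vals[, m$genes] <- vals[, m$genes] + term
    }
  }

  noise <- with_seed(derive_seed(master_seed, "noise"), {
    n <- matrix(stats::rnorm(n_total * length(genes), sd = cfg$noise_sd),
                n_total, length(genes), dimnames = list(ids, genes))
    n[, refs] <- stats::rnorm(n_total * length(refs), sd = cfg$reference_sd)
    n
  })
  vals <- vals + noise

  ct <- ct_matrix(vals, group_of, groups = groups)

  # planted truth
  de <- cfg$de_effects
  de$true_log2fc <- vapply(seq_len(nrow(de)), function(i) {
    shift[de$gene[i], de$control_group[i]] - shift[de$gene[i], de$test_group[i]]
  }, 1)
  module_edges <- do.call(rbind, lapply(seq_along(cfg$modules), function(k) {
    gs <- sort(cfg$modules[[k]]$genes)
    if (length(gs) < 2) return(NULL)
    pr <- t(utils::combn(gs, 2))
    data.frame(gene_a = pr[, 1], gene_b = pr[, 2], module = k,
               pool = paste(cfg$modules[[k]]$pool, collapse = "+"),
               stringsAsFactors = FALSE)
  })) %||% data.frame(gene_a = character(), gene_b = character(),
                      module = integer(), pool = character())

  expected_dct <- (baseline[targets] + shift[targets, , drop = FALSE]) -
    mean(baseline[refs])
  expr <- normalize_delta_ct(ct, panel)
  realized_dct <- vapply(groups, function(g) {
    colMeans(expr$values[expr$group == g, , drop = FALSE])
  }, numeric(length(targets)))

  truth <- list(baseline = baseline, ct_shift = shift, de_table = de,
                module_edges = module_edges,
                expected_delta_ct = expected_dct,
                realized_delta_ct = realized_dct,
                master_seed = master_seed)
  list(ct = ct, truth = truth)
}

#' Study-structured generator preset
#'
#' Generator configuration planting the qualitative structure of the rat
#' cardiac-graft findings on the default 88-gene panel: the six genes
#' regulated by prolonged (5 h vs. 1 h) ischemia at their reported fold
#' regulations (Fos 2.29, Hspa1a 3.70, Txnrd1 2.33, Ccl2 3.92, Icam1 2.40
#' up; Tlr4 5.85 down), planted identically in the vehicle and AAT arms so
#' the 5h+AAT vs. 5h contrast stays null for them; Ccl11 up (3.00) and
#' Vcam1 down (2.35) in the 5h ischemia+AAT group; one coherent
#' positive-correlation module in the AAT arm pool versus a mixed-sign
#' module in the vehicle pool; silent genes Il9, Gpx5, Gpx6; and a Tlr4
#' baseline of 28.5 cycles so its down-regulation pushes the 5 h arms past
#' the 30-cycle QC threshold.
#'
#' @param master_seed Integer master seed.
#' @return A [generator_config()].
#' @export
study_preset <- function(master_seed = 1L) {
  de_main <- data.frame(
    gene = c("Fos", "Hspa1a", "Txnrd1", "Ccl2", "Icam1", "Tlr4"),
    log2fc = c(log2(2.29), log2(3.70), log2(2.33), log2(3.92), log2(2.40),
               -log2(5.85)),
    stringsAsFactors = FALSE)
  de <- rbind(
    transform(de_main, test_group = "5h ischemia",
              control_group = "1h ischemia"),
    transform(de_main, test_group = "5h ischemia+AAT",
              control_group = "1h ischemia+AAT"),
    data.frame(gene = c("Ccl11", "Vcam1"),
               log2fc = c(log2(3.00), -log2(2.35)),
               test_group = "5h ischemia+AAT",
               control_group = "5h ischemia",
               stringsAsFactors = FALSE))
  generator_config(
    de_effects = de[, c("gene", "test_group", "control_group", "log2fc")],
    modules = list(
      list(genes = c("Gpx1", "Gpx4", "Prdx1", "Sod2"),
           pool = c("1h ischemia+AAT", "5h ischemia+AAT"),
           loading = 1, signs = c(1, 1, 1, 1)),
      list(genes = c("Casp3", "Fadd", "Bcl2", "Cycs"),
           pool = c("1h ischemia", "5h ischemia"),
           loading = 1, signs = c(1, 1, -1, -1))),
    silent_genes = c("Il9", "Gpx5", "Gpx6"),
    baseline_overrides = c(Tlr4 = 28.5),
    master_seed = master_seed)
}

#' Write generator ground truth as JSON
#'
#' @param truth The `truth` element returned by [simulate_study()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  obj <- list(baseline = as.list(truth$baseline),
              de_table = truth$de_table,
              module_edges = truth$module_edges,
              master_seed = truth$master_seed)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows", pretty = TRUE), path)
  invisible(path)
}
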