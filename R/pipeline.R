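#' Assemble an end-to-end run configuration
#'
#' @param input Optional path to a Ct CSV (read with [read_ct_table()]);
#'   when `NULL` the `generator` is used instead.
#' @param generator A [generator_config()] (default [study_preset()]);
#'   ignored when `input` is given.
#' @param panel A [panel_spec()].
#' @param contrasts List of `c(test, control)` group pairs; default the
#'   four study contrasts.
#' @param pools Named list of group-label vectors, one network per pool;
#'   default the vehicle arm (1h + 5h ischemia) and the AAT arm.
#' @param boruta A [boruta_config()].
#' @param tree A [tree_config()].
#' @param filter A [filter_config()].
#' @param ml_scale Matrix the machine-learning stages (networks, tree) run
#'   on: `"ct"` (raw Ct, default), `"delta_ct"`, or `"linear"`.
#' @param out_dir Output directory.
#' @param master_seed Master seed for the generator, networks and layouts.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL,
                       generator = study_preset(),
                       panel = generator$panel %||% default_panel(),
                       contrasts = list(
                         c("5h ischemia", "1h ischemia"),
                         c("1h ischemia+AAT", "1h ischemia"),
                         c("5h ischemia+AAT", "5h ischemia"),
                         c("5h ischemia+AAT", "1h ischemia+AAT")),
                       pools = list(
                         "Ischemia" = c("1h ischemia", "5h ischemia"),
                         "AAT" = c("1h ischemia+AAT", "5h ischemia+AAT")),
                       boruta = boruta_config(),
                       tree = tree_config(),
                       filter = filter_config(),
                       ml_scale = c("ct", "delta_ct", "linear"),
                       out_dir = tempfile("crossboruta_run_"),
                       master_seed = 1L) {
  structure(
    list(input = input, generator = generator, panel = panel,
         contrasts = contrasts, pools = pools, boruta = boruta,
         tree = tree, filter = filter, ml_scale = match.arg(ml_scale),
         out_dir = out_dir, master_seed = as.integer(master_seed)),
    class = "run_config"
  )
}

subset_samples <- function(obj, keep) {
  obj$values <- obj$values[keep, , drop = FALSE]
  obj$group <- droplevels(obj$group[keep])
  obj$sample_ids <- obj$sample_ids[keep]
  if (!is.null(obj$substituted)) {
    obj$substituted <- obj$substituted[keep, , drop = FALSE]
  }
  obj
}

sanitize <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

#' Run the full pipeline
#'
#' Executes, in order: data acquisition (file or generator), delta-Ct
#' quantification, the configured group comparisons with significance
#' filtering, one CrossBoruta network per arm pool with SMACOF layouts and
#' a pairwise network contrast, and gain-ratio tree induction over all
#' samples. Every stage's artifacts are written under `cfg$out_dir` as
#' delimited text or JSON, plus a run log with seeds, package version and
#' stage timings. A stage failure aborts with the stage name after writing
#' a partial-results manifest.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory stage results (`ct`,
#'   `comparisons`, `filters`, `networks`, `summaries`, `layouts`,
#'   `contrast`, `tree`) and the artifact `manifest`.
#' @export
run_full <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  timings <- c()
  log_lines <- c("crossboruta run log",
                 paste("package version:",
                       as.character(utils::packageVersion("crossboruta"))),
                 paste("master seed:", cfg$master_seed),
                 paste("ml scale:", cfg$ml_scale),
                 paste("started:", format(Sys.time())))

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste("FAILED at stage:", name),
                   conditionMessage(e)),
                 file.path(cfg$out_dir, "run_log.txt"))
      writeLines(manifest, file.path(cfg$out_dir, "partial_manifest.txt"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  # -- data acquisition ------------------------------------------------
  sim <- NULL
  ct <- stage("acquire", {
    if (!is.null(cfg$input)) {
      read_ct_table(cfg$input, cfg$panel)
    } else {
      sim <- simulate_study(cfg$generator, master_seed = cfg$master_seed)
      p_ct <- file.path(cfg$out_dir, "simulated_ct.csv")
      write_ct_table(sim$ct, p_ct)
      p_truth <- file.path(cfg$out_dir, "simulated_truth.json")
      write_truth(sim$truth, p_truth)
      manifest <- c(manifest, p_ct, p_truth)
      sim$ct
    }
  })

  stage("validate", {
    declared <- levels(ct$group)
    for (ctr in cfg$contrasts) {
      bad <- setdiff(ctr, declared)
      if (length(bad)) {
        stop("contrast '", paste(ctr, collapse = " vs "),
             "' names undeclared group(s): ", paste(bad, collapse = ", "))
      }
    }
    for (nm in names(cfg$pools)) {
      bad <- setdiff(cfg$pools[[nm]], declared)
      if (length(bad)) {
        stop("pool '", nm, "' names undeclared group(s): ",
             paste(bad, collapse = ", "))
      }
    }
    invisible(NULL)
  })

  # -- quantification --------------------------------------------------
  lin <- stage("quantify", linearize(normalize_delta_ct(ct, cfg$panel)))

  # -- comparisons + filter --------------------------------------------
  comparisons <- stage("compare", {
    out <- list()
    for (ctr in cfg$contrasts) {
      res <- compare_groups(lin, ct, ctr[1], ctr[2])
      nm <- paste0(sanitize(ctr[1]), "_vs_", sanitize(ctr[2]))
      p <- file.path(cfg$out_dir, paste0("comparison_", nm, ".csv"))
      write_comparison(res, p)
      manifest <- c(manifest, p)
      out[[nm]] <- res
    }
    out
  })

  filters <- stage("filter", {
    fl <- lapply(comparisons, significance_filter, cfg = cfg$filter)
    p <- file.path(cfg$out_dir, "filter_summary.txt")
    lines <- unlist(lapply(names(fl), function(nm) {
      f <- fl[[nm]]
      c(paste0("[", nm, "]"),
        paste0("  altered: ", length(f$up) + length(f$down)),
        paste0("  up (", length(f$up), "): ",
               if (length(f$up)) paste(f$up, collapse = ", ") else "-"),
        paste0("  down (", length(f$down), "): ",
               if (length(f$down)) paste(f$down, collapse = ", ") else "-"))
    }))
    writeLines(lines, p)
    manifest <- c(manifest, p)
    fl
  })

  # -- machine-learning matrix -----------------------------------------
  ml <- switch(cfg$ml_scale,
               ct = {
                 m <- ct
                 m$values <- m$values[, cfg$panel$target_genes, drop = FALSE]
                 m$genes <- cfg$panel$target_genes
                 m
               },
               delta_ct = normalize_delta_ct(ct, cfg$panel),
               linear = lin)

  # -- networks --------------------------------------------------------
  networks <- stage("network", {
    out <- list()
    for (nm in names(cfg$pools)) {
      keep <- ct$group %in% cfg$pools[[nm]]
      sub <- subset_samples(ml, keep)
      bcfg <- cfg$boruta
      bcfg$rng_seed <- derive_seed(cfg$master_seed, "network", nm)
      net <- crossboruta(sub, bcfg, pool_label = nm)
      manifest <- c(manifest, write_network(net, cfg$out_dir, prefix = nm))
      out[[nm]] <- net
    }
    out
  })
  summaries <- lapply(networks, summarize_network)

  layouts <- stage("layout", {
    out <- list()
    for (nm in names(networks)) {
      lay <- layout_network(networks[[nm]],
                            rng_seed = derive_seed(cfg$master_seed,
                                                   "layout", nm))
      p <- file.path(cfg$out_dir, paste0(sanitize(nm), "_layout.csv"))
      write_layout(lay, p)
      manifest <- c(manifest, p)
      out[[nm]] <- lay
    }
    out
  })

  contrast <- stage("network_contrast", {
    if (length(networks) < 2) return(NULL)
    cmp <- compare_networks(networks[[1]], networks[[2]])
    p <- file.path(cfg$out_dir, "network_contrast.json")
    writeLines(jsonlite::toJSON(unclass(cmp), auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), p)
    manifest <- c(manifest, p)
    cmp
  })

  # -- decision tree ---------------------------------------------------
  tree <- stage("tree", {
    fit <- induce_tree(ml$values, as.character(ml$group), cfg$tree)
    p_json <- file.path(cfg$out_dir, "tree.json")
    tree_to_json(fit, p_json)
    p_txt <- file.path(cfg$out_dir, "tree.txt")
    writeLines(utils::capture.output(print(fit)), p_txt)
    manifest <- c(manifest, p_json, p_txt)
    fit
  })

  log_lines <- c(log_lines,
                 paste("finished:", format(Sys.time())),
                 "stage timings (s):",
                 paste0("  ", names(timings), ": ", unlist(timings)),
                 "artifacts:", paste0("  ", manifest))
  p_log <- file.path(cfg$out_dir, "run_log.txt")
  writeLines(log_lines, p_log)
  p_manifest <- file.path(cfg$out_dir, "manifest.txt")
  writeLines(manifest, p_manifest)

  invisible(list(ct = ct, truth = if (!is.null(sim)) sim$truth,
                 comparisons = comparisons, filters = filters,
                 networks = networks, summaries = summaries,
                 layouts = layouts, contrast = contrast, tree = tree,
                 manifest = c(manifest, p_log, p_manifest)))
}
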