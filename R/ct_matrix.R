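#' Construct a Ct matrix
#'
#' The universal raw input of the pipeline: one row per biological replicate,
#' one column per gene, threshold-cycle (Ct) values in PCR cycles, and a
#' group label per replicate.
#'
#' @param values Numeric matrix, samples x genes, with row names (sample ids)
#'   and column names (gene symbols). All non-missing values must be finite
#'   and positive.
#' @param group Character or factor vector of group labels, one per row.
#' @param groups Optional declared group set; defaults to the labels present.
#' @param substituted Optional logical matrix of the same shape marking wells
#'   whose undetermined Ct was replaced by the panel ceiling.
#' @return An object of class `ct_matrix` with elements `values`, `group`
#'   (factor over the declared group set), `genes`, `sample_ids`, and
#'   `substituted`.
#' @export
ct_matrix <- function(values, group, groups = NULL, substituted = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("ct_matrix values need gene column names")
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  }
  if (anyDuplicated(colnames(values))) {
    stop("gene symbols must be unique within the panel")
  }
  if (length(group) != nrow(values)) {
    stop("one group label per sample required: got ", length(group),
         " labels for ", nrow(values), " samples")
  }
  groups <- groups %||% unique(as.character(group))
  if (any(!as.character(group) %in% groups)) {
    bad <- setdiff(unique(as.character(group)), groups)
    stop("group labels outside the declared group set: ",
         paste(bad, collapse = ", "))
  }
  storage.mode(values) <- "double"
  ok <- is.na(values) | (is.finite(values) & values > 0)
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive or non-finite Ct at sample '%s', gene '%s'",
                 rownames(values)[idx[1]], colnames(values)[idx[2]]))
  }
  if (is.null(substituted)) {
    substituted <- matrix(FALSE, nrow(values), ncol(values),
                          dimnames = dimnames(values))
  }
  structure(
    list(values = values,
         group = factor(as.character(group), levels = groups),
         genes = colnames(values),
         sample_ids = rownames(values),
         substituted = substituted),
    class = "ct_matrix"
  )
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat("Ct matrix:", nrow(x$values), "samples x", ncol(x$values), "genes\n")
  print(table(group = x$group))
  nsub <- sum(x$substituted)
  if (nsub) cat(nsub, "undetermined wells substituted by the Ct ceiling\n")
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$values)

#' Read a wide-format Ct table
#'
#' Parses a delimited text file with columns `sample_id`, `group`, then one
#' column per panel gene. Undetermined wells (the `missing_mark` string, an
#' empty field, or `NA`) are replaced by the panel's Ct ceiling and counted
#' in the attached load report.
#'
#' @param path File path.
#' @param panel A [panel_spec()]; the file must contain every panel gene.
#' @param sep Field separator, default `","`.
#' @param missing_mark Sentinel string for undetermined wells, default
#'   `"Undetermined"`.
#' @return A [ct_matrix()] whose `load_report` attribute records the number
#'   and coordinates of substituted wells.
#' @export
read_ct_table <- function(path, panel, sep = ",", missing_mark = "Undetermined") {
  stopifnot(inherits(panel, "panel_spec"))
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("missing 'sample_id' column in ", path)
  if (!"group" %in% names(df)) stop("missing 'group' column in ", path)
  gene_cols <- setdiff(names(df), c("sample_id", "group"))
  absent <- setdiff(panel$all_genes, gene_cols)
  if (length(absent)) {
    stop("gene columns missing from ", path, ": ",
         paste(absent, collapse = ", "))
  }
  extra <- setdiff(gene_cols, panel$all_genes)
  if (length(extra)) {
    stop("gene columns not in panel: ", paste(extra, collapse = ", "))
  }
  raw <- as.matrix(df[, panel$all_genes, drop = FALSE])
  rownames(raw) <- df$sample_id
  missing <- raw == missing_mark | raw == "" | is.na(raw)
  vals <- suppressWarnings(
    matrix(as.numeric(raw), nrow(raw), ncol(raw), dimnames = dimnames(raw)))
  bad <- is.na(vals) & !missing
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric Ct '%s' at row %d (sample '%s'), column '%s'",
                 raw[idx[1], idx[2]], idx[1], rownames(raw)[idx[1]],
                 colnames(raw)[idx[2]]))
  }
  vals[missing] <- panel$ct_ceiling
  out <- ct_matrix(vals, df$group, substituted = missing)
  coords <- which(missing, arr.ind = TRUE)
  attr(out, "load_report") <- list(
    n_substituted = sum(missing),
    ct_ceiling = panel$ct_ceiling,
    substituted = data.frame(
      sample_id = rownames(raw)[coords[, 1]],
      gene = colnames(raw)[coords[, 2]],
      stringsAsFactors = FALSE))
  out
}

#' Write a Ct matrix to delimited text
#'
#' Inverse of [read_ct_table()]: emits `sample_id`, `group`, then one column
#' per gene.
#'
#' @param ct A `ct_matrix`.
#' @param path Output file path.
#' @param sep Field separator, default `","`.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path, sep = ",") {
  stopifnot(inherits(ct, "ct_matrix"))
  df <- data.frame(sample_id = ct$sample_ids,
                   group = as.character(ct$group),
                   ct$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}
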