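#' Declare a qPCR array panel
#'
#' A panel specification names the ordered gene columns of a Ct table, the
#' subset of stable reference (housekeeping) genes used for delta-Ct
#' normalization, and the Ct ceiling substituted for undetermined wells.
#'
#' @param all_genes Character vector of unique gene symbols, in array order.
#' @param reference_genes Non-empty subset of `all_genes` used for
#'   normalization. Defaults to the five stable genes of the rat
#'   inflammation/apoptosis/oxidative-stress array: Rplp1, ACTB, B2m,
#'   Hprt1, Ldha.
#' @param ct_ceiling Ct value (cycles) substituted for undetermined wells;
#'   default 35.
#' @return An object of class `panel_spec`.
#' @seealso [default_panel()]
#' @export
panel_spec <- function(all_genes,
                       reference_genes = c("Rplp1", "ACTB", "B2m", "Hprt1", "Ldha"),
                       ct_ceiling = 35) {
  all_genes <- as.character(all_genes)
  reference_genes <- as.character(reference_genes)
  if (anyDuplicated(all_genes)) {
    stop("panel gene symbols must be unique; duplicated: ",
         paste(unique(all_genes[duplicated(all_genes)]), collapse = ", "))
  }
  if (length(reference_genes) == 0L) stop("at least one reference gene is required")
  missing_ref <- setdiff(reference_genes, all_genes)
  if (length(missing_ref)) {
    stop("reference genes not in panel: ", paste(missing_ref, collapse = ", "))
  }
  stopifnot(is.numeric(ct_ceiling), length(ct_ceiling) == 1L, ct_ceiling > 0)
  structure(
    list(all_genes = all_genes,
         reference_genes = reference_genes,
         target_genes = setdiff(all_genes, reference_genes),
         ct_ceiling = as.numeric(ct_ceiling)),
    class = "panel_spec"
  )
}

#' @export
print.panel_spec <- function(x, ...) {
  cat("qPCR panel:", length(x$all_genes), "genes (",
      length(x$target_genes), "targets +", length(x$reference_genes),
      "reference )\n")
  cat("reference genes:", paste(x$reference_genes, collapse = ", "), "\n")
  cat("Ct ceiling for undetermined wells:", x$ct_ceiling, "\n")
  invisible(x)
}

#' Default 88-target rat inflammation/apoptosis/oxidative-stress panel
#'
#' The default panel mirrors a pathway-focused 88-gene rat array covering
#' apoptosis and cell death, oxidative stress and antioxidant defense, and
#' the inflammatory response, plus five stable reference genes. The symbols
#' that drive the packaged reference results (e.g. Ccl2, Icam1, Tlr4,
#' Hspa1a, Ccl11, Vcam1, Flt1, Cflar, Il9, Gpx5, Gpx6) are fixed; the
#' remaining entries are representative rat pathway genes completing the
#' 88-gene layout.
#'
#' @param ct_ceiling Passed through to [panel_spec()].
#' @return A `panel_spec` with 88 target genes and 5 reference genes.
#' @export
default_panel <- function(ct_ceiling = 35) {
  apoptosis <- c("Aifm1", "Bad", "Bax", "Bcl2", "Casp3", "Casp9", "Cflar",
                 "Cycs", "Fadd", "Fos")
  oxidative <- c("Ccs", "Cyba", "Gpx1", "Gpx3", "Gpx4", "Gpx5", "Gpx6",
                 "Gpx7", "Gstk1", "Hspa1a", "Ncf1", "Nox4", "Prdx1",
                 "Prdx2", "Prdx3", "Sod3", "Txnrd1", "Txnrd2")
  inflammatory <- c("Ccl2", "Ccl11", "Ccl20", "CxCr4", "Icam1", "Il9",
                    "Tlr4", "Tollip", "Vcam1", "Vegfc")
  growth <- "Flt1"
  complement <- c("Tnf", "Il1a", "Il1b", "Il6", "Il10", "Il18", "Nfkb1",
                  "Rela", "Tgfb1", "Ccl3", "Ccl4", "Ccl5", "Cxcl1",
                  "Cxcl2", "Cxcl10", "Cxcr2", "Sele", "Selp", "Mmp2",
                  "Mmp9", "Timp1", "Vegfa", "Kdr", "Nos2", "Nos3",
                  "Ptgs2", "Hmox1", "Nqo1", "Cat", "Sod1", "Sod2",
                  "Gpx2", "Gsr", "Gclc", "Gclm", "Txn1", "Prdx5",
                  "Prdx6", "Srxn1", "Casp1", "Casp7", "Casp8", "Bak1",
                  "Bid", "Bcl2l1", "Mcl1", "Apaf1", "Tp53", "Xiap")
  refs <- c("Rplp1", "ACTB", "B2m", "Hprt1", "Ldha")
  panel_spec(c(apoptosis, oxidative, inflammatory, growth, complement, refs),
             reference_genes = refs, ct_ceiling = ct_ceiling)
}
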