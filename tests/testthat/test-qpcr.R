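test_that("Ct tables round-trip through the reader with validation", {
  panel <- panel_spec(c("G1", "G2", "Ref1"), reference_genes = "Ref1",
                      ct_ceiling = 35)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,G1,G2,Ref1",
               "s1,ctrl,24.1,25.2,20.0",
               "s2,test,23.0,Undetermined,20.5"), f)
  ct <- read_ct_table(f, panel)
  expect_equal(dim(ct), c(2L, 3L))
  expect_equal(ct$values["s1", "G1"], 24.1)
  expect_equal(ct$values["s2", "G2"], 35)   # ceiling substitution
  rep <- attr(ct, "load_report")
  expect_equal(rep$n_substituted, 1L)
  expect_equal(rep$substituted$gene, "G2")

  # missing reference-gene column is named in the error
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,G1,G2", "s1,ctrl,24.1,25.2"), f2)
  expect_error(read_ct_table(f2, panel), "Ref1")

  # non-numeric Ct carries row/column coordinates
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,G1,G2,Ref1", "s1,ctrl,24.1,oops,20.0"), f3)
  expect_error(read_ct_table(f3, panel), "oops.*G2")

  # write -> read identity
  f4 <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(ct, f4)
  ct2 <- read_ct_table(f4, panel)
  expect_equal(ct2$values, ct$values)
  expect_equal(as.character(ct2$group), as.character(ct$group))
})

test_that("delta-Ct normalization subtracts the per-sample reference mean", {
  panel <- panel_spec(c("G1", "R1", "R2", "R3", "R4", "R5"),
                      reference_genes = paste0("R", 1:5))
  vals <- matrix(c(25, rep(20, 5)), nrow = 1,
                 dimnames = list("s1", panel$all_genes))
  expr <- normalize_delta_ct(ct_matrix(vals, "g"), panel)
  expect_equal(unname(expr$values[1, "G1"]), 5)       # 25 - mean(20...)
  expect_equal(expr$genes, "G1")                       # references dropped

  vals[1, "G1"] <- 20
  expr0 <- normalize_delta_ct(ct_matrix(vals, "g"), panel)
  expect_equal(unname(expr0$values[1, "G1"]), 0)

  # random matrix vs brute-force recomputation
  set.seed(11)
  p2 <- panel_spec(c(paste0("G", 1:4), "Ra", "Rb"),
                   reference_genes = c("Ra", "Rb"))
  m <- matrix(runif(18, 18, 30), 3, 6,
              dimnames = list(paste0("s", 1:3), p2$all_genes))
  expr2 <- normalize_delta_ct(ct_matrix(m, rep("g", 3)), p2)
  for (s in 1:3) {
    for (g in paste0("G", 1:4)) {
      expect_equal(expr2$values[s, g],
                   m[s, g] - mean(c(m[s, "Ra"], m[s, "Rb"])))
    }
  }

  # missing reference measurement names sample and gene
  m[2, "Rb"] <- NA
  expect_error(
    normalize_delta_ct(ct_matrix(m, rep("g", 3)), p2),
    "s2.*Rb")
})

test_that("linearize maps delta-Ct to strictly positive 2^(-dCt)", {
  panel <- tiny_panel(3)
  vals <- matrix(c(20, 23, 18, 20, 20),
                 nrow = 1, dimnames = list("s1", panel$all_genes))
  expr <- normalize_delta_ct(ct_matrix(vals, "g"), panel)
  lin <- linearize(expr)
  expect_equal(unname(lin$values[1, ]), c(1, 0.125, 4))  # dCt 0, 3, -2
  expect_equal(lin$scale, "linear")
  expect_true(all(lin$values > 0))
  expect_error(linearize(lin), "delta_ct")
})

test_that("compare_groups matches the closed-form pooled t-test and fold rules", {
  lin_vals <- rbind(2, 2, 2, 1, 1.0001, 0.9999)
  colnames(lin_vals) <- "G1"
  fx <- ct_from_linear(lin_vals, rep(c("test", "ctrl"), each = 3))
  expr <- linearize(normalize_delta_ct(fx$ct, fx$panel))
  res <- compare_groups(expr, fx$ct, "test", "ctrl")
  expect_equal(res$fold_change, 2, tolerance = 1e-4)
  expect_equal(res$fold_regulation, 2, tolerance = 1e-4)
  expect_lt(res$p_value, 0.05)
  # textbook pooled-variance t statistic
  xt <- c(2, 2, 2); xc <- c(1, 1.0001, 0.9999)
  sp <- sqrt(((3 - 1) * var(xt) + (3 - 1) * var(xc)) / (3 + 3 - 2))
  tstat <- (mean(xt) - mean(xc)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), df = 4), tolerance = 1e-12)

  # identical groups: no difference
  fx2 <- ct_from_linear(cbind(G1 = rep(1.5, 6)),
                        rep(c("test", "ctrl"), each = 3))
  expr2 <- linearize(normalize_delta_ct(fx2$ct, fx2$panel))
  res2 <- compare_groups(expr2, fx2$ct, "test", "ctrl")
  expect_equal(res2$fold_change, 1)
  expect_equal(res2$fold_regulation, 1)
  expect_equal(res2$p_value, 1)

  # quarter-expression: FR = -1/FC
  set.seed(4)
  lin3 <- cbind(G1 = c(0.5, 0.5, 0.5, 2, 2, 2) * exp(rnorm(6, 0, 0.01)))
  fx3 <- ct_from_linear(lin3, rep(c("test", "ctrl"), each = 3))
  expr3 <- linearize(normalize_delta_ct(fx3$ct, fx3$panel))
  res3 <- compare_groups(expr3, fx3$ct, "test", "ctrl")
  expect_equal(res3$fold_regulation, -4, tolerance = 0.05)

  # validation: absent and singleton groups
  expect_error(compare_groups(expr, fx$ct, "nope", "ctrl"), "absent")
  expect_error(compare_groups(expr, fx$ct, "test", "ctrl2"), "absent")
})

test_that("high-Ct QC categories follow the strict 30-cycle rule", {
  expect_equal(qc_flag(31.2, 24.0), "A")
  expect_equal(qc_flag(24.0, 31.2), "A")
  expect_equal(qc_flag(31.0, 32.5), "B")
  expect_equal(qc_flag(25.0, 26.0), "none")
  expect_equal(qc_flag(30.0, 30.0), "none")   # ties at 30 are 'low'
  expect_equal(qc_flag(30.0, 30.5), "A")
  expect_equal(qc_flag(c(31, 25), c(32, 26)), c("B", "none"))
})

test_that("significance filter reproduces the packaged reference outcomes", {
  f1 <- significance_filter(read_deg_table("5h_vs_1h"))
  expect_setequal(f1$up, c("Fos", "Hspa1a", "Txnrd1", "Ccl2", "Icam1"))
  expect_equal(f1$down, "Tlr4")
  expect_equal(length(f1$up) + length(f1$down), 6L)

  f2 <- significance_filter(read_deg_table("1hAAT_vs_1h"))
  expect_equal(length(f2$up), 0L)
  expect_equal(length(f2$down), 0L)

  f3 <- significance_filter(read_deg_table("5hAAT_vs_5h"))
  expect_equal(f3$up, "Ccl11")
  expect_equal(f3$down, "Vcam1")

  f4 <- significance_filter(read_deg_table("5hAAT_vs_1hAAT"))
  expect_equal(f4$up, character(0))
  expect_equal(f4$down, "Ccl20")

  # idempotence / brute-force row scan equivalence on every fixture
  for (ctr in c("5h_vs_1h", "1hAAT_vs_1h", "5hAAT_vs_5h", "5hAAT_vs_1hAAT")) {
    tab <- read_deg_table(ctr)
    f <- significance_filter(tab)
    up <- character(0); down <- character(0)
    for (i in seq_len(nrow(tab))) {
      if (tab$p_value[i] < 0.05 && tab$fold_regulation[i] > 2) {
        up <- c(up, tab$gene[i])
      }
      if (tab$p_value[i] < 0.05 && tab$fold_regulation[i] < -2) {
        down <- c(down, tab$gene[i])
      }
    }
    expect_identical(f$up, up)
    expect_identical(f$down, down)
    sub <- tab[tab$gene %in% c(f$up, f$down), ]
    if (nrow(sub) > 0) {
      f_again <- significance_filter(sub)
      expect_identical(f_again$up, f$up)   # idempotent on its own output
      expect_identical(f_again$down, f$down)
    }
  }
})

test_that("fold-regulation identities and group-swap symmetry hold", {
  fr <- function(fc) ifelse(fc >= 1, fc, -1 / fc)
  x <- c(1.001, 1.5, 2, 4, 10, 100)
  expect_equal(fr(1 / x), -fr(x))                 # odd on the log scale
  expect_true(all(diff(fr(sort(c(x, 1 / x)))) > 0))  # monotone in FC
  expect_true(all(abs(fr(c(x, 1 / x, 1))) >= 1))

  set.seed(21)
  panel <- tiny_panel(5)
  vals <- matrix(runif(10 * 7, 18, 30), 10, 7,
                 dimnames = list(paste0("s", 1:10), panel$all_genes))
  ct <- ct_matrix(vals, rep(c("a", "b"), each = 5))
  expr <- linearize(normalize_delta_ct(ct, panel))
  ab <- compare_groups(expr, ct, "a", "b")
  ba <- compare_groups(expr, ct, "b", "a")
  expect_equal(ab$fold_change, 1 / ba$fold_change, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  nontrivial <- abs(ab$fold_change - 1) > 1e-9
  expect_equal(ab$fold_regulation[nontrivial],
               -ba$fold_regulation[nontrivial], tolerance = 1e-9)

  # FC equals 2^(-ddCt) from group-mean delta-Ct within 1e-9
  dct <- normalize_delta_ct(ct, panel)
  for (g in panel$target_genes) {
    ddct <- mean(dct$values[ct$group == "a", g]) -
      mean(dct$values[ct$group == "b", g])
    expect_equal(ab$fold_change[ab$gene == g], 2^(-ddct),
                 tolerance = 1e-9)
  }
})

test_that("genes undetermined in most of a group are excluded with a warning", {
  panel <- tiny_panel(2)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,G1,G2,Ref1,Ref2",
               "s1,a,24,Undetermined,20,20",
               "s2,a,24,Undetermined,20,20",
               "s3,a,24,25,20,20",
               "s4,b,24,25,20,20",
               "s5,b,24,25,20,20",
               "s6,b,24,25,20,20"), f)
  ct <- read_ct_table(f, panel)
  expr <- linearize(normalize_delta_ct(ct, panel))
  expect_warning(res <- compare_groups(expr, ct, "a", "b"), "G2")
  expect_false("G2" %in% res$gene)
  expect_true("G1" %in% res$gene)
})
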