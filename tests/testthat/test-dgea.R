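make_ct <- function(ct_vals, group, panel) {
  ct_matrix(ct_vals, group, panel = panel)
}

test_that("housekeeping normalization implements 2^-dCt with the mean housekeeping Ct", {
  panel <- tiny_panel()
  # sample 1: hk mean 20; IL23A at hk mean -> 1.0, BCL6 one cycle above -> 0.5
  ct_vals <- rbind(
    R_01 = c(IL23A = 20, BCL6 = 21, CXCL2 = 18, ACTB = 19, GAPDH = 21),
    R_02 = c(24, 25, 22, 23, 25),
    NR_01 = c(25, 24, 23, 22, 24),
    NR_02 = c(26, 25, 24, 23, 25)
  )
  colnames(ct_vals) <- c("IL23A", "BCL6", "CXCL2", "ACTB", "GAPDH")
  ct <- make_ct(ct_vals, c("responder", "responder",
                           "non-responder", "non-responder"), panel)
  norm <- normalize_delta_ct(ct, panel)
  expect_equal(norm$values["R_01", "IL23A"], 1.0)
  expect_equal(norm$values["R_01", "BCL6"], 0.5)
  expect_equal(norm$values["R_01", "CXCL2"], 4.0)  # two cycles below hk mean

  # an undetermined housekeeping well is fatal and names the culprit
  ct$undetermined["R_02", "ACTB"] <- TRUE
  expect_error(normalize_delta_ct(ct, panel), "R_02.*ACTB")
})

test_that("fold regulation is the signed reciprocal display transform", {
  expect_equal(fold_regulation(1), 1)
  expect_equal(fold_regulation(0.5), -2)
  expect_equal(fold_regulation(1 / 24.3), -24.3)
  expect_equal(fold_regulation(c(4, 0.25)), c(4, -4))
  expect_error(fold_regulation(0), "positive")
  expect_error(fold_regulation(-1), "positive")
  # antisymmetry under FC -> 1/FC across a grid
  x <- c(1 + 1e-9, 1.5, 2, 3.7, 10, 24.3, 100)
  expect_equal(fold_regulation(1 / x), -fold_regulation(x), tolerance = 1e-12)
})

test_that("per-gene pooled t-test matches the classical two-sample test", {
  # frozen oracle: t.test(var.equal=TRUE) on the worked example
  a <- c(2.0, 2.1, 1.9)
  b <- c(1.0, 1.1, 0.9)
  oracle_p <- stats::t.test(a, b, var.equal = TRUE)$p.value
  vals <- cbind(g1 = c(b, a), g2 = c(1, 2, 3, 1, 2, 3))
  rownames(vals) <- paste0("S", 1:6)
  norm <- make_norm(vals, rep(c("responder", "non-responder"), each = 3))
  tab_vals <- uskit:::group_t_tests(vals, norm$group)
  expect_equal(tab_vals$p_value[["g1"]], oracle_p, tolerance = 1e-12)
  expect_equal(oracle_p, 2.552167e-4, tolerance = 1e-6)
  # identical groups -> p = 1
  expect_equal(tab_vals$p_value[["g2"]], 1)

  # vectorized path agrees with t.test across random genes, both variants
  set.seed(1)
  m <- matrix(stats::rlnorm(12 * 20), 12, 20,
              dimnames = list(paste0("S", 1:12), paste0("g", 1:20)))
  grp <- rep(c("responder", "non-responder"), each = 6)
  for (ve in c(TRUE, FALSE)) {
    got <- uskit:::group_t_tests(m, stats::setNames(grp, rownames(m)),
                                 var_equal = ve)$p_value
    want <- apply(m, 2, function(x)
      stats::t.test(x[grp == "non-responder"], x[grp == "responder"],
                    var.equal = ve)$p.value)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("degenerate zero-variance genes are handled with the documented conventions", {
  vals <- cbind(flat_eq = rep(2, 6), flat_ne = rep(c(1, 2), each = 3))
  rownames(vals) <- paste0("S", 1:6)
  grp <- stats::setNames(rep(c("responder", "non-responder"), each = 3),
                         rownames(vals))
  expect_warning(res <- uskit:::group_t_tests(vals, grp), "zero pooled variance")
  expect_equal(res$p_value[["flat_eq"]], 1)
  expect_gt(res$p_value[["flat_ne"]], 0)
  expect_lt(res$p_value[["flat_ne"]], 1e-300)
})

test_that("dgea flags follow the nominal p and fold-regulation thresholds", {
  panel <- default_panel()
  spec <- study_cohort_spec(panel, noise_sd = 0, modules = FALSE)
  tab <- suppressWarnings(dgea(generate_cohort(spec, 3), panel))
  # TNFSF14 planted at +1.38: below the +/-2 cutoff
  expect_false(tab$dysregulated[tab$gene == "TNFSF14"])
  expect_identical(sum(tab$dysregulated), 29L)
  expect_true(all(tab$fold_change > 0))
  expect_true(all(abs(tab$fold_regulation) >= 1))
  expect_identical(tab$significant, tab$p_value < 0.05)
})

test_that("dgea is invariant to gene column order", {
  panel <- default_panel()
  ct <- generate_cohort(study_cohort_spec(panel), seed = 8)
  perm <- ct
  cols <- sample(colnames(ct$ct))
  perm$ct <- perm$ct[, cols]
  perm$undetermined <- perm$undetermined[, cols]
  t1 <- dgea(ct, panel)
  t2 <- dgea(perm, panel)
  expect_identical(t1$gene, t2$gene)  # stable panel order regardless of input
  expect_equal(t1$fold_regulation, t2$fold_regulation, tolerance = 1e-12)
})

test_that("candidate selection unions the fold filter with forced inclusions", {
  panel <- default_panel()
  spec <- study_cohort_spec(panel, noise_sd = 0, modules = FALSE)
  tab <- suppressWarnings(dgea(generate_cohort(spec, 3), panel))
  cand <- select_candidates(tab, force_include = "TNFSF14")
  expect_length(cand, 30L)
  expect_true("TNFSF14" %in% cand)
  # stable panel order
  expect_identical(cand, tab$gene[tab$gene %in% cand])
  # forced gene must exist
  expect_error(select_candidates(tab, force_include = "NOPE"), "NOPE")
  # nothing passes and nothing forced -> empty
  null_spec <- cohort_spec(panel, 5, 5, noise_sd = 0.01)
  null_tab <- dgea(generate_cohort(null_spec, 1), panel)
  expect_length(select_candidates(null_tab), 0L)
})

test_that("estimated fold regulations track planted effects at study scale", {
  # 200 seeded cohorts at n=22/14, sd=0.5: median |relative error| of the
  # estimated vs planted fold-regulation magnitude stays under 15% for the
  # 29 genes beyond the fold cutoff
  panel <- default_panel()
  spec <- study_cohort_spec(panel, modules = FALSE)
  planted <- spec$fold_regulation
  eff <- names(planted)[abs(planted) >= 2]
  rel_err <- matrix(NA_real_, 200, length(eff), dimnames = list(NULL, eff))
  for (s in 1:200) {
    tab <- dgea(generate_cohort(spec, seed = 5000 + s), panel)
    fr <- stats::setNames(tab$fold_regulation, tab$gene)[eff]
    rel_err[s, ] <- abs(abs(fr) - abs(planted[eff])) / abs(planted[eff])
  }
  expect_lt(stats::median(rel_err), 0.15)
})
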