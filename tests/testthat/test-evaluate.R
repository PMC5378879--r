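test_that("evaluating the planted module on its own cohort is strongly prognostic", {
  cfg <- sim_config(n_genes = 40, n_cohorts = 1, n_samples = 300,
                    beta_effect = 1, rng_seed = 7)
  panel <- generate_panel(cfg)
  rec <- evaluate_signature(gene_signature(panel$planted), panel$cohorts[[1]])
  expect_gt(rec$c_index, 0.7)
  expect_gt(rec$neg_log10_logrank_p, 2)
  expect_gte(rec$n_sig_genes, 4)
  expect_true(rec$converged)
})

test_that("missing signature genes are dropped; an all-missing signature errors", {
  co <- make_cohort(n = 30, genes = c("A", "B", "C"), seed = 3)
  expect_warning(rec <- evaluate_signature(c("A", "B", "ZZ"), co),
                 "absent from")
  expect_equal(rec$n_genes_used, 2)
  expect_error(evaluate_signature(c("Q", "Z"), co), "no signature genes")
})

test_that("a constant gene yields an NA record rather than an error", {
  co <- make_cohort(n = 20, genes = c("FLAT", "B"),
                    expr = rbind(rep(1, 20), rnorm(20)), seed = 10)
  rec <- evaluate_signature("FLAT", co)
  expect_true(is.na(rec$c_index))
  expect_true(is.na(rec$logrank_p))
  expect_false(rec$converged)
})

test_that("evaluation is invariant to sample order", {
  cfg <- sim_config(n_genes = 20, n_cohorts = 1, n_samples = 80, rng_seed = 12)
  panel <- generate_panel(cfg)
  co <- panel$cohorts[[1]]
  set.seed(1)
  perm <- sample(ncol(co$expr))
  co2 <- expression_cohort(co$cohort_id, co$expr[, perm],
                           co$time[perm], co$event[perm])
  r1 <- evaluate_signature(panel$planted, co)
  r2 <- evaluate_signature(panel$planted, co2)
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("the random-signature null is reproducible and bounded", {
  cfg <- sim_config(n_genes = 30, n_cohorts = 1, n_samples = 60,
                    beta_effect = 0, rng_seed = 44)
  panel <- generate_panel(cfg)
  co <- panel$cohorts[[1]]
  n1 <- random_null(co, k = 4, n_models = 30, rng_seed = 5)
  n2 <- random_null(co, k = 4, n_models = 30, rng_seed = 5)
  expect_identical(n1$c_values, n2$c_values)
  expect_true(all(n1$c_values >= 0 & n1$c_values <= 1, na.rm = TRUE))
  n3 <- random_null(co, k = 4, n_models = 30, rng_seed = 6)
  expect_false(identical(n1$c_values, n3$c_values))
  expect_error(random_null(co, k = 31, n_models = 5, rng_seed = 1),
               "exceeds")
})

test_that("k equal to the gene universe gives a zero-variance null", {
  cfg <- sim_config(n_genes = 12, n_cohorts = 1, n_samples = 50, rng_seed = 3)
  panel <- generate_panel(cfg)
  co <- panel$cohorts[[1]]
  nd <- random_null(co, k = nrow(co$expr), n_models = 5, rng_seed = 2)
  expect_equal(length(unique(nd$c_values)), 1)
})

test_that("empirical p-values use the add-one rule and stay in (0, 1]", {
  null <- structure(list(k = 5L, cohort_id = "X", c_values = (1:99) / 100,
                         n_models = 99L, rng_seed = 1L),
                    class = "null_distribution")
  expect_equal(empirical_pvalue(1.0, null)$p_value, 1 / 100)
  expect_equal(empirical_pvalue(0.0, null)$p_value, 1.0)
  mid <- empirical_pvalue(0.5, null)$p_value
  expect_gt(mid, 0.45); expect_lt(mid, 0.55)
  expect_true(empirical_pvalue(1.0, null)$significant)
  expect_false(empirical_pvalue(0.5, null)$significant)
})

test_that("cross-panel reports lay out C-indexes with averages", {
  cfg <- sim_config(n_genes = 20, n_cohorts = 2, n_samples = 60, rng_seed = 18)
  panel <- generate_panel(cfg)
  sig <- gene_signature(panel$planted)
  grid <- cross_panel_report(list(planted = sig), panel$cohorts)
  expect_equal(grid$signature, c("planted", "Average"))
  single <- suppressWarnings(evaluate_signature(sig, panel$cohorts[[1]]))
  expect_equal(grid$SIM1[1], single$c_index)
  expect_equal(grid$average[1], mean(c(grid$SIM1[1], grid$SIM2[1])))

  # identical cohorts give identical columns
  twin <- panel$cohorts[[1]]
  twin$cohort_id <- "TWIN"
  g2 <- cross_panel_report(list(planted = sig),
                           list(panel$cohorts[[1]], twin))
  expect_equal(g2$SIM1, g2$TWIN)
})

test_that("per-tissue averaging weights tissues, not cohorts", {
  sig <- gene_signature("A")
  co <- function(id, shift) {
    set.seed(1)
    expr <- matrix(rnorm(40), nrow = 1, dimnames = list("A", sprintf("s%02d", 1:40)))
    time <- rexp(40, exp(shift * expr[1, ]))
    expression_cohort(id, expr, time, rep(1L, 40))
  }
  cohorts <- list(co("C1", 2), co("C2", 2), co("C3", 2))
  grid <- cross_panel_report(list(s = sig), cohorts,
                             tissue = c(C1 = "t1", C2 = "t1", C3 = "t2"))
  plain <- cross_panel_report(list(s = sig), cohorts)
  manual <- mean(c(mean(c(plain$C1[1], plain$C2[1])), plain$C3[1]))
  expect_equal(grid$average[1], manual)
})

test_that("evaluation reports mirror the per-cohort summary columns", {
  cfg <- sim_config(n_genes = 20, n_cohorts = 2, n_samples = 60, rng_seed = 23)
  panel <- generate_panel(cfg)
  p <- withr::local_tempfile(fileext = ".tsv")
  rep <- evaluation_report(gene_signature(panel$planted), panel$cohorts, p)
  expect_equal(nrow(rep), 2)
  expect_named(rep, c("cohort_id", "n_genes_used", "c_index",
                      "neg_log10_logrank_p", "neg_log10_cox_p",
                      "n_sig_genes", "n_de_genes"))
  back <- read.delim(p)
  expect_equal(back$c_index, rep$c_index, tolerance = 1e-12)
})
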