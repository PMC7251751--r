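make_toy_snuc <- function(counts, n_donors = 2) {
  n <- ncol(counts)
  meta <- data.frame(cell_id = colnames(counts),
                     donor = rep_len(paste0("d", seq_len(n_donors)), n),
                     diagnosis = rep_len(c("ASD", "control"), n),
                     cluster = 1L)
  snuc_dataset(counts, meta)
}

test_that("normalize_counts: hand arithmetic, zeros, scale invariance", {
  cts <- matrix(c(1, 1, 2), 3, 1, dimnames = list(paste0("g", 1:3), "c1"))
  cts <- cbind(cts, c2 = c(0, 4, 0))
  d <- make_toy_snuc(cts)
  nm <- normalize_counts(d, scale_factor = 4)
  expect_equal(as.numeric(nm$values[, "c1"]), log2(c(2, 2, 3)))
  expect_equal(as.numeric(nm$values["g1", "c2"]), 0)  # zero stays exactly 0
  # doubling every count of a cell leaves its values unchanged
  d2 <- make_toy_snuc(cbind(cts[, 1, drop = FALSE] * 2, cts[, 2, drop = FALSE]))
  nm2 <- normalize_counts(d2, scale_factor = 4)
  expect_equal(as.numeric(nm2$values[, 1]), as.numeric(nm$values[, "c1"]))
})

test_that("zero-total cells are dropped with a warning; bad counts rejected", {
  cts <- matrix(c(1, 2, 0, 0), 2, 2,
                dimnames = list(c("g1", "g2"), c("c1", "c2")))
  d <- make_toy_snuc(cts)
  expect_warning(nm <- normalize_counts(d), "zero total")
  expect_equal(ncol(nm$values), 1)
  bad <- matrix(c(1.5, 1), 1, 2, dimnames = list("g", c("c1", "c2")))
  expect_error(make_toy_snuc(bad), "non-negative integers")
  expect_error(make_toy_snuc(matrix(-1, 1, 1, dimnames = list("g", "c"))),
               "non-negative integers")
})

test_that("fit_hurdle degenerate inputs are flagged, not dropped silently", {
  meta <- data.frame(donor = rep(paste0("d", 1:4), each = 10),
                     diagnosis = rep(c("ASD", "control"), each = 20))
  # all-zero gene -> no fittable component
  f0 <- fit_hurdle(rep(0, 40), meta, hurdle_spec(covariates = character()))
  expect_equal(f0$fit_status, "failed")
  expect_equal(lrt_diagnosis(f0)$df, 0)
  # all detected -> discrete part dropped, df = 1
  set.seed(1)
  f1 <- fit_hurdle(rnorm(40, 3), meta, hurdle_spec(covariates = character()))
  expect_null(f1$discrete)
  expect_equal(f1$df, 1L)
  expect_equal(lrt_diagnosis(f1)$df, 1)
  # single donor per group -> failed with reason
  meta1 <- data.frame(donor = rep(c("d1", "d2"), each = 20),
                      diagnosis = rep(c("ASD", "control"), each = 20))
  f2 <- fit_hurdle(rnorm(40, 2), meta1, hurdle_spec())
  expect_equal(f2$fit_status, "failed")
  expect_match(attr(f2, "reason"), "donors")
})

test_that("exchangeability: identical groups give ~zero diagnosis effects", {
  set.seed(42)
  half <- ifelse(rbinom(100, 1, 0.6) == 1, rnorm(100, 2), 0)
  y <- c(half, half)   # control group is a literal copy of the ASD group
  meta <- data.frame(donor = rep(paste0("d", 1:4), each = 50),
                     diagnosis = rep(c("ASD", "control"), each = 100))
  fit <- fit_hurdle(y, meta, hurdle_spec(covariates = character()))
  expect_lt(abs(fit$discrete$coef_diag), 0.05)
  expect_lt(abs(fit$continuous$coef_diag), 0.05)
  expect_lt(abs(fold_change(fit)$log2_fc), 0.05)
})

test_that("lrt_diagnosis and fold_change on hand-built fits", {
  fit <- structure(list(
    discrete = list(status = "mixed", logLik_full = -10, logLik_reduced = -10,
                    intercept = qlogis(0.4), coef_diag = 0),
    continuous = list(status = "mixed", logLik_full = -5, logLik_reduced = -5,
                      intercept = 2, coef_diag = 0),
    fit_status = "mixed", df = 2L, n_cells = 100, n_pos = 40,
    detect_rate = 0.4), class = "hurdle_fit")
  lrt <- lrt_diagnosis(fit)
  expect_equal(lrt$lrt_stat, 0)
  expect_equal(lrt$p_value, 1)
  fc <- fold_change(fit)
  expect_equal(fc$log2_fc, 0)
  expect_equal(fc$pct_change, 0)
})

test_that("call_de: BH within cluster and the conjunction gate", {
  res <- data.frame(gene = paste0("g", 1:4), cluster = 1,
                    p_value = c(0.01, 0.02, 0.03, 0.04),
                    pct_change = c(0.5, 0.5, 0.05, 0.5),
                    pct_change_simplified = c(0.5, 0.05, 0.5, 0.5),
                    fit_status = "mixed")
  out <- call_de(res, fdr_cut = 0.05, fc_cut = 0.10)
  expect_equal(out$fdr, rep(0.04, 4))   # hand-applied BH
  # gene 2 fails the simplified gate, gene 3 the full-model gate
  expect_equal(out$is_de, c(TRUE, FALSE, FALSE, TRUE))
  # all p = 1 -> no events
  res$p_value <- 1
  expect_false(any(call_de(res)$is_de))
  # 1.05-fold change fails the 10% gate regardless of p
  res2 <- data.frame(gene = "g", cluster = 1, p_value = 1e-10,
                     pct_change = 0.05, pct_change_simplified = 0.05,
                     fit_status = "mixed")
  expect_false(call_de(res2)$is_de)
})

test_that("BH via call_de equals the sort/cummin oracle on random vectors", {
  set.seed(7)
  for (i in 1:10) {
    p <- runif(sample(5:40, 1))^sample(1:3, 1)
    res <- data.frame(gene = seq_along(p), cluster = 1, p_value = p,
                      pct_change = 1, pct_change_simplified = 1,
                      fit_status = "mixed")
    expect_equal(call_de(res)$fdr, bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("label permutation negates log2_fc and preserves the p-value", {
  cfg <- sim_config(seed = 44, n_genes = 3, n_clusters = 1,
                    n_cells_per_donor = 150,
                    planted_de = data.frame(gene = "G000001", cluster = NA,
                                            log2_effect = 1, logit_effect = 0.5))
  sim <- gen_snuc_dataset(cfg)
  meta <- sim$cell_meta
  meta_sw <- meta
  meta_sw$diagnosis <- ifelse(meta$diagnosis == "ASD", "control", "ASD")
  sp <- hurdle_spec(covariates = character())
  for (g in c("G000001", "G000002")) {
    y <- as.numeric(sim$values[g, ])
    f1 <- fit_hurdle(y, meta, sp)
    f2 <- fit_hurdle(y, meta_sw, sp)
    expect_equal(fold_change(f1)$log2_fc, -fold_change(f2)$log2_fc,
                 tolerance = 1e-3)
    expect_equal(lrt_diagnosis(f1)$p_value, lrt_diagnosis(f2)$p_value,
                 tolerance = 1e-3)
  }
})

test_that("donor random intercept rejects less than the fixed fallback", {
  # null data with real donor effects: the mixed model is what keeps the
  # type-I error (approximately) controlled; the fixed-effects path treats
  # nuclei as independent and over-rejects grossly.
  n_genes <- 40
  cfg <- sim_config(seed = 45, n_genes = n_genes, n_clusters = 1,
                    n_cells_per_donor = 300)
  sim <- gen_snuc_dataset(cfg)
  p_mixed <- p_fixed <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    y <- as.numeric(sim$values[g, ])
    p_mixed[g] <- lrt_diagnosis(fit_hurdle(y, sim$cell_meta,
                                           hurdle_spec(covariates = character())))$p_value
    p_fixed[g] <- lrt_diagnosis(fit_hurdle(y, sim$cell_meta,
                                           hurdle_spec(covariates = character(),
                                                       random = NULL)))$p_value
  }
  rej_mixed <- mean(p_mixed < 0.05, na.rm = TRUE)
  rej_fixed <- mean(p_fixed < 0.05, na.rm = TRUE)
  expect_gt(rej_fixed, rej_mixed)
  expect_gt(rej_fixed, 0.2)   # gross over-rejection without the random term
})

test_that("find_markers recovers separation and planted markers", {
  cfg <- sim_config(seed = 46, n_genes = 15, n_clusters = 3,
                    n_cells_per_donor = 60,
                    planted_markers = data.frame(gene = gene_namespace(2),
                                                 cluster = 1:2,
                                                 log2_effect = 2,
                                                 logit_effect = 2))
  sim <- gen_snuc_dataset(cfg, counts = TRUE)
  mk <- suppressWarnings(find_markers(sim$dataset))
  for (i in 1:2) {
    hit <- mk[mk$gene == gene_namespace(2)[i] & mk$cluster == i, ]
    expect_true(hit$is_marker)
    top <- mk[mk$cluster == i & mk$is_marker, ]
    expect_equal(top$gene[which.max(top$log2_enrichment)],
                 gene_namespace(2)[i])
  }
  # a gene uniform across clusters is not an enriched marker anywhere
  uniform <- mk[mk$gene == "G000010", ]
  expect_false(any(uniform$is_marker))
})

test_that("celltype_overlap: trivial cases and enumeration toy", {
  de <- data.frame(gene = c("X", "Y"), cluster = 1, is_de = c(TRUE, TRUE))
  ov <- celltype_overlap(de, list(gene_set(c("Y", "Z"), "s1")), universe = 4)
  expect_equal(ov$overlap, 1)
  expect_equal(ov$genes, "Y")
  # enumeration over all 2-subsets of a 4-gene universe: P(X >= 1) = 5/6
  expect_equal(ov$p_value, enum_overlap_p(4, 2, 2, 1), tolerance = 1e-10)
  de_none <- data.frame(gene = "X", cluster = 1, is_de = FALSE)
  ov0 <- celltype_overlap(de_none, list(gene_set("X", "s")), universe = 10)
  expect_equal(ov0$overlap, 0)
  expect_equal(ov0$p_value, 1)
})

test_that("de_event_counts: events >= genes, equality iff single-cluster", {
  de <- data.frame(gene = c("A", "A", "B"), cluster = c(1, 2, 1),
                   is_de = c(TRUE, TRUE, TRUE))
  ec <- de_event_counts(de)
  expect_equal(ec$events, 3)
  expect_equal(ec$genes, 2)
  de$is_de <- c(TRUE, FALSE, TRUE)
  ec2 <- de_event_counts(de)
  expect_equal(ec2$events, ec2$genes)
})
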