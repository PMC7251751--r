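test_that("average_hemispheres: mean of pairs, pass-through singletons", {
  m <- toy_dev_expression()
  avg <- average_hemispheres(m)
  expect_equal(ncol(avg$values), 2)     # 2 donors, 1 region, 1 period
  expect_equal(unname(avg$values["G1", ]), c(5, 7.2))   # (4+6)/2, (7.2+7.2)/2
  expect_equal(unname(avg$values["G3", ]), c(1, 1))
  # singleton passes through unchanged
  single <- dev_expression(matrix(7.2, 1, 1, dimnames = list("g", "s1")),
                           data.frame(sample_id = "s1", region = "AMY",
                                      period = 2L, hemisphere = "L",
                                      donor = "d1"))
  expect_equal(unname(average_hemispheres(single)$values[1, 1]), 7.2)
  # idempotent
  expect_equal(unname(average_hemispheres(avg)$values), unname(avg$values))
})

test_that("average_hemispheres rejects >2 entries per key", {
  vals <- matrix(1:3, 1, dimnames = list("g", paste0("s", 1:3)))
  meta <- data.frame(sample_id = paste0("s", 1:3), region = "AMY",
                     period = 2L, hemisphere = c("L", "R", "L"), donor = "d1")
  expect_error(average_hemispheres(dev_expression(vals, meta)),
               ">2 hemisphere")
})

test_that("summarize_by_period takes medians with midpoint convention", {
  vals <- matrix(c(5, 7, 9, 5, 7, 99), 2, 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), paste0("s", 1:3)))
  meta <- data.frame(sample_id = paste0("s", 1:3), region = "AMY",
                     period = c(4L, 4L, 4L), hemisphere = NA,
                     donor = paste0("d", 1:3))
  m <- dev_expression(vals, meta)
  prof <- summarize_by_period(m, "AMY")
  expect_equal(unname(prof["G1", "4"]), 7)
  # even count -> midpoint
  meta2 <- meta[1:2, ]
  m2 <- dev_expression(vals[, 1:2], meta2)
  expect_equal(unname(summarize_by_period(m2, "AMY")["G1", "4"]), 6)
  # order invariance
  perm <- c(3, 1, 2)
  m3 <- dev_expression(vals[, perm], meta[perm, ])
  expect_equal(summarize_by_period(m3, "AMY"), prof)
  expect_error(summarize_by_period(m, "CBC"), "absent")
})

test_that("filter_expressed applies a strict threshold within the window", {
  prof <- matrix(5.9, 2, 7, dimnames = list(c("g1", "g2"), as.character(2:8)))
  prof["g2", "3"] <- 6.1
  class(prof) <- c("period_profile", "matrix", "array")
  crit <- human_filter_criteria()
  expect_setequal(filter_expressed(prof, crit)$symbols, "G2")
  # boundary: exactly 6.0 fails (strict >)
  prof["g1", "5"] <- 6.0
  expect_setequal(filter_expressed(prof, crit)$symbols, "G2")
  expect_error(filter_expressed(prof, human_filter_criteria(period_lo = 9,
                                                            period_hi = 12)),
               "window")
})

test_that("threshold/window monotonicity and any_sample superset", {
  cfg <- sim_config(seed = 5, n_genes = 60, periods = 1:10,
                    n_samples_per_period = 4)
  pass <- gene_namespace(60)[1:35]
  m <- gen_dev_expression(cfg, pass)
  base <- filter_expressed(m, human_filter_criteria())
  higher <- filter_expressed(m, human_filter_criteria(threshold = 6.8))
  expect_true(all(higher$symbols %in% base$symbols))
  narrow <- filter_expressed(m, human_filter_criteria(period_lo = 3,
                                                      period_hi = 6))
  expect_true(all(narrow$symbols %in% base$symbols))
  wide <- filter_expressed(m, human_filter_criteria(period_lo = 1,
                                                    period_hi = 10))
  expect_true(all(base$symbols %in% wide$symbols))
  any_s <- filter_expressed(m, human_filter_criteria(mode = "any_sample"))
  expect_true(all(base$symbols %in% any_s$symbols))
})

test_that("filter_human separates pass/fail/no_data and reports pct", {
  cfg <- sim_config(seed = 6, n_genes = 10, periods = 2:8,
                    n_samples_per_period = 3)
  pass <- gene_namespace(10)[1:7]
  m <- gen_dev_expression(cfg, pass)
  query <- gene_set(c(gene_namespace(10), "ABSENT1", "ABSENT2"))
  res <- filter_human(m, query)
  expect_setequal(res$pass$symbols, pass)
  expect_length(res$fail$symbols, 3)
  expect_setequal(res$no_data$symbols, c("ABSENT1", "ABSENT2"))
  expect_equal(res$pct_pass, 70.0)
  # partition property
  expect_setequal(c(res$pass$symbols, res$fail$symbols, res$no_data$symbols),
                  query$symbols)
})

test_that("variance_summary: sample variance, background, and errors", {
  m <- toy_dev_expression()
  v <- variance_summary(m, per_gene = TRUE)
  expect_equal(unname(v["G2"]), var(c(5, 5, 7, 7)))
  expect_equal(unname(v["G3"]), var(c(0, 2, 0, 2)))
  # constant gene -> variance 0
  vals <- matrix(3, 1, 4, dimnames = list("c1", paste0("s", 1:4)))
  mc <- dev_expression(vals, m$sample_meta)
  expect_equal(unname(variance_summary(mc, per_gene = TRUE)), 0)
  # {0, 2} -> sample variance 2 (n-1 denominator)
  v2 <- matrix(c(0, 2), 1, 2, dimnames = list("g", c("s1", "s2")))
  m2 <- dev_expression(v2, m$sample_meta[1:2, ])
  expect_equal(unname(variance_summary(m2)), 2)
  # 3-gene toy equals hand-computed mean of per-gene variances
  expect_equal(variance_summary(m),
               mean(c(var(c(4, 6, 7.2, 7.2)), var(c(5, 5, 7, 7)),
                      var(c(0, 2, 0, 2)))))
  expect_warning(variance_summary(m, gene_set(c("G1", "NOPE"))), "skipped")
  expect_error(suppressWarnings(variance_summary(m, gene_set("NOPE"))),
               "empty effective subset")
})

test_that("dev expression TSV round trip", {
  m <- toy_dev_expression()
  e <- tempfile(fileext = ".tsv"); s <- tempfile(fileext = ".tsv")
  write_dev_expression(m, e, s)
  m2 <- read_dev_expression(e, s)
  expect_equal(m2$values, m$values)
  expect_equal(m2$sample_meta$donor, m$sample_meta$donor)
})
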