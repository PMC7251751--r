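test_that("sim_config validates fields", {
  expect_error(sim_config(dropout_base = 1.5), "probability")
  expect_error(sim_config(n_genes = 0), "integer")
  expect_error(sim_config(periods = 16), "1..15")
  expect_error(sim_config(donor_sd = -1), "non-negative")
})

test_that("identical configs give identical outputs (all generators)", {
  mk <- function() sim_config(seed = 21, n_genes = 40, n_clusters = 2,
                              n_cells_per_donor = 20, periods = 2:5,
                              n_samples_per_period = 3)
  g1 <- gen_scored_genelists(mk(), 20, 15, 5)
  g2 <- gen_scored_genelists(mk(), 20, 15, 5)
  expect_identical(g1, g2)
  pass <- gene_namespace(40)[1:10]
  expect_identical(gen_dev_expression(mk(), pass),
                   gen_dev_expression(mk(), pass))
  expect_identical(gen_atlas_table(mk(), pass, gene_namespace(40)[11:15]),
                   gen_atlas_table(mk(), pass, gene_namespace(40)[11:15]))
  s1 <- gen_snuc_dataset(mk(), counts = TRUE)
  s2 <- gen_snuc_dataset(mk(), counts = TRUE)
  expect_identical(s1$values, s2$values)
  expect_identical(s1$dataset$counts, s2$dataset$counts)
})

test_that("gen_scored_genelists honors sizes and overlap exactly", {
  cfg <- sim_config(seed = 1)
  gl <- gen_scored_genelists(cfg, 280, 102, 59)
  a <- filter_by_category(gl$a, c("S", "1", "2", "3"))
  b <- filter_by_category(gl$b, c("S", "1", "2", "3"))
  expect_length(a$symbols, 280)
  expect_length(b$symbols, 102)
  expect_length(intersect(a$symbols, b$symbols), 59)
  # full overlap -> identical symbol sets
  gi <- gen_scored_genelists(cfg, 3, 3, 3)
  expect_setequal(names(gi$a$entries), names(gi$b$entries))
  # disjoint -> union of size 5
  gd <- gen_scored_genelists(cfg, 2, 3, 0)
  expect_length(union(names(gd$a$entries), names(gd$b$entries)), 5)
  expect_error(gen_scored_genelists(cfg, 2, 3, 3), "overlap")
})

test_that("gen_dev_expression round-trips through the human filter", {
  cfg <- sim_config(seed = 31, n_genes = 30, periods = 1:9,
                    n_samples_per_period = 4)
  genes <- gene_namespace(30)
  # saturated: all genes pass
  m_all <- gen_dev_expression(cfg, genes)
  expect_setequal(filter_expressed(m_all, human_filter_criteria())$symbols,
                  genes)
  # empty: none pass
  m_none <- gen_dev_expression(cfg, character())
  expect_length(filter_expressed(m_none, human_filter_criteria())$symbols, 0)
  # arbitrary constructed membership is exactly recovered
  pass <- genes[c(2, 9, 17, 30)]
  m <- gen_dev_expression(cfg, pass)
  expect_setequal(filter_expressed(m, human_filter_criteria())$symbols, pass)
  expect_error(gen_dev_expression(cfg, "NOT_A_GENE"), "namespace")
})

test_that("gen_dev_expression hemisphere layout follows the config", {
  cfg <- sim_config(seed = 32, n_genes = 5, periods = 3,
                    n_samples_per_period = 5, both_hemispheres_frac = 0.8)
  m <- gen_dev_expression(cfg, character())
  amy <- m$sample_meta[m$sample_meta$region == "AMY", ]
  per_donor <- table(amy$donor)
  expect_equal(sum(per_donor == 2), 4)  # ceiling(0.8 * 5) with both hemispheres
  expect_equal(sum(per_donor == 1), 1)
})

test_that("gen_atlas_table round-trips through the mouse filter", {
  cfg <- sim_config(seed = 33, n_genes = 90)
  g <- gene_namespace(90)
  tab <- gen_atlas_table(cfg, g[1:80], g[81:82])
  expect_true(all(tab$level >= -1.5 & tab$level <= 3.5))
  res <- filter_atlas(tab, gene_set(g))
  expect_setequal(res$pass$symbols, g[1:80])
  expect_setequal(res$fail$symbols, g[81:82])
  expect_setequal(res$no_data$symbols, g[83:90])
  expect_error(gen_atlas_table(cfg, g[1:3], g[3:4]), "disjoint")
})

test_that("gen_snuc_dataset carries complete metadata and matched donors", {
  cfg <- sim_config(seed = 34, n_genes = 10, n_clusters = 4,
                    n_cells_per_donor = 12, n_donors_per_group = 3)
  sim <- gen_snuc_dataset(cfg)
  cm <- sim$cell_meta
  expect_equal(nrow(cm), 2 * 3 * 12)
  expect_setequal(unique(cm$diagnosis), c("ASD", "control"))
  expect_true(all(c("age", "sex", "RIN", "PMI") %in% names(cm)))
  # age/sex matched across groups
  dm <- unique(cm[, c("donor", "diagnosis", "age", "sex")])
  expect_equal(sort(dm$age[dm$diagnosis == "ASD"]),
               sort(dm$age[dm$diagnosis == "control"]))
  expect_equal(sort(unique(cm$cluster)), 1:4)
})

test_that("no-noise degenerate case: groups statistically identical", {
  cfg <- sim_config(seed = 35, n_genes = 20, n_clusters = 1,
                    n_cells_per_donor = 300, donor_sd = 0, dropout_base = 0)
  sim <- gen_snuc_dataset(cfg)
  v <- as.matrix(sim$values)
  asd <- sim$cell_meta$diagnosis == "ASD"
  diff <- rowMeans(v[, asd]) - rowMeans(v[, !asd])
  # sigma = 1, 1500 cells per group -> se of the difference ~ 0.037
  expect_lt(max(abs(diff)), 0.15)
})

test_that("counts mode produces integer counts preserving zeros", {
  cfg <- sim_config(seed = 36, n_genes = 15, n_clusters = 2,
                    n_cells_per_donor = 15)
  sim <- gen_snuc_dataset(cfg, counts = TRUE)
  cts <- sim$dataset$counts
  expect_true(all(cts@x == floor(cts@x) & cts@x >= 0))
  # a zero on the normalized scale can never become a positive count
  expect_true(all(as.matrix(cts)[as.matrix(sim$values) == 0] == 0))
})

test_that("MTX triplet round trip", {
  cfg <- sim_config(seed = 37, n_genes = 8, n_clusters = 2,
                    n_cells_per_donor = 6)
  sim <- gen_snuc_dataset(cfg, counts = TRUE)
  dir <- tempfile()
  write_snuc_dataset(sim$dataset, dir)
  d2 <- read_snuc_dataset(dir)
  expect_equal(as.matrix(d2$counts), as.matrix(sim$dataset$counts))
  expect_equal(d2$cell_meta$donor, sim$dataset$cell_meta$donor)
})
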