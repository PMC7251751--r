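# Build a complete synthetic input bundle on disk plus its pipeline config.
# Constructed truth (returned alongside) is known exactly at every stage:
#   lists of sizes 32 and 20 sharing 7 symbols -> union = all 45 universe
#   symbols; the expression matrix covers genes 1..40 (5 union genes have no
#   data) with genes 1..30 passing; the atlas covers 22 of the human-pass
#   genes with 20 passing; the snRNA-seq data carries two strongly planted
#   cluster-specific DE effects in mouse-pass genes. Donor noise is kept
#   small (donor_sd = 0.05) so the planted DE truth is recoverable.
build_bundle <- function(dir, seed = 99) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- gene_namespace(45)
  truth <- list(union = g,
                human_pass = g[1:30],
                human_no_data = g[41:45],
                mouse_pass = g[1:20],
                mouse_fail = g[21:22],
                de = data.frame(gene = g[c(1, 5)], cluster = c(1L, 2L),
                                log2_effect = 2.5, logit_effect = 1.5))

  cfg_lists <- sim_config(seed = seed, universe = 45)
  gl <- gen_scored_genelists(cfg_lists, 32, 20, 7)
  write_scored_genelist(gl$a, file.path(dir, "list_a.tsv"))
  write_scored_genelist(gl$b, file.path(dir, "list_b.tsv"))

  cfg_expr <- sim_config(seed = seed + 1, n_genes = 40, periods = 1:9,
                         n_samples_per_period = 4)
  m <- gen_dev_expression(cfg_expr, truth$human_pass)
  write_dev_expression(m, file.path(dir, "expression.tsv"),
                       file.path(dir, "samples.tsv"))

  cfg_atlas <- sim_config(seed = seed + 2, n_genes = 45)
  tab <- gen_atlas_table(cfg_atlas, truth$mouse_pass, truth$mouse_fail)
  write_atlas_table(tab, file.path(dir, "atlas.tsv"))

  cfg_snuc <- sim_config(seed = seed + 3, n_genes = 45, n_clusters = 2,
                         n_donors_per_group = 3, n_cells_per_donor = 60,
                         donor_sd = 0.05, planted_de = truth$de)
  sim <- gen_snuc_dataset(cfg_snuc, counts = TRUE)
  write_snuc_dataset(sim$dataset, file.path(dir, "snuc"))

  config <- list(schema_version = 1L, seed = seed, universe = 20000,
                 lists = list(a = file.path(dir, "list_a.tsv"),
                              b = file.path(dir, "list_b.tsv"),
                              keep = c("S", "1", "2", "3")),
                 human = list(expr = file.path(dir, "expression.tsv"),
                              meta = file.path(dir, "samples.tsv")),
                 mouse = list(atlas = file.path(dir, "atlas.tsv")),
                 snuc = list(dir = file.path(dir, "snuc"),
                             min_detect = 0.05),
                 out_dir = file.path(dir, "out"))
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE)
  list(config = config, config_path = cfg_path, truth = truth)
}

# One shared bundle + orchestrated run per test session (the DE stage is the
# slow part; several tests only need to inspect the same deterministic run).
.bundle_cache <- new.env(parent = emptyenv())
get_bundle_run <- function() {
  if (!exists("res", envir = .bundle_cache)) {
    b <- build_bundle(tempfile("bundle"))
    rep <- suppressWarnings(run_pipeline(b$config, verbose = FALSE))
    assign("res", list(bundle = b, report = rep), envir = .bundle_cache)
  }
  get("res", envir = .bundle_cache)
}
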