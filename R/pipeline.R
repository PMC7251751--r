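#' @title End-to-end pipeline orchestration
#' @name pipeline
#' @description
#' Runs the full candidate-gene pipeline in order — list integration,
#' human developmental-expression filter, mouse atlas filter, then (if a
#' single-nucleus dataset is configured) per-cluster differential
#' expression and cell-type-resolved overlap — writing every intermediate
#' gene set to disk plus a machine-readable report. Counts are internally
#' consistent at every stage (`pass + fail + no_data = input`) and
#' percentages are `100 * pass / (pass + fail)` rounded half-up to one
#' decimal.
NULL

PIPELINE_SCHEMA_VERSION <- 1L

#' Read a pipeline configuration file (JSON)
#'
#' @param path JSON file with fields `schema_version`, `seed`, `universe`,
#'   `lists` (paths `a`, `b`, categories `keep`), `human` (paths `expr`,
#'   `meta` plus [human_filter_criteria()] fields), `mouse` (path `atlas`
#'   plus [atlas_criteria()] fields), optional `snuc` (path `dir` plus DE
#'   thresholds), `out_dir`.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.integer(cfg$schema_version %||% -1L),
                 PIPELINE_SCHEMA_VERSION))
    stop_validation("unsupported config schema_version (expected %d)",
                    PIPELINE_SCHEMA_VERSION)
  structure(cfg, class = "pipeline_config")
}

# stable config fingerprint without external digest packages (FNV-1a 32 bit)
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    # 32-bit modular multiply in doubles without losing low-order bits
    h <- ((h %/% 65536 * 16777619) %% 65536 * 65536 +
            h %% 65536 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' @param config a `pipeline_config` (see [read_pipeline_config()]) or a
#'   list with the same structure.
#' @param verbose log per-stage counts.
#' @return list of class `pipeline_report` (also written to
#'   `out_dir/report.json` and `out_dir/report.tsv`).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  cfg <- config
  out <- cfg$out_dir %||% "."
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  universe <- cfg$universe %||% 20000
  log_line <- function(...) if (verbose) message(sprintf(...))

  # 1. gene-list integration ------------------------------------------------
  stage1 <- run_stage("integrate", {
    la <- read_scored_genelist(cfg$lists$a)
    lb <- read_scored_genelist(cfg$lists$b)
    keep <- cfg$lists$keep %||% c("S", "1", "2", "3")
    sa <- filter_by_category(la, keep)
    sb <- filter_by_category(lb, keep)
    int <- integrate_sets(sa, sb)
    ov <- overlap_test(sa, sb, universe = universe)
    write_gene_set(int$union, file.path(out, "genes_union.txt"))
    write_gene_set(int$intersection, file.path(out, "genes_intersection.txt"))
    list(set_a = sa, set_b = sb, union = int$union,
         intersection = int$intersection, overlap = ov)
  })
  log_line("[integrate] |A|=%d |B|=%d overlap=%d union=%d p=%.3g",
           length(stage1$set_a), length(stage1$set_b),
           stage1$overlap$overlap, length(stage1$union),
           stage1$overlap$p_value)

  # 2. human developmental expression filter --------------------------------
  stage2 <- run_stage("filter-human", {
    m <- read_dev_expression(cfg$human$expr, cfg$human$meta)
    crit <- human_filter_criteria(
      region = cfg$human$region %||% "AMY",
      period_lo = cfg$human$period_lo %||% 2,
      period_hi = cfg$human$period_hi %||% 8,
      threshold = cfg$human$threshold %||% 6.0,
      mode = cfg$human$mode %||% "period_median")
    res <- filter_human(m, stage1$union, crit)
    write_gene_set(res$pass, file.path(out, "genes_human_pass.txt"))
    write_filter_report(res, file.path(out, "human_filter_report.tsv"))
    if (!is.null(res$profile))
      write_period_profile(res$profile, file.path(out, "human_period_profile.tsv"))
    res$variance <- list(
      subset = tryCatch(variance_summary(m, res$pass), error = function(e) NA_real_),
      background = tryCatch(variance_summary(m), error = function(e) NA_real_))
    res
  })
  log_line("[filter-human] %d input, %d no-data, %d pass / %d with data (%.1f%%)",
           length(stage1$union), length(stage2$no_data), length(stage2$pass),
           length(stage2$pass) + length(stage2$fail), stage2$pct_pass)

  # 3. mouse atlas filter ----------------------------------------------------
  stage3 <- run_stage("filter-mouse", {
    tab <- read_atlas_table(cfg$mouse$atlas)
    crit <- atlas_criteria(
      structures = cfg$mouse$structures %||% c("RSP", "Tel", "PedHy"),
      min_level = cfg$mouse$min_level %||% 2.0,
      ages = cfg$mouse$ages %||% c("E11.5", "E13.5", "E15.5", "E18.5", "P4"))
    cov <- coverage_report(tab, stage2$pass)
    res <- filter_atlas(tab, stage2$pass, crit)
    res$coverage <- cov
    write_gene_set(res$pass, file.path(out, "genes_mouse_pass.txt"))
    write_filter_report(res, file.path(out, "mouse_filter_report.tsv"))
    res
  })
  log_line("[filter-mouse] %d queried, %d no-data, %d pass / %d with data (%.1f%%)",
           length(stage2$pass), length(stage3$no_data), length(stage3$pass),
           length(stage3$pass) + length(stage3$fail), stage3$pct_pass)

  # 4. single-nucleus DE + cell-type overlap --------------------------------
  stage4 <- NULL
  if (!is.null(cfg$snuc)) {
    stage4 <- run_stage("de", {
      d <- read_snuc_dataset(cfg$snuc$dir)
      de <- run_de(d,
                   fdr_cut = cfg$snuc$fdr %||% 0.05,
                   fc_cut = cfg$snuc$fc %||% 0.10,
                   min_detect = cfg$snuc$min_detect %||% 0.01,
                   fdr_scope = cfg$snuc$fdr_scope %||% "cluster")
      counts <- de_event_counts(de)
      ov <- celltype_overlap(de, list(stage2$pass, stage3$pass),
                             universe = universe)
      write_result_table(de, file.path(out, "de_table.tsv"))
      write_result_table(ov, file.path(out, "celltype_overlap.tsv"))
      list(de = de, events = counts$events, genes = counts$genes,
           overlap = ov)
    })
    log_line("[de] %d DE events in %d genes", stage4$events, stage4$genes)
  }

  report <- list(
    schema_version = PIPELINE_SCHEMA_VERSION,
    provenance = list(config_hash = config_hash(cfg),
                      seed = cfg$seed %||% NA,
                      timestamp = format(Sys.time(), tz = "UTC")),
    integrate = list(size_a = length(stage1$set_a),
                     size_b = length(stage1$set_b),
                     overlap = stage1$overlap$overlap,
                     union = length(stage1$union),
                     overlap_p = stage1$overlap$p_value,
                     universe = universe),
    human = list(input = length(stage1$union),
                 no_data = length(stage2$no_data),
                 pass = length(stage2$pass), fail = length(stage2$fail),
                 pct_pass = stage2$pct_pass,
                 variance_subset = stage2$variance$subset,
                 variance_background = stage2$variance$background),
    mouse = list(input = length(stage2$pass),
                 no_data = length(stage3$no_data),
                 pass = length(stage3$pass), fail = length(stage3$fail),
                 pct_pass = stage3$pct_pass,
                 with_data = stage3$coverage$with_data,
                 without_data = stage3$coverage$without_data),
    de = if (!is.null(stage4)) list(events = stage4$events,
                                    genes = stage4$genes) else NULL,
    gene_sets = list(union = stage1$union$symbols,
                     human_pass = stage2$pass$symbols,
                     mouse_pass = stage3$pass$symbols))
  class(report) <- "pipeline_report"
  write_pipeline_report(report, out)
  report
}

#' Write a pipeline report as JSON and TSV
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  stages <- c("integrate", "human", "mouse", "de")
  rows <- list()
  for (s in stages) {
    x <- report[[s]]
    if (is.null(x)) next
    for (f in names(x))
      if (is.numeric(x[[f]]) && length(x[[f]]) == 1)
        rows[[length(rows) + 1L]] <- data.frame(stage = s, field = f,
                                                value = x[[f]])
  }
  write.table(do.call(rbind, rows), file.path(dir, "report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
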