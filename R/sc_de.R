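#' @title Cell-type-resolved differential expression
#' @name sc_de
#' @description
#' Per-cluster diagnosis testing over all (sufficiently detected) genes:
#' hurdle mixed-model fit, likelihood-ratio test, model-based fold change
#' from both the full covariate model and a simplified diagnosis-only
#' model, Benjamini-Hochberg FDR within cluster, and the conjunction call
#' `is_de = (FDR < 0.05) AND (at least 10% expression difference under both
#' models)`. A (gene, cluster) pair that is called is one differential
#' expression *event*; a gene may contribute events in several clusters.
NULL

test_gene <- function(y, meta, spec, fc_spec) {
  fit <- fit_hurdle(y, meta, spec)
  lrt <- lrt_diagnosis(fit)
  fc_full <- fold_change(fit)
  fit_s <- fit_hurdle(y, meta, fc_spec)
  fc_simp <- fold_change(fit_s)
  data.frame(log2_fc = fc_full$log2_fc,
             pct_change = fc_full$pct_change,
             log2_fc_simplified = fc_simp$log2_fc,
             pct_change_simplified = fc_simp$pct_change,
             lrt_stat = lrt$lrt_stat, df = lrt$df,
             p_value = lrt$p_value,
             fit_status = fit$fit_status,
             detect_rate = fit$detect_rate)
}

#' Run diagnosis differential expression per cluster
#'
#' Normalizes the counts, then for every cluster tests every gene detected
#' in at least `min_detect` of the cluster's cells: full-model hurdle fit
#' with LRT for diagnosis, simplified diagnosis-only fit for the second
#' fold-change gate, then [call_de()] for FDR and the DE call.
#'
#' @param d a [snuc_dataset()].
#' @param clusters clusters to test (default all).
#' @param genes optional subset of gene symbols to test.
#' @param fdr_cut FDR threshold (default 0.05).
#' @param fc_cut minimum fractional expression difference (default 0.10,
#'   i.e. at least 10% change on the linear scale, required under both the
#'   full and the simplified model).
#' @param min_detect minimum fraction of the cluster's cells in which a
#'   gene must be detected to be tested (default 0.01).
#' @param spec a [hurdle_spec()] for the full model.
#' @param scale_factor normalization pseudo library size.
#' @param fdr_scope `"cluster"` (default: BH within each cluster, matching
#'   per-cell-type gene lists) or `"global"` (BH across all tested pairs).
#' @param verbose print per-cluster progress.
#' @return a `de_result` data.frame: gene, cluster, log2_fc, pct_change,
#'   (simplified variants), lrt_stat, df, p_value, fdr, is_de, fit_status.
#' @export
run_de <- function(d, clusters = NULL, genes = NULL, fdr_cut = 0.05,
                   fc_cut = 0.10, min_detect = 0.01, spec = hurdle_spec(),
                   scale_factor = 10000,
                   fdr_scope = c("cluster", "global"), verbose = FALSE) {
  stopifnot(inherits(d, "snuc_dataset"))
  fdr_scope <- match.arg(fdr_scope)
  norm <- normalize_counts(d, scale_factor)
  clusters <- clusters %||% sort(unique(norm$cell_meta$cluster))
  genes <- genes %||% rownames(norm$values)
  fc_spec <- hurdle_spec(random = spec$random, simplified = TRUE,
                         nAGQ = spec$nAGQ, min_pos = spec$min_pos)
  rows <- list()
  for (cl in clusters) {
    idx <- which(norm$cell_meta$cluster == cl)
    if (!length(idx)) next
    meta <- norm$cell_meta[idx, , drop = FALSE]
    sub <- as.matrix(norm$values[genes, idx, drop = FALSE])
    det <- rowMeans(sub > 0)
    test_genes <- rownames(sub)[det >= min_detect]
    skipped <- setdiff(genes, test_genes)
    if (verbose)
      message(sprintf("cluster %s: %d cells, testing %d/%d genes",
                      cl, length(idx), length(test_genes), length(genes)))
    for (g in test_genes) {
      r <- test_gene(sub[g, ], meta, spec, fc_spec)
      r$gene <- g; r$cluster <- cl
      rows[[length(rows) + 1L]] <- r
    }
    if (length(skipped))
      rows[[length(rows) + 1L]] <- data.frame(
        log2_fc = NA_real_, pct_change = NA_real_,
        log2_fc_simplified = NA_real_, pct_change_simplified = NA_real_,
        lrt_stat = NA_real_, df = 0L, p_value = NA_real_,
        fit_status = "failed", detect_rate = det[skipped],
        gene = skipped, cluster = cl)
  }
  res <- do.call(rbind, rows)
  res <- res[, c("gene", "cluster", "log2_fc", "pct_change",
                 "log2_fc_simplified", "pct_change_simplified",
                 "lrt_stat", "df", "p_value", "fit_status", "detect_rate")]
  call_de(res, fdr_cut = fdr_cut, fc_cut = fc_cut, fdr_scope = fdr_scope)
}

#' Apply FDR correction and the differential-expression call
#'
#' Benjamini-Hochberg FDR over the LRT p-values (within each cluster by
#' default), then `is_de = (fdr < fdr_cut) AND (|pct_change| >= fc_cut
#' under BOTH the full and the simplified model)`. Failed fits are never
#' called.
#'
#' @param results data.frame with at least `gene`, `cluster`, `p_value`,
#'   `pct_change`, `pct_change_simplified`, `fit_status`.
#' @param fdr_cut,fc_cut thresholds (defaults 0.05 and 0.10).
#' @param fdr_scope `"cluster"` or `"global"`.
#' @return the data.frame with `fdr` and `is_de` columns, class
#'   `de_result`.
#' @export
call_de <- function(results, fdr_cut = 0.05, fc_cut = 0.10,
                    fdr_scope = c("cluster", "global")) {
  fdr_scope <- match.arg(fdr_scope)
  results$fdr <- NA_real_
  if (fdr_scope == "global") {
    ok <- !is.na(results$p_value)
    results$fdr[ok] <- p.adjust(results$p_value[ok], method = "BH")
  } else {
    for (cl in unique(results$cluster)) {
      ix <- which(results$cluster == cl & !is.na(results$p_value))
      results$fdr[ix] <- p.adjust(results$p_value[ix], method = "BH")
    }
  }
  pct_ok <- !is.na(results$pct_change) & !is.na(results$pct_change_simplified) &
    abs(results$pct_change) >= fc_cut &
    abs(results$pct_change_simplified) >= fc_cut
  results$is_de <- results$fit_status != "failed" &
    !is.na(results$fdr) & results$fdr < fdr_cut & pct_ok
  class(results) <- c("de_result", "data.frame")
  attr(results, "fdr_cut") <- fdr_cut
  attr(results, "fc_cut") <- fc_cut
  results
}

#' Count DE events and distinct DE genes
#'
#' @param de a `de_result`.
#' @return list `events` (called gene-cluster pairs) and `genes` (distinct
#'   genes); `events >= genes`, with equality iff no gene is called in two
#'   clusters.
#' @export
de_event_counts <- function(de) {
  hits <- de[de$is_de, , drop = FALSE]
  list(events = nrow(hits), genes = length(unique(hits$gene)))
}

#' One-vs-rest cluster marker identification
#'
#' For each requested cluster, every sufficiently detected gene is tested
#' with a covariate-free, fixed-effects hurdle model of the cluster
#' indicator (logistic detection part + Gaussian level part, LRT for the
#' indicator). Enrichment is the model-based log2 difference between the
#' cluster and all other nuclei; a marker is an enriched gene
#' (`enrichment > 0`) at `fdr < fdr_cut`.
#'
#' @param d a [snuc_dataset()].
#' @param clusters clusters to profile (default all).
#' @param min_detect minimum detection fraction among the cluster's cells.
#' @param fdr_cut marker FDR threshold (default 0.05).
#' @param scale_factor normalization pseudo library size.
#' @return `marker_result` data.frame: gene, cluster, log2_enrichment,
#'   lrt_stat, df, p_value, fdr, is_marker.
#' @export
find_markers <- function(d, clusters = NULL, min_detect = 0.05,
                         fdr_cut = 0.05, scale_factor = 10000) {
  stopifnot(inherits(d, "snuc_dataset"))
  norm <- normalize_counts(d, scale_factor)
  clusters <- clusters %||% sort(unique(norm$cell_meta$cluster))
  all_cl <- norm$cell_meta$cluster
  vals <- as.matrix(norm$values)
  spec <- hurdle_spec(covariates = character(), random = NULL)
  rows <- list()
  for (cl in clusters) {
    in_cl <- all_cl == cl
    if (!any(in_cl) || all(in_cl))
      stop_validation("cluster %s is empty or spans all cells", cl)
    det <- rowMeans(vals[, in_cl, drop = FALSE] > 0)
    # reuse the diagnosis machinery with the cluster indicator as the group
    meta <- data.frame(diagnosis = ifelse(in_cl, "ASD", "control"),
                       donor = "d0")
    for (g in rownames(vals)[det >= min_detect]) {
      fit <- fit_hurdle_indicator(vals[g, ], meta, spec)
      lrt <- lrt_diagnosis(fit)
      fc <- fold_change(fit)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, cluster = cl, log2_enrichment = fc$log2_fc,
        lrt_stat = lrt$lrt_stat, df = lrt$df, p_value = lrt$p_value,
        fit_status = fit$fit_status)
    }
  }
  res <- do.call(rbind, rows)
  res$fdr <- NA_real_
  for (cl in unique(res$cluster)) {
    ix <- which(res$cluster == cl & !is.na(res$p_value))
    res$fdr[ix] <- p.adjust(res$p_value[ix], method = "BH")
  }
  res$is_marker <- !is.na(res$fdr) & res$fdr < fdr_cut &
    !is.na(res$log2_enrichment) & res$log2_enrichment > 0
  class(res) <- c("marker_result", "data.frame")
  res
}

# fit_hurdle requires >= 2 donors per group; the marker model has no
# grouping, so bypass that check with a single pseudo-donor per group.
fit_hurdle_indicator <- function(y, meta, spec) {
  meta$donor <- paste0(meta$diagnosis, rep(c("a", "b"), length.out = nrow(meta)))
  fit_hurdle(y, meta, spec)
}

#' Overlap DE genes per cluster with candidate gene sets
#'
#' For every cluster with DE calls and every supplied gene set, reports the
#' intersecting symbols and a hypergeometric enrichment p-value (via
#' [overlap_test()]) against a stated universe.
#'
#' @param de a `de_result` (from [run_de()] / [call_de()]).
#' @param sets list of [gene_set()]s.
#' @param universe universe size for the enrichment test (default 20000).
#' @return data.frame: cluster, set, n_de, n_set, overlap, p_value,
#'   expected_overlap, genes (comma-separated intersecting symbols).
#' @export
celltype_overlap <- function(de, sets, universe = 20000) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  rows <- list()
  for (cl in unique(de$cluster)) {
    de_genes <- gene_set(de$gene[de$cluster == cl & de$is_de],
                         name = paste0("de_cluster", cl))
    for (s in sets) {
      ov <- overlap_test(de_genes, s, universe = universe)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, set = s$name,
        n_de = ov$size_a, n_set = ov$size_b, overlap = ov$overlap,
        expected_overlap = ov$expected_overlap, p_value = ov$p_value,
        genes = paste(intersect(de_genes$symbols, s$symbols),
                      collapse = ","))
    }
  }
  do.call(rbind, rows)
}

# ---- I/O ------------------------------------------------------------------

#' Write a single-nucleus dataset as MatrixMarket triplet
#'
#' Writes `matrix.mtx` (genes x cells), `genes.tsv` (one symbol per line)
#' and `cells.tsv` (cell metadata incl. barcode column `cell_id`) into
#' `dir`.
#'
#' @param d a [snuc_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_snuc_dataset <- function(d, dir) {
  stopifnot(inherits(d, "snuc_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(d$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(d$counts), file.path(dir, "genes.tsv"))
  write.table(d$cell_meta, file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a single-nucleus dataset from a MatrixMarket triplet directory
#'
#' Expects `matrix.mtx`, `genes.tsv`, `cells.tsv` as written by
#' [write_snuc_dataset()].
#'
#' @param dir directory path.
#' @return a [snuc_dataset()].
#' @export
read_snuc_dataset <- function(dir) {
  m <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  meta <- read.delim(file.path(dir, "cells.tsv"))
  rownames(m) <- genes
  colnames(m) <- as.character(meta$cell_id)
  snuc_dataset(m, meta)
}

#' Write a DE, marker or overlap table as TSV
#' @param x data.frame result table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
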