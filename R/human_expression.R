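#' @title Developmental human brain expression filtering
#' @name human_expression
#' @description
#' Operations over a developmental expression matrix of log2 signal
#' intensities (genes x samples) with per-sample metadata (brain region,
#' developmental period 1-15, hemisphere, donor). The filtering rule for
#' "expressed in the developing amygdala" is: after averaging left/right
#' hemisphere values within each (donor, region, period), take per-period
#' medians across samples and require the median to exceed a log2-intensity
#' threshold (default strictly > 6.0) in at least one period inside the
#' susceptibility window (default periods 2 through 8: early fetal through
#' early infancy).
NULL

#' Construct a developmental expression matrix
#'
#' @param values numeric matrix, genes x samples, finite log2 intensities;
#'   rownames are gene symbols, colnames are sample ids.
#' @param sample_meta data.frame with one row per sample and columns
#'   `sample_id`, `region`, `period` (integer 1-15), `hemisphere`
#'   (`"L"`, `"R"` or `NA`), `donor`.
#' @return object of class `dev_expression`.
#' @export
dev_expression <- function(values, sample_meta) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_validation("values must have gene rownames and sample colnames")
  req <- c("sample_id", "region", "period", "hemisphere", "donor")
  miss <- setdiff(req, names(sample_meta))
  if (length(miss))
    stop_validation("sample_meta missing columns: %s",
                    paste(miss, collapse = ", "))
  sample_meta <- as.data.frame(sample_meta)
  if (!identical(sort(colnames(values)), sort(as.character(sample_meta$sample_id))))
    stop_validation("colnames(values) must match sample_meta$sample_id")
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ]
  if (any(!is.finite(values)))
    stop_validation("expression values must all be finite")
  if (any(is.na(sample_meta$region)) || any(is.na(sample_meta$period)))
    stop_validation("every sample needs a region and a period")
  rownames(values) <- normalize_symbols(rownames(values))
  structure(list(values = values, sample_meta = sample_meta),
            class = "dev_expression")
}

#' @export
print.dev_expression <- function(x, ...) {
  cat(sprintf("<dev_expression: %d genes x %d samples; regions: %s; periods %s>\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$sample_meta$region), collapse = ","),
              paste(range(x$sample_meta$period), collapse = "-")))
  invisible(x)
}

#' Criteria for the human developmental expression filter
#'
#' @param region region code to filter on (default `"AMY"`, amygdala).
#' @param period_lo,period_hi inclusive developmental-period window
#'   (defaults 2 and 8: ~8 post-conceptional weeks through 6 months of age).
#' @param threshold log2 signal intensity that a gene must strictly exceed
#'   (default 6.0, the conventional positive-expression cutoff for these
#'   arrays; a value of exactly 6.0 fails).
#' @param mode `"period_median"` (default; threshold applied to per-period
#'   medians) or `"any_sample"` (threshold applied to individual
#'   hemisphere-averaged sample values). `any_sample` is never stricter.
#' @return list of class `human_filter_criteria`.
#' @export
human_filter_criteria <- function(region = "AMY", period_lo = 2, period_hi = 8,
                                  threshold = 6.0,
                                  mode = c("period_median", "any_sample")) {
  mode <- match.arg(mode)
  period_lo <- assert_count(period_lo, "period_lo")
  period_hi <- assert_count(period_hi, "period_hi")
  if (period_lo > period_hi) stop_validation("period_lo > period_hi")
  if (!is.finite(threshold)) stop_validation("threshold must be finite")
  structure(list(region = region, period_lo = period_lo,
                 period_hi = period_hi, threshold = threshold, mode = mode),
            class = "human_filter_criteria")
}

#' Average hemispheric values into one value per (donor, region, period)
#'
#' Samples sharing a (donor, region, period) key but differing in hemisphere
#' are collapsed to their arithmetic mean; samples with a single hemisphere
#' (or no hemisphere annotation) pass through unchanged. More than two
#' entries for one key is a validation error. Idempotent.
#'
#' @param m a [dev_expression()].
#' @return a [dev_expression()] with one column per (donor, region, period),
#'   hemisphere set to `NA`.
#' @export
average_hemispheres <- function(m) {
  stopifnot(inherits(m, "dev_expression"))
  meta <- m$sample_meta
  key <- paste(meta$donor, meta$region, meta$period, sep = "\r")
  groups <- split(seq_len(nrow(meta)), key)
  n_per <- lengths(groups)
  if (any(n_per > 2)) {
    bad <- names(groups)[which(n_per > 2)[1]]
    stop_validation(">2 hemisphere entries for (donor, region, period) = (%s)",
                    gsub("\r", ", ", bad))
  }
  groups <- groups[order(vapply(groups, min, 1L))]  # keep input sample order
  vals <- vapply(groups, function(ix) {
    if (length(ix) == 1) m$values[, ix] else rowMeans(m$values[, ix])
  }, numeric(nrow(m$values)))
  first <- vapply(groups, `[`, 1L, 1L)
  out_meta <- data.frame(sample_id = paste0("avg_", meta$donor[first], "_",
                                            meta$region[first], "_p",
                                            meta$period[first]),
                         region = meta$region[first],
                         period = meta$period[first],
                         hemisphere = NA_character_,
                         donor = meta$donor[first],
                         stringsAsFactors = FALSE)
  vals <- matrix(vals, nrow = nrow(m$values),
                 dimnames = list(rownames(m$values), out_meta$sample_id))
  dev_expression(vals, out_meta)
}

#' Per-period median expression profile for one region
#'
#' Hemisphere-averages the matrix, restricts to `region`, then takes the
#' median across samples within each developmental period, per gene. Medians
#' of an even number of values use the midpoint convention.
#'
#' @param m a [dev_expression()].
#' @param region region code present in the metadata.
#' @return a `period_profile`: numeric matrix genes x periods (columns named
#'   by period index, ascending), with attribute `region`.
#' @export
summarize_by_period <- function(m, region = "AMY") {
  stopifnot(inherits(m, "dev_expression"))
  if (!region %in% m$sample_meta$region)
    stop_validation("region '%s' absent from sample metadata", region)
  avg <- average_hemispheres(m)
  keep <- avg$sample_meta$region == region
  vals <- avg$values[, keep, drop = FALSE]
  periods <- sort(unique(avg$sample_meta$period[keep]))
  prof <- vapply(periods, function(p) {
    cols <- avg$sample_meta$period[keep] == p
    apply(vals[, cols, drop = FALSE], 1, median)
  }, numeric(nrow(vals)))
  prof <- matrix(prof, nrow = nrow(vals),
                 dimnames = list(rownames(vals), as.character(periods)))
  structure(prof, region = region, class = c("period_profile", "matrix", "array"))
}

#' Filter genes expressed in the developmental window
#'
#' In mode `"period_median"` a gene passes iff its per-period median strictly
#' exceeds `crit$threshold` in at least one period within
#' `[crit$period_lo, crit$period_hi]`. In mode `"any_sample"` a gene passes
#' iff any single hemisphere-averaged sample value in the window exceeds the
#' threshold (requires the full matrix, not just the profile).
#'
#' @param x a `period_profile` (from [summarize_by_period()]) or a
#'   [dev_expression()] (required for mode `"any_sample"`).
#' @param crit a [human_filter_criteria()].
#' @return a [gene_set()] of passing genes.
#' @export
filter_expressed <- function(x, crit = human_filter_criteria()) {
  stopifnot(inherits(crit, "human_filter_criteria"))
  if (inherits(x, "dev_expression")) {
    if (crit$mode == "any_sample") {
      avg <- average_hemispheres(x)
      keep <- avg$sample_meta$region == crit$region &
        avg$sample_meta$period >= crit$period_lo &
        avg$sample_meta$period <= crit$period_hi
      if (!any(keep))
        stop_validation("no samples in region %s periods %d-%d",
                        crit$region, crit$period_lo, crit$period_hi)
      v <- avg$values[, keep, drop = FALSE]
      pass <- apply(v, 1, function(r) any(r > crit$threshold))
      return(gene_set(rownames(v)[pass], name = "human_expressed"))
    }
    x <- summarize_by_period(x, crit$region)
  }
  if (!inherits(x, "period_profile"))
    stop_validation("x must be a dev_expression or period_profile")
  if (crit$mode == "any_sample")
    stop_validation("mode 'any_sample' needs the full dev_expression matrix")
  if (!nrow(x)) stop_validation("empty profile")
  periods <- as.integer(colnames(x))
  win <- periods >= crit$period_lo & periods <= crit$period_hi
  if (!any(win))
    stop_validation("no periods in window %d-%d present in the profile",
                    crit$period_lo, crit$period_hi)
  pass <- apply(x[, win, drop = FALSE], 1, function(r) any(r > crit$threshold))
  gene_set(rownames(x)[pass], name = "human_expressed")
}

#' Apply the human expression filter to a query gene set
#'
#' Partitions the query genes into `pass`, `fail` and `no_data` (genes absent
#' from the expression matrix entirely — e.g. candidates with no array data —
#' which are reported separately and never counted as failures). The reported
#' pass rate is `100 * pass / (pass + fail)`, rounded half-up to 1 decimal.
#'
#' @param m a [dev_expression()].
#' @param genes a [gene_set()] of query genes.
#' @param crit a [human_filter_criteria()].
#' @return list with `pass`, `fail`, `no_data` ([gene_set()]s), `pct_pass`,
#'   and `profile` (the per-period median matrix for the query genes with
#'   data).
#' @export
filter_human <- function(m, genes, crit = human_filter_criteria()) {
  stopifnot(inherits(m, "dev_expression"), inherits(genes, "gene_set"))
  have <- intersect(genes$symbols, rownames(m$values))
  no_data <- setdiff(genes$symbols, have)
  sub <- dev_expression(m$values[have, , drop = FALSE], m$sample_meta)
  passed <- if (length(have)) filter_expressed(sub, crit)$symbols else character()
  prof <- if (length(have)) summarize_by_period(sub, crit$region) else NULL
  n_pass <- length(passed); n_data <- length(have)
  list(pass = gene_set(passed, "human_pass"),
       fail = gene_set(setdiff(have, passed), "human_fail"),
       no_data = gene_set(no_data, "human_no_data"),
       pct_pass = if (n_data) round_half_up(100 * n_pass / n_data, 1) else NA_real_,
       profile = prof)
}

#' Mean per-gene expression variance
#'
#' Computes the sample variance (n-1 denominator) of each gene across all
#' samples, then averages the per-gene variances over `subset`. With
#' `subset = NULL` the background is "all expressed genes": those with mean
#' expression > 0. Query genes missing from the matrix are skipped with a
#' warning.
#'
#' @param m a [dev_expression()].
#' @param subset a [gene_set()], or `NULL` for the expressed background.
#' @param per_gene if `TRUE`, return the named vector of per-gene variances
#'   instead of their mean.
#' @return a single number (mean of per-gene variances), or a named vector.
#' @export
variance_summary <- function(m, subset = NULL, per_gene = FALSE) {
  stopifnot(inherits(m, "dev_expression"))
  if (is.null(subset)) {
    genes <- rownames(m$values)[rowMeans(m$values) > 0]
  } else {
    stopifnot(inherits(subset, "gene_set"))
    genes <- intersect(subset$symbols, rownames(m$values))
    missing <- setdiff(subset$symbols, genes)
    if (length(missing))
      warning(sprintf("%d subset genes absent from the matrix were skipped",
                      length(missing)))
  }
  if (!length(genes)) stop_validation("empty effective subset")
  v <- apply(m$values[genes, , drop = FALSE], 1, var)
  if (per_gene) v else mean(v)
}

# ---- I/O ------------------------------------------------------------------

#' Read an expression matrix TSV plus sample-metadata TSV
#'
#' The expression TSV has gene symbols in the first column and sample ids in
#' the header; the metadata TSV has columns sample_id, region, period,
#' hemisphere, donor.
#'
#' @param expr_path,meta_path file paths.
#' @return a [dev_expression()].
#' @export
read_dev_expression <- function(expr_path, meta_path) {
  vals <- read.delim(expr_path, row.names = 1, check.names = FALSE)
  meta <- read.delim(meta_path, colClasses = c(period = "integer"))
  dev_expression(as.matrix(vals), meta)
}

#' Write an expression matrix and its sample metadata as TSV
#' @param m a [dev_expression()].
#' @param expr_path,meta_path output paths.
#' @return `expr_path`, invisibly.
#' @export
write_dev_expression <- function(m, expr_path, meta_path) {
  stopifnot(inherits(m, "dev_expression"))
  df <- data.frame(gene = rownames(m$values), m$values, check.names = FALSE)
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(m$sample_meta, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(expr_path)
}

#' Write a period profile as TSV (heatmap-ready gene x period matrix)
#' @param profile a `period_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_period_profile <- function(profile, path) {
  df <- data.frame(gene = rownames(profile), unclass(profile),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
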