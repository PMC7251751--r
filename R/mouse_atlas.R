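#' @title Developing mouse brain atlas filtering
#' @name mouse_atlas
#' @description
#' Applies regional/temporal expression criteria to an atlas-style
#' annotation table of (gene, structure, age, level) records, where `level`
#' is an expression summary on a log scale confined to \[-1.5, 3.5\]. The
#' default criteria keep genes expressed at level >= 2.0 (inclusive: "log 2
#' or higher") in at least one amygdala-precursor structure — rostral
#' secondary prosencephalon (RSP), telencephalic vesicle (Tel) or peduncular
#' hypothalamus (PedHy) — at at least one of five embryonic/early-postnatal
#' stages (E11.5, E13.5, E15.5, E18.5, P4). Note the asymmetry with the
#' human filter: the mouse level threshold is inclusive (>=) while the human
#' log2-intensity threshold is strict (>); each follows its stated rule.
NULL

ATLAS_LEVEL_RANGE <- c(-1.5, 3.5)

#' Construct an atlas annotation table
#'
#' @param gene,structure,age character vectors (recycled to equal length).
#' @param level numeric expression levels, each in \[-1.5, 3.5\].
#' @return data.frame of class `atlas_table` with those four columns; gene
#'   symbols are uppercased so human/mouse symbol matching is
#'   case-insensitive.
#' @export
atlas_table <- function(gene, structure, age, level) {
  df <- data.frame(gene = normalize_symbols(gene),
                   structure = as.character(structure),
                   age = as.character(age),
                   level = as.numeric(level),
                   stringsAsFactors = FALSE)
  bad <- which(!is.finite(df$level) | df$level < ATLAS_LEVEL_RANGE[1] |
                 df$level > ATLAS_LEVEL_RANGE[2])
  if (length(bad))
    stop_validation(
      "level outside [%.1f, %.1f] for record %d (gene %s, %s, %s: %s)",
      ATLAS_LEVEL_RANGE[1], ATLAS_LEVEL_RANGE[2], bad[1],
      df$gene[bad[1]], df$structure[bad[1]], df$age[bad[1]],
      format(df$level[bad[1]]))
  class(df) <- c("atlas_table", "data.frame")
  df
}

#' Criteria for the mouse atlas filter
#'
#' @param structures non-empty set of qualifying structure codes.
#' @param min_level inclusive minimum expression level (default 2.0).
#' @param ages non-empty set of qualifying age stages.
#' @return list of class `atlas_criteria`.
#' @export
atlas_criteria <- function(structures = c("RSP", "Tel", "PedHy"),
                           min_level = 2.0,
                           ages = c("E11.5", "E13.5", "E15.5", "E18.5", "P4")) {
  if (!length(structures) || !length(ages))
    stop_validation("structures and ages must be non-empty")
  structure(list(structures = as.character(structures),
                 min_level = as.numeric(min_level),
                 ages = as.character(ages)),
            class = "atlas_criteria")
}

#' Filter query genes by atlas expression criteria
#'
#' Partitions the query set into three disjoint gene sets: `pass` (at least
#' one record with qualifying structure AND age AND `level >= min_level`),
#' `fail` (present in the table but never qualifying), and `no_data` (absent
#' from the table entirely — tracked separately, never counted as a
#' failure). The pass rate is `100 * pass / (pass + fail)` rounded half-up
#' to 1 decimal.
#'
#' @param table an [atlas_table()].
#' @param genes a [gene_set()] of query genes.
#' @param crit an [atlas_criteria()].
#' @return list with `pass`, `fail`, `no_data` ([gene_set()]s), `pct_pass`,
#'   and `qualifying` (data.frame of the records that made each gene pass).
#' @export
filter_atlas <- function(table, genes, crit = atlas_criteria()) {
  stopifnot(inherits(table, "atlas_table"), inherits(genes, "gene_set"))
  q <- genes$symbols
  have <- intersect(q, unique(table$gene))
  no_data <- setdiff(q, have)
  hits <- table[table$gene %in% have &
                  table$structure %in% crit$structures &
                  table$age %in% crit$ages &
                  table$level >= crit$min_level, , drop = FALSE]
  pass <- intersect(have, unique(hits$gene))
  n_data <- length(have)
  list(pass = gene_set(pass, "mouse_pass"),
       fail = gene_set(setdiff(have, pass), "mouse_fail"),
       no_data = gene_set(no_data, "mouse_no_data"),
       pct_pass = if (n_data) round_half_up(100 * length(pass) / n_data, 1)
                  else NA_real_,
       qualifying = hits)
}

#' Atlas coverage of a query gene set
#'
#' @param table an [atlas_table()].
#' @param genes a [gene_set()].
#' @return list with counts `with_data` and `without_data`; they always sum
#'   to `length(genes)`.
#' @export
coverage_report <- function(table, genes) {
  stopifnot(inherits(table, "atlas_table"), inherits(genes, "gene_set"))
  with_data <- sum(genes$symbols %in% unique(table$gene))
  list(with_data = with_data,
       without_data = length(genes$symbols) - with_data)
}

#' Read an atlas table from long-form TSV (gene, structure, age, level)
#' @param path TSV path with a header row.
#' @return an [atlas_table()].
#' @export
read_atlas_table <- function(path) {
  df <- read.delim(path, colClasses = c(level = "numeric"))
  atlas_table(df$gene, df$structure, df$age, df$level)
}

#' Write an atlas table as long-form TSV
#' @param table an [atlas_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_atlas_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pass/fail/no-data filter report as TSV
#'
#' @param result output of [filter_atlas()] or [filter_human()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(result, path) {
  df <- rbind(
    data.frame(gene = result$pass$symbols, status = "pass"),
    data.frame(gene = result$fail$symbols, status = "fail"),
    data.frame(gene = result$no_data$symbols, status = "no_data"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
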