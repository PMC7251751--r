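#' @title Scored gene lists and derived gene sets
#' @name genesets
#' @description
#' A scored gene list maps gene symbols to an evidence-score category on the
#' SFARI-style scale: `"S"` (syndromic) then `"1"` (high confidence) through
#' `"6"` (evidence does not support a role). Downstream analysis keeps only
#' the higher-confidence categories (S, 1, 2, 3 by default), takes unions and
#' intersections of the resulting plain gene sets, and quantifies overlap
#' significance with a one-sided hypergeometric test.
NULL

ALLOWED_CATEGORIES <- c("S", "1", "2", "3", "4", "5", "6")

#' Construct a scored gene list
#'
#' @param symbols character vector of gene symbols (normalized internally).
#' @param categories character vector of categories, one per symbol, each in
#'   `c("S","1","2","3","4","5","6")`.
#' @param name label for the list.
#' @return object of class `scored_gene_list`.
#' @export
scored_gene_list <- function(symbols, categories, name = "genelist") {
  symbols <- normalize_symbols(symbols)
  categories <- as.character(categories)
  if (length(symbols) != length(categories))
    stop_validation("symbols and categories must have equal length")
  bad <- setdiff(unique(categories), ALLOWED_CATEGORIES)
  if (length(bad))
    stop_validation("unknown categories: %s", paste(bad, collapse = ", "))
  if (anyDuplicated(symbols)) {
    keep <- !duplicated(symbols)
    warning(sprintf("%d duplicate symbols dropped after normalization",
                    sum(!keep)))
    symbols <- symbols[keep]; categories <- categories[keep]
  }
  structure(list(name = name,
                 entries = setNames(categories, symbols)),
            class = "scored_gene_list")
}

#' @export
print.scored_gene_list <- function(x, ...) {
  cat(sprintf("<scored_gene_list '%s': %d genes; categories: %s>\n",
              x$name, length(x$entries),
              paste(sprintf("%s=%d", names(table(x$entries)),
                            table(x$entries)), collapse = " ")))
  invisible(x)
}

#' Construct a gene set
#'
#' @param symbols character vector of symbols; duplicates collapse.
#' @param name label.
#' @return object of class `gene_set` (named list with `name`, `symbols`).
#' @export
gene_set <- function(symbols, name = "geneset") {
  structure(list(name = name,
                 symbols = sort(unique(normalize_symbols(symbols)))),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s': %d genes>\n", x$name, length(x$symbols)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$symbols)

#' Filter a scored list by evidence category
#'
#' Keeps exactly the symbols whose category is in `keep`; the default keeps
#' the high-confidence end of the scale (syndromic through suggestive
#' evidence).
#'
#' @param list a [scored_gene_list()].
#' @param keep non-empty character vector of categories to keep.
#' @return a [gene_set()].
#' @export
filter_by_category <- function(list, keep = c("S", "1", "2", "3")) {
  stopifnot(inherits(list, "scored_gene_list"))
  keep <- as.character(keep)
  if (!length(keep)) stop_validation("'keep' must be non-empty")
  bad <- setdiff(keep, ALLOWED_CATEGORIES)
  if (length(bad))
    stop_validation("unknown categories in 'keep': %s",
                    paste(bad, collapse = ", "))
  gene_set(names(list$entries)[list$entries %in% keep],
           name = paste0(list$name, "_", paste(keep, collapse = "")))
}

#' Integrate two gene sets
#'
#' Cross-references two candidate-gene sets, returning their union (the
#' combined candidate list) and intersection (the genes supported by both
#' sources). `|union| = |a| + |b| - |intersection|` always holds.
#'
#' @param a,b [gene_set()] objects.
#' @return list with elements `union` and `intersection`, both `gene_set`s.
#' @export
integrate_sets <- function(a, b) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  list(union = gene_set(c(a$symbols, b$symbols),
                        name = paste0(a$name, "+", b$name)),
       intersection = gene_set(intersect(a$symbols, b$symbols),
                               name = paste0(a$name, "&", b$name)))
}

#' Hypergeometric overlap enrichment test
#'
#' One-sided enrichment p-value `P(X >= k)` for observing an overlap of size
#' `k = |a intersect b|` between sets of sizes `|a|` and `|b|` drawn from a
#' universe of `universe` genes. The tail sum is evaluated in log space (via
#' [stats::phyper()] with `log.p = TRUE`) so that p-values far below double
#' underflow (~1e-300), such as 1e-120, remain finite and exact.
#'
#' @param a,b [gene_set()] objects.
#' @param universe total number of genes in the sampling universe; defaults
#'   to 20000 (approximate protein-coding gene count).
#' @return list of class `overlap_result`: `size_a`, `size_b`, `overlap`,
#'   `universe`, `expected_overlap`, `p_value`, `log10_p`.
#' @export
overlap_test <- function(a, b, universe = 20000) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  universe <- assert_count(universe, "universe", min = 1)
  k <- length(intersect(a$symbols, b$symbols))
  na <- length(a$symbols); nb <- length(b$symbols)
  n_union <- na + nb - k
  if (universe < n_union)
    stop_validation("universe (%d) smaller than union of the sets (%d)",
                    universe, n_union)
  # P(X >= k) for X ~ Hypergeometric(universe, na marked, nb drawn)
  log_p <- phyper(k - 1, m = na, n = universe - na, k = nb,
                  lower.tail = FALSE, log.p = TRUE)
  structure(list(size_a = na, size_b = nb, overlap = k,
                 universe = universe,
                 expected_overlap = na * nb / universe,
                 p_value = exp(log_p),
                 log10_p = log_p / log(10)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result: |A|=%d |B|=%d overlap=%d universe=%d expected=%.2f p=%.3g (log10 p = %.2f)>\n",
    x$size_a, x$size_b, x$overlap, x$universe, x$expected_overlap,
    x$p_value, x$log10_p))
  invisible(x)
}

# ---- I/O ------------------------------------------------------------------

#' Read a scored gene list from a 2-column TSV (symbol, category)
#'
#' @param path TSV path; a header line is detected by a non-allowed category
#'   token in column 2.
#' @param name label; defaults to the file name.
#' @return a [scored_gene_list()].
#' @export
read_scored_genelist <- function(path, name = NULL) {
  df <- read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop_validation("expected 2 columns in %s", path)
  if (nrow(df) && !(df[1, 2] %in% ALLOWED_CATEGORIES)) df <- df[-1, , drop = FALSE]
  scored_gene_list(df[[1]], df[[2]], name = name %||% basename(path))
}

#' Read a plain gene set from a 1-column text file
#' @param path file with one symbol per line.
#' @param name label; defaults to the file name.
#' @return a [gene_set()].
#' @export
read_gene_set <- function(path, name = NULL) {
  x <- readLines(path)
  x <- x[nzchar(trimws(x))]
  gene_set(x, name = name %||% basename(path))
}

#' Write a gene set as a 1-column text file
#' @param x a [gene_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(x, path) {
  stopifnot(inherits(x, "gene_set"))
  writeLines(x$symbols, path)
  invisible(path)
}

#' Write a scored gene list as 2-column TSV
#' @param x a [scored_gene_list()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scored_genelist <- function(x, path) {
  stopifnot(inherits(x, "scored_gene_list"))
  write.table(data.frame(symbol = names(x$entries),
                         category = unname(x$entries)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
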