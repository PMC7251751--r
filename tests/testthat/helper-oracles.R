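# Independent oracles used across test files.

# Exhaustive hypergeometric upper tail: enumerate every size_b subset of the
# universe and count those overlapping the (fixed) size_a set by >= k.
# Only feasible for small universes; that is the point.
enum_overlap_p <- function(universe, size_a, size_b, k) {
  a <- seq_len(size_a)
  draws <- combn(universe, size_b)
  mean(apply(draws, 2, function(s) sum(s %in% a) >= k))
}

# Build two gene_sets with exact sizes and overlap over a shared namespace.
make_sets <- function(size_a, size_b, k, universe) {
  syms <- sprintf("T%03d", seq_len(universe))
  a <- gene_set(syms[seq_len(size_a)], "a")
  b <- gene_set(syms[c(seq_len(k), size_a + seq_len(size_b - k))], "b")
  list(a = a, b = b)
}

# Brute-force Benjamini-Hochberg: sort, n*p/rank, cumulative min from the
# largest rank down, cap at 1, restore input order.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(1, q)[order(o)]
}

# Small toy expression matrix: 3 genes x 4 AMY samples (2 donors x L/R),
# one period. Used for hand-computed medians/variances.
toy_dev_expression <- function() {
  vals <- rbind(g1 = c(4, 6, 7.2, 7.2),
                g2 = c(5, 5, 7, 7),
                g3 = c(0, 2, 0, 2))
  colnames(vals) <- paste0("s", 1:4)
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     region = "AMY", period = 3L,
                     hemisphere = c("L", "R", "L", "R"),
                     donor = c("d1", "d1", "d2", "d2"))
  dev_expression(vals, meta)
}
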