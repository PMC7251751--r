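#' @title Synthetic-data generators
#' @name synthetic_data
#' @description
#' Generators that emulate the statistical structure of every input the
#' pipeline consumes — scored candidate-gene lists, a developmental log2
#' expression matrix with (donor, region, period, hemisphere) metadata, an
#' atlas-style (gene, structure, age, level) table, and a single-nucleus
#' dataset with donor random effects and planted differential expression —
#' so the complete pipeline is testable without any external download.
#' Pass/fail memberships are built in by construction and are exactly
#' recovered by the corresponding downstream filters. All output is a
#' deterministic function of the [sim_config()] (including its seed).
NULL

#' Deterministic gene namespace
#'
#' @param n number of symbols.
#' @return character vector `"G000001" ... `, collision-free and
#'   independent of any seed.
#' @export
gene_namespace <- function(n) {
  sprintf("G%06d", seq_len(n))
}

#' Simulation configuration
#'
#' @param seed integer RNG seed; identical configs give identical outputs.
#' @param n_genes number of genes in the simulated universe.
#' @param n_samples_per_period donors sampled per developmental period in
#'   the human expression matrix.
#' @param periods developmental periods simulated (integers within 1-15).
#' @param n_donors_per_group donors per diagnosis group in the
#'   single-nucleus dataset (default 5 vs 5, the matched case/control
#'   design).
#' @param n_cells_per_donor nuclei per donor (default 400).
#' @param n_clusters number of cell clusters (default 15).
#' @param planted_de data.frame of planted diagnosis effects with columns
#'   `gene`, `cluster` (`NA` = all clusters), `log2_effect` (continuous
#'   part, log2 units), `logit_effect` (detection part, logit units);
#'   `NULL` for a null dataset.
#' @param planted_markers data.frame of planted cluster-marker effects,
#'   columns `gene`, `cluster`, `log2_effect`, `logit_effect`.
#' @param donor_sd standard deviation of the per-donor random intercept,
#'   applied on the log2 scale (continuous part) and logit scale
#'   (detection part). Default 0.2, a typical between-individual effect for
#'   postmortem single-nucleus data.
#' @param dropout_base baseline probability that a gene is *not* detected
#'   in a cell (default 0.7, i.e. genes detected in ~30% of nuclei).
#' @param sigma residual standard deviation of the continuous part on the
#'   log2 scale (default 1.0).
#' @param both_hemispheres_frac fraction of human samples with both
#'   hemispheres measured (default 0.8); the rest alternate L/R
#'   deterministically.
#' @param universe universe size for symbol sampling in
#'   [gen_scored_genelists()] (default 20000).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_genes = 1000, n_samples_per_period = 6,
                       periods = 1:15, n_donors_per_group = 5,
                       n_cells_per_donor = 400, n_clusters = 15,
                       planted_de = NULL, planted_markers = NULL,
                       donor_sd = 0.2, dropout_base = 0.7, sigma = 1.0,
                       both_hemispheres_frac = 0.8, universe = 20000) {
  cfg <- list(seed = assert_count(seed, "seed", min = 0),
              n_genes = assert_count(n_genes, "n_genes"),
              n_samples_per_period = assert_count(n_samples_per_period,
                                                  "n_samples_per_period"),
              periods = vapply(periods, assert_count, 1L, name = "periods"),
              n_donors_per_group = assert_count(n_donors_per_group,
                                                "n_donors_per_group", min = 2),
              n_cells_per_donor = assert_count(n_cells_per_donor,
                                               "n_cells_per_donor"),
              n_clusters = assert_count(n_clusters, "n_clusters"),
              planted_de = planted_de, planted_markers = planted_markers,
              donor_sd = donor_sd, dropout_base = assert_prob(dropout_base,
                                                              "dropout_base"),
              sigma = sigma,
              both_hemispheres_frac = assert_prob(both_hemispheres_frac,
                                                  "both_hemispheres_frac"),
              universe = assert_count(universe, "universe"))
  if (any(cfg$periods < 1 | cfg$periods > 15))
    stop_validation("periods must lie in 1..15")
  if (cfg$donor_sd < 0) stop_validation("donor_sd must be non-negative")
  if (cfg$sigma < 0) stop_validation("sigma must be non-negative")
  structure(cfg, class = "sim_config")
}

with_sim_seed <- function(config, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((config$seed * 131L + offset) %% .Machine$integer.max)
  expr
}

#' Generate two scored gene lists with a controlled intersection
#'
#' Symbols are drawn from the deterministic namespace of
#' `config$universe` genes; each list is assigned evidence categories drawn
#' from `categories`. Exactly `overlap` symbols are shared.
#'
#' @param config a [sim_config()].
#' @param size_a,size_b list sizes (defaults 280 and 102, the sizes of the
#'   two source candidate lists).
#' @param overlap shared symbols (default 59); must satisfy
#'   `overlap <= min(size_a, size_b)` and
#'   `size_a + size_b - overlap <= universe`.
#' @param categories categories to sample from (default the
#'   high-confidence set S, 1, 2, 3).
#' @return list of two [scored_gene_list()]s, `a` and `b`.
#' @export
gen_scored_genelists <- function(config, size_a = 280, size_b = 102,
                                 overlap = 59,
                                 categories = c("S", "1", "2", "3")) {
  stopifnot(inherits(config, "sim_config"))
  size_a <- assert_count(size_a, "size_a"); size_b <- assert_count(size_b, "size_b")
  overlap <- assert_count(overlap, "overlap", min = 0)
  if (overlap > min(size_a, size_b))
    stop_validation("overlap (%d) exceeds min(size_a, size_b) = %d",
                    overlap, min(size_a, size_b))
  n_union <- size_a + size_b - overlap
  if (n_union > config$universe)
    stop_validation("union (%d) exceeds universe (%d)", n_union,
                    config$universe)
  with_sim_seed(config, 101L, {
    pool <- sample(gene_namespace(config$universe), n_union)
    shared <- pool[seq_len(overlap)]
    only_a <- pool[overlap + seq_len(size_a - overlap)]
    only_b <- pool[size_a + seq_len(size_b - overlap)]
    list(a = scored_gene_list(c(shared, only_a),
                              sample(categories, size_a, replace = TRUE),
                              name = "list_a"),
         b = scored_gene_list(c(shared, only_b),
                              sample(categories, size_b, replace = TRUE),
                              name = "list_b"))
  })
}

#' Generate a developmental expression matrix with a built-in pass set
#'
#' Genes in `pass_genes` receive one "qualifying" period (drawn inside
#' `pass_window` intersected with the configured periods) in which every
#' amygdala sample value lies well above the threshold, so the per-period
#' median after hemisphere averaging exceeds it; all other genes are kept
#' strictly below the threshold in every amygdala sample. A second region
#' (`NCX`) carries unconstrained values so region selection is exercised.
#' The first `both_hemispheres_frac` of each period's donors carry both
#' hemispheres; the rest alternate L/R deterministically.
#'
#' @param config a [sim_config()].
#' @param pass_genes character vector (or [gene_set()]) of genes that must
#'   pass the downstream filter; subset of the gene namespace.
#' @param threshold the log2 threshold the construction is anchored to
#'   (default 6.0).
#' @param pass_window periods within which the qualifying period is placed
#'   (default `c(2, 8)`).
#' @return a [dev_expression()] over `config$n_genes` genes.
#' @export
gen_dev_expression <- function(config, pass_genes, threshold = 6.0,
                               pass_window = c(2, 8)) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(pass_genes, "gene_set")) pass_genes <- pass_genes$symbols
  genes <- gene_namespace(config$n_genes)
  if (length(setdiff(pass_genes, genes)))
    stop_validation("pass_genes outside the gene namespace")
  qual_periods <- intersect(config$periods, seq(pass_window[1], pass_window[2]))
  if (length(pass_genes) && !length(qual_periods))
    stop_validation("no configured periods fall inside pass_window")

  with_sim_seed(config, 202L, {
    # sample sheet: per period x donor x region, 2 hemispheres for the
    # first both_hemispheres_frac donors, alternating single ones after
    meta <- list(); k <- 0L
    for (p in config$periods) {
      n_both <- ceiling(config$both_hemispheres_frac * config$n_samples_per_period)
      for (i in seq_len(config$n_samples_per_period)) {
        donor <- sprintf("HSB_p%02d_d%02d", p, i)
        hems <- if (i <= n_both) c("L", "R") else if (i %% 2 == 0) "L" else "R"
        for (reg in c("AMY", "NCX")) for (h in hems) {
          k <- k + 1L
          meta[[k]] <- data.frame(sample_id = sprintf("s%05d", k),
                                  region = reg, period = p, hemisphere = h,
                                  donor = donor)
        }
      }
    }
    meta <- do.call(rbind, meta)
    n_s <- nrow(meta)
    vals <- matrix(NA_real_, config$n_genes, n_s,
                   dimnames = list(genes, meta$sample_id))
    is_amy <- meta$region == "AMY"
    # non-qualifying background: strictly below threshold with margin
    vals[, !is_amy] <- runif(config$n_genes * sum(!is_amy), 4.0, 8.0)
    vals[, is_amy] <- runif(config$n_genes * sum(is_amy),
                            threshold - 1.6, threshold - 0.2)
    pass_idx <- match(pass_genes, genes)
    if (length(pass_idx)) {
      qual_period <- sample(rep(qual_periods, 2), length(pass_idx),
                            replace = TRUE)
      for (j in seq_along(pass_idx)) {
        cols <- is_amy & meta$period == qual_period[j]
        vals[pass_idx[j], cols] <- runif(sum(cols), threshold + 0.5,
                                         threshold + 1.8)
      }
    }
    dev_expression(vals, meta)
  })
}

#' Generate an atlas annotation table with built-in pass/fail structure
#'
#' Genes in `pass_genes` get at least one record with a qualifying
#' structure, a qualifying age and `level >= min_level`; genes in
#' `fail_genes` appear in the table but never qualify (alternating between
#' sub-threshold levels everywhere and high levels confined to
#' non-qualifying structures/ages); all other genes are absent (no data).
#' Levels stay inside the atlas scale \[-1.5, 3.5\].
#'
#' @param config a [sim_config()].
#' @param pass_genes,fail_genes character vectors or [gene_set()]s.
#' @param crit an [atlas_criteria()] the construction is anchored to.
#' @return an [atlas_table()].
#' @export
gen_atlas_table <- function(config, pass_genes, fail_genes = character(),
                            crit = atlas_criteria()) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(pass_genes, "gene_set")) pass_genes <- pass_genes$symbols
  if (inherits(fail_genes, "gene_set")) fail_genes <- fail_genes$symbols
  if (length(intersect(pass_genes, fail_genes)))
    stop_validation("pass_genes and fail_genes must be disjoint")
  decoy_structures <- c("Mb", "p1", "PPH")
  decoy_ages <- c("P14", "P28", "P56")
  with_sim_seed(config, 303L, {
    rows <- list()
    add <- function(g, s, a, lv) {
      rows[[length(rows) + 1L]] <<- data.frame(gene = g, structure = s,
                                               age = a, level = lv)
    }
    for (g in pass_genes) {
      add(g, sample(crit$structures, 1), sample(crit$ages, 1),
          runif(1, crit$min_level, 3.5))
      for (i in 1:2)
        add(g, sample(c(crit$structures, decoy_structures), 1),
            sample(c(crit$ages, decoy_ages), 1), runif(1, -1.5,
                                                       crit$min_level - 0.1))
    }
    for (j in seq_along(fail_genes)) {
      g <- fail_genes[j]
      if (j %% 2 == 1) {
        # present at qualifying structure/age but below the level threshold
        for (i in 1:3)
          add(g, sample(crit$structures, 1), sample(crit$ages, 1),
              runif(1, -1.5, crit$min_level - 0.1))
      } else {
        # high level, but only at non-qualifying structures or ages
        add(g, sample(decoy_structures, 1), sample(crit$ages, 1),
            runif(1, crit$min_level, 3.5))
        add(g, sample(crit$structures, 1), sample(decoy_ages, 1),
            runif(1, crit$min_level, 3.5))
      }
    }
    df <- do.call(rbind, rows)
    atlas_table(df$gene, df$structure, df$age, df$level)
  })
}

#' Generate a single-nucleus dataset with donor effects and planted DE
#'
#' Cells are simulated from the same two-part process the model assumes:
#' detection is Bernoulli with a logit linear in diagnosis (planted
#' `logit_effect`) plus a per-donor, per-gene random intercept of sd
#' `donor_sd`; conditional positive expression is Gaussian on the
#' log2(normalized) scale with mean linear in diagnosis (planted
#' `log2_effect`) plus the donor intercept, residual sd `sigma`. Genes
#' without planted effects have exactly zero diagnosis effect in both
#' parts. Donors are age- and sex-matched across groups; RIN and PMI are
#' donor-level nuisance covariates carried in the metadata (with zero
#' simulated effect by default).
#'
#' @param config a [sim_config()]; planted effects come from
#'   `config$planted_de` and `config$planted_markers`.
#' @param counts if `TRUE`, also back-transform to integer UMI counts
#'   (Poisson around the linear-scale means with per-cell depth factors)
#'   and return a [snuc_dataset()] under `$dataset` for end-to-end I/O
#'   testing. The direct log-scale matrix in `$values` is the fast default.
#' @return object of class `snuc_sim`: `values` (sparse gene x cell matrix
#'   on the normalized log2 scale), `cell_meta`, `config`, and optionally
#'   `dataset`.
#' @export
gen_snuc_dataset <- function(config, counts = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  nd <- config$n_donors_per_group
  genes <- gene_namespace(config$n_genes)
  with_sim_seed(config, 404L, {
    donors <- c(sprintf("ASD%02d", seq_len(nd)), sprintf("CTL%02d", seq_len(nd)))
    diagnosis <- rep(c("ASD", "control"), each = nd)
    pair_age <- round(seq(4, 20, length.out = nd), 1)
    pair_sex <- rep(c("M", "F"), length.out = nd)
    donor_meta <- data.frame(donor = donors, diagnosis = diagnosis,
                             age = rep(pair_age, 2), sex = rep(pair_sex, 2),
                             RIN = round(rnorm(2 * nd, 7.5, 0.5), 2),
                             PMI = round(pmax(rnorm(2 * nd, 15, 4), 5), 1))
    n_cells <- 2 * nd * config$n_cells_per_donor
    cell_donor <- rep(donors, each = config$n_cells_per_donor)
    cluster <- rep_len(seq_len(config$n_clusters), n_cells)
    cell_meta <- donor_meta[match(cell_donor, donor_meta$donor), ]
    cell_meta$cell_id <- sprintf("cell%06d", seq_len(n_cells))
    cell_meta$cluster <- cluster
    rownames(cell_meta) <- NULL
    cell_meta <- cell_meta[, c("cell_id", "donor", "diagnosis", "cluster",
                               "age", "sex", "RIN", "PMI")]

    is_asd <- cell_meta$diagnosis == "ASD"
    donor_idx <- match(cell_meta$donor, donors)
    base_logit <- qlogis(1 - config$dropout_base) +
      rnorm(config$n_genes, 0, 0.5)
    base_mu <- runif(config$n_genes, 1, 3)

    pde <- config$planted_de
    pmk <- config$planted_markers
    rows <- vector("list", config$n_genes)
    for (g in seq_len(config$n_genes)) {
      b_det <- rnorm(2 * nd, 0, config$donor_sd)[donor_idx]
      b_cont <- rnorm(2 * nd, 0, config$donor_sd)[donor_idx]
      eta <- base_logit[g] + b_det
      mu <- base_mu[g] + b_cont
      if (!is.null(pde)) {
        hits <- pde[pde$gene == genes[g], , drop = FALSE]
        for (h in seq_len(nrow(hits))) {
          in_cl <- if (is.na(hits$cluster[h])) rep(TRUE, n_cells)
                   else cell_meta$cluster == hits$cluster[h]
          w <- is_asd & in_cl
          eta[w] <- eta[w] + hits$logit_effect[h]
          mu[w] <- mu[w] + hits$log2_effect[h]
        }
      }
      if (!is.null(pmk)) {
        hits <- pmk[pmk$gene == genes[g], , drop = FALSE]
        for (h in seq_len(nrow(hits))) {
          w <- cell_meta$cluster == hits$cluster[h]
          eta[w] <- eta[w] + hits$logit_effect[h]
          mu[w] <- mu[w] + hits$log2_effect[h]
        }
      }
      z <- rbinom(n_cells, 1, plogis(eta))
      y <- numeric(n_cells)
      npos <- sum(z)
      if (npos)
        y[z == 1] <- pmax(rnorm(npos, mu[z == 1], config$sigma), 0.01)
      rows[[g]] <- y
    }
    values <- as(Matrix::Matrix(do.call(rbind, rows), sparse = TRUE,
                                dimnames = list(genes, cell_meta$cell_id)),
                 "CsparseMatrix")
    out <- structure(list(values = values, cell_meta = cell_meta,
                          config = config),
                     class = "snuc_sim")
    if (counts) {
      depth <- exp(rnorm(n_cells, 0, 0.3))
      lambda <- t(t(as.matrix(2^values - 1) * 3) * depth)
      cts <- matrix(rpois(length(lambda), lambda), nrow(lambda),
                    dimnames = dimnames(values))
      out$dataset <- snuc_dataset(Matrix::Matrix(cts, sparse = TRUE),
                                  cell_meta)
    }
    out
  })
}

#' @export
print.snuc_sim <- function(x, ...) {
  cat(sprintf("<snuc_sim: %d genes x %d cells, %d planted DE effects%s>\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$config$planted_de)) 0L else nrow(x$config$planted_de),
              if (is.null(x$dataset)) "" else "; counts attached"))
  invisible(x)
}
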