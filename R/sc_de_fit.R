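#' @title Hurdle-model fitting for single-nucleus differential expression
#' @name sc_de_fit
#' @description
#' Expression of a gene across nuclei is modeled in two parts: a logistic
#' regression for whether the gene is detected (normalized value > 0), and a
#' Gaussian linear model for the normalized level conditional on detection.
#' Both parts carry the same fixed covariates (diagnosis, age, sex, RIN,
#' PMI) and a per-donor random intercept that accounts for many nuclei being
#' captured from each individual. Diagnosis is tested by a likelihood-ratio
#' test against the nested model without the diagnosis term, summing the
#' statistic over whichever hurdle components are actually fitted.
NULL

#' Construct a single-nucleus dataset
#'
#' @param counts gene x cell matrix of non-negative integer UMI counts;
#'   dense or sparse (coerced to `dgCMatrix`). Needs gene rownames and cell
#'   colnames.
#' @param cell_meta data.frame with one row per cell: `cell_id`, `donor`,
#'   `diagnosis` (`"ASD"` or `"control"`), `cluster`, and covariates `age`
#'   (years), `sex`, `RIN`, `PMI` (hours).
#' @return object of class `snuc_dataset`.
#' @export
snuc_dataset <- function(counts, cell_meta) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_validation("counts must have gene rownames and cell colnames")
  x <- counts@x
  if (any(x < 0) || any(x != floor(x)))
    stop_validation("counts must be non-negative integers")
  req <- c("cell_id", "donor", "diagnosis", "cluster")
  miss <- setdiff(req, names(cell_meta))
  if (length(miss))
    stop_validation("cell_meta missing columns: %s", paste(miss, collapse = ", "))
  cell_meta <- as.data.frame(cell_meta)
  if (!identical(sort(colnames(counts)), sort(as.character(cell_meta$cell_id))))
    stop_validation("colnames(counts) must match cell_meta$cell_id")
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$cell_id), ]
  if (any(is.na(cell_meta$donor)) || any(is.na(cell_meta$diagnosis)) ||
      any(is.na(cell_meta$cluster)))
    stop_validation("every cell needs a donor, diagnosis and cluster")
  bad <- setdiff(unique(as.character(cell_meta$diagnosis)), c("ASD", "control"))
  if (length(bad))
    stop_validation("diagnosis values must be 'ASD' or 'control' (got %s)",
                    paste(bad, collapse = ", "))
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "snuc_dataset")
}

#' @export
print.snuc_dataset <- function(x, ...) {
  cat(sprintf(
    "<snuc_dataset: %d genes x %d cells; %d donors (%d ASD / %d control); %d clusters>\n",
    nrow(x$counts), ncol(x$counts),
    length(unique(x$cell_meta$donor)),
    length(unique(x$cell_meta$donor[x$cell_meta$diagnosis == "ASD"])),
    length(unique(x$cell_meta$donor[x$cell_meta$diagnosis == "control"])),
    length(unique(x$cell_meta$cluster))))
  invisible(x)
}

#' Library-size normalize UMI counts
#'
#' `value = log2(1 + count * scale_factor / cell_total)`. Zeros stay exactly
#' zero, so the sparsity pattern is preserved; doubling every count of a
#' cell leaves its normalized values unchanged. Cells with zero total count
#' have no defined normalization and are dropped with a warning.
#'
#' @param d a [snuc_dataset()].
#' @param scale_factor pseudo library size (default 10000).
#' @return object of class `normalized_matrix`: list with `values` (sparse
#'   gene x cell matrix), `cell_meta`, `scale_factor`.
#' @export
normalize_counts <- function(d, scale_factor = 10000) {
  stopifnot(inherits(d, "snuc_dataset"))
  scale_factor <- assert_count(scale_factor, "scale_factor")
  totals <- Matrix::colSums(d$counts)
  keep <- totals > 0
  if (any(!keep))
    warning(sprintf("dropping %d cells with zero total UMI count", sum(!keep)))
  m <- d$counts[, keep, drop = FALSE]
  totals <- totals[keep]
  v <- as(m, "CsparseMatrix")
  # per-column scaling on the non-zero entries only
  col_of <- rep.int(seq_len(ncol(v)), diff(v@p))
  v@x <- log2(1 + v@x * (scale_factor / totals[col_of]))
  structure(list(values = v,
                 cell_meta = d$cell_meta[keep, , drop = FALSE],
                 scale_factor = scale_factor),
            class = "normalized_matrix")
}

#' Hurdle model specification
#'
#' @param covariates fixed-effect covariates beyond diagnosis; numeric ones
#'   are centered and scaled before fitting, factors are used as-is.
#'   Covariates that are constant in the data at hand are dropped.
#' @param random grouping factor for the random intercept (default
#'   `"donor"`); set to `NULL` for a fixed-effects-only model.
#' @param simplified if `TRUE`, drop all covariates and keep only diagnosis
#'   (plus the random intercept) — the simplified model used as a second
#'   fold-change gate.
#' @param nAGQ integration accuracy for the logistic mixed fit (passed to
#'   [lme4::glmer()]; 0 = fast penalized-likelihood approximation, the
#'   default; 1 = Laplace).
#' @param min_pos minimum number of detected (positive) cells required to
#'   fit the continuous part (default 5).
#' @return list of class `hurdle_spec`.
#' @export
hurdle_spec <- function(covariates = c("age", "sex", "RIN", "PMI"),
                        random = "donor", simplified = FALSE, nAGQ = 0,
                        min_pos = 5) {
  structure(list(covariates = if (simplified) character() else covariates,
                 random = random, simplified = simplified,
                 nAGQ = nAGQ, min_pos = min_pos),
            class = "hurdle_spec")
}

# Center/scale numeric covariates, factor-code the rest; drop constants.
# Returns the data plus the names of usable covariates.
prep_model_data <- function(meta, spec) {
  df <- data.frame(row.names = seq_len(nrow(meta)))
  df$diagnosis <- factor(as.character(meta$diagnosis),
                         levels = c("control", "ASD"))
  if (!is.null(spec$random)) df$.grp <- factor(meta[[spec$random]])
  usable <- character()
  for (cv in spec$covariates) {
    v <- meta[[cv]]
    if (is.null(v)) next
    if (is.numeric(v)) {
      s <- sd(v)
      if (!is.finite(s) || s == 0) next
      df[[cv]] <- (v - mean(v)) / s
    } else {
      v <- factor(v)
      if (nlevels(droplevels(v)) < 2) next
      df[[cv]] <- droplevels(v)
    }
    usable <- c(usable, cv)
  }
  list(data = df, covariates = usable)
}

# Fit a nested pair (full with diagnosis, reduced without) for one hurdle
# part. Mixed fits that error out (or give non-finite likelihoods) trigger a
# joint fallback: BOTH models are refit without the random intercept so the
# two likelihoods stay comparable.
fit_part_pair <- function(data, covariates, family, spec) {
  rhs_red <- paste(c("1", covariates), collapse = " + ")
  rhs_full <- paste(c("diagnosis", covariates), collapse = " + ")
  gaussian_part <- identical(family, "gaussian")
  use_mixed <- !is.null(spec$random) && nlevels(droplevels(data$.grp)) >= 2

  fit_one <- function(rhs, mixed) {
    f <- as.formula(paste("y ~", rhs, if (mixed) "+ (1 | .grp)" else ""))
    if (mixed && gaussian_part)
      lme4::lmer(f, data = data, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))
    else if (mixed)
      lme4::glmer(f, data = data, family = binomial(), nAGQ = spec$nAGQ,
                  control = lme4::glmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore"))
    else if (gaussian_part) lm(f, data = data)
    else suppressWarnings(glm(f, data = data, family = binomial()))
  }
  try_pair <- function(mixed) {
    full <- tryCatch(fit_one(rhs_full, mixed), error = function(e) NULL)
    red <- tryCatch(fit_one(rhs_red, mixed), error = function(e) NULL)
    ok <- !is.null(full) && !is.null(red) &&
      is.finite(as.numeric(logLik(full))) &&
      is.finite(as.numeric(logLik(red)))
    if (ok) list(full = full, reduced = red) else NULL
  }
  pair <- if (use_mixed) try_pair(TRUE) else NULL
  status <- if (!is.null(pair)) "mixed" else NA_character_
  if (is.null(pair)) {
    pair <- try_pair(FALSE)
    status <- if (!is.null(pair)) {
      if (use_mixed) "fixed_fallback" else "fixed"
    } else "failed"
  }
  if (identical(status, "failed")) return(list(status = "failed"))
  coefs <- function(m) if (is(m, "merMod")) lme4::fixef(m) else coef(m)
  cf <- coefs(pair$full)
  list(status = status, full = pair$full, reduced = pair$reduced,
       logLik_full = as.numeric(logLik(pair$full)),
       logLik_reduced = as.numeric(logLik(pair$reduced)),
       intercept = unname(cf["(Intercept)"]),
       coef_diag = unname(cf["diagnosisASD"]))
}

#' Fit the two-part hurdle model for one gene
#'
#' Fits full (with diagnosis) and reduced (without) models for the
#' detection part (logistic, on the indicator `y > 0`) and the continuous
#' part (Gaussian, on the positive values), each with a donor random
#' intercept. Degenerate parts are dropped: the detection part when the
#' gene is detected in all or no cells, the continuous part when fewer than
#' `spec$min_pos` positive values (or no variation) remain. Mixed fits that
#' fail fall back to fixed-effects-only fits for *both* members of the
#' nested pair (`fit_status = "fixed_fallback"`); likelihoods from
#' different fitting families are never compared.
#'
#' @param y numeric vector of normalized expression values for one gene
#'   (one entry per cell).
#' @param meta cell metadata data.frame aligned with `y` (columns
#'   `diagnosis`, the random grouping, and the spec covariates).
#' @param spec a [hurdle_spec()].
#' @return object of class `hurdle_fit`: parts `discrete` and `continuous`
#'   (each with fits, log-likelihoods, diagnosis coefficient, status),
#'   overall `fit_status` (`"mixed"`, `"fixed_fallback"`, `"fixed"` or
#'   `"failed"`), `df` (number of diagnosis parameters across fitted
#'   parts), `n_cells`, `n_pos`, `detect_rate`.
#' @export
fit_hurdle <- function(y, meta, spec = hurdle_spec()) {
  stopifnot(length(y) == nrow(meta))
  res <- structure(list(discrete = NULL, continuous = NULL,
                        fit_status = "failed", df = 0L,
                        n_cells = length(y), n_pos = sum(y > 0),
                        detect_rate = mean(y > 0)),
                   class = "hurdle_fit")
  dpg <- table(unique(data.frame(d = meta$donor, g = meta$diagnosis))$g)
  if (length(dpg) < 2 || any(dpg < 2)) {
    attr(res, "reason") <- "fewer than 2 donors per diagnosis group"
    return(res)
  }
  pd <- prep_model_data(meta, spec)
  z <- as.integer(y > 0)

  parts <- list(); statuses <- character()
  if (any(z == 1) && any(z == 0)) {
    dat <- pd$data; dat$y <- z
    parts$discrete <- fit_part_pair(dat, pd$covariates, "binomial", spec)
  }
  pos <- which(z == 1)
  if (length(pos) >= spec$min_pos && sd(y[pos]) > 0 &&
      length(unique(pd$data$diagnosis[pos])) == 2) {
    dat <- pd$data[pos, , drop = FALSE]
    dat$y <- y[pos]
    parts$continuous <- fit_part_pair(dat, pd$covariates, "gaussian", spec)
  }
  parts <- Filter(function(p) !identical(p$status, "failed"), parts)
  if (!length(parts)) {
    attr(res, "reason") <- "no fittable hurdle component"
    return(res)
  }
  statuses <- vapply(parts, `[[`, "", "status")
  res$discrete <- parts$discrete
  res$continuous <- parts$continuous
  res$fit_status <- if (any(statuses == "fixed_fallback")) "fixed_fallback"
                    else statuses[[1]]
  res$df <- length(parts)  # one diagnosis parameter per fitted component
  res
}

#' Likelihood-ratio test for the diagnosis term
#'
#' `stat = 2 * (logLik_full - logLik_reduced)`, summed over the hurdle
#' components actually fitted; `df` is the number of diagnosis parameters
#' removed (2 when both components are present, 1 for a single-component
#' gene); p from the upper tail of the chi-square distribution. Identical
#' likelihoods give stat 0 and p = 1.
#'
#' @param fit a [fit_hurdle()] result.
#' @return list `lrt_stat`, `df`, `p_value`.
#' @export
lrt_diagnosis <- function(fit) {
  stopifnot(inherits(fit, "hurdle_fit"))
  if (fit$fit_status == "failed" || fit$df == 0L)
    return(list(lrt_stat = NA_real_, df = 0L, p_value = NA_real_))
  parts <- Filter(Negate(is.null), list(fit$discrete, fit$continuous))
  stat <- sum(vapply(parts, function(p) {
    2 * (p$logLik_full - p$logLik_reduced)
  }, 1.0))
  stat <- max(stat, 0)  # optimizer jitter can leave tiny negatives
  list(lrt_stat = stat, df = fit$df,
       p_value = pchisq(stat, df = fit$df, lower.tail = FALSE))
}

# Model-predicted mean normalized expression for one diagnosis group,
# covariates at their (centered) means and random effects at zero:
# P(detected) * E[level | detected].
predicted_mean <- function(fit, group = c("control", "ASD")) {
  group <- match.arg(group)
  d <- if (group == "ASD") 1 else 0
  p_det <- if (!is.null(fit$discrete)) {
    plogis(fit$discrete$intercept + d * fit$discrete$coef_diag)
  } else if (fit$detect_rate == 1) 1 else fit$detect_rate
  mu <- if (!is.null(fit$continuous)) {
    fit$continuous$intercept + d * fit$continuous$coef_diag
  } else if (fit$n_pos == 0) 0 else NA_real_
  if (fit$n_pos == 0) return(0)
  p_det * mu
}

#' Model-based fold change between diagnosis groups
#'
#' The expected normalized expression (detection probability times
#' conditional mean, covariates at reference values, random effects at
#' zero) is computed for each diagnosis group; `log2_fc` is their
#' difference (the normalized scale is log2, so a difference of predicted
#' means is a log2 fold change) and `pct_change = 2^log2_fc - 1` expresses
#' it as a linear-scale fractional change.
#'
#' @param fit a [fit_hurdle()] result (full covariate model or simplified
#'   diagnosis-only model).
#' @return list `log2_fc`, `pct_change`; `NA`s for failed fits.
#' @export
fold_change <- function(fit) {
  stopifnot(inherits(fit, "hurdle_fit"))
  if (fit$fit_status == "failed")
    return(list(log2_fc = NA_real_, pct_change = NA_real_))
  m1 <- predicted_mean(fit, "ASD")
  m0 <- predicted_mean(fit, "control")
  if (!is.finite(m1) || !is.finite(m0))
    return(list(log2_fc = NA_real_, pct_change = NA_real_))
  lfc <- m1 - m0
  list(log2_fc = lfc, pct_change = 2^lfc - 1)
}
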