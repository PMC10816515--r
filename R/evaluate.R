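# Performance evaluation: Mann-Whitney AUC with stratified bootstrap CIs,
# covariate-adjusted AUC via placement values, threshold confusion metrics,
# Spearman concordance, clr-PCA with out-of-sample projection, and
# Procrustes comparison of ordinations.

as_case_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) abort("Numeric labels must be 0/1.")
    return(labels == 1)
  }
  lv <- unique(labels)
  if (length(lv) > 2) abort("Labels must be binary.")
  # conventional positive-class spellings
  pos <- intersect(c("case", "CRC", "cancer", "1", "TRUE"), lv)
  if (length(pos) == 0) pos <- sort(lv)[length(lv)]
  labels %in% pos
}

auc_point <- function(scores, case) {
  r <- rank(scores) # midranks handle ties as half-concordant
  n1 <- sum(case)
  n0 <- sum(!case)
  (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with stratified bootstrap confidence interval
#'
#' The Mann-Whitney AUC, `P(score_case > score_control) + P(tie)/2`, with a
#' percentile confidence interval from class-stratified bootstrap resamples.
#'
#' @param scores Numeric scores or probabilities.
#' @param labels Binary labels (`case`/`control`, logical, 0/1, or factor);
#'   both classes must be present.
#' @param n_boot Number of bootstrap resamples (default 2000; 0 skips the
#'   CI).
#' @param seed Optional integer seed for the bootstrap.
#' @param conf_level CI coverage (default 0.95).
#' @return A `roc_result` object (see [glance.roc_result()]).
#' @export
roc_auc <- function(scores, labels, n_boot = 2000, seed = NULL,
                    conf_level = 0.95) {
  case <- as_case_logical(labels)
  if (length(scores) != length(case)) abort("scores/labels length mismatch.")
  if (all(case) || !any(case)) abort("Both classes must be present.")
  est <- auc_point(scores, case)
  ci <- c(NA_real_, NA_real_)
  boot <- numeric(0)
  if (n_boot > 0) {
    local_seed_if(seed)
    i1 <- which(case)
    i0 <- which(!case)
    boot <- vapply(seq_len(n_boot), function(b) {
      j <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
      auc_point(scores[j], case[j])
    }, numeric(1))
    alpha <- (1 - conf_level) / 2
    ci <- unname(quantile(boot, c(alpha, 1 - alpha), type = 7))
  }
  structure(
    list(auc = est, ci_low = ci[1], ci_high = ci[2], n_boot = n_boot,
         conf_level = conf_level, n_case = sum(case), n_control = sum(!case),
         method = "mann-whitney", scores = scores, case = case,
         boot_auc = boot, seed = seed),
    class = "roc_result"
  )
}

#' Covariate-adjusted AUC via placement values
#'
#' Adjusts the AUC for covariates that differ between the compared groups:
#' a linear location model of the score on the covariates is fitted among
#' controls; each case's placement value is the proportion of control
#' residuals below its own residual (ties counted half); the adjusted AUC is
#' the mean placement value. The bootstrap refits the covariate model in
#' every class-stratified resample.
#'
#' @inheritParams roc_auc
#' @param covariates Data frame of numeric covariates (e.g. sex, age, BMI),
#'   one row per sample, no `sample_id` needed (row order must match
#'   `scores`). Constant columns are dropped with a warning.
#' @return A `roc_result` with `method = "placement-adjusted"`.
#' @export
adjusted_auc <- function(scores, labels, covariates, n_boot = 2000,
                         seed = NULL, conf_level = 0.95) {
  case <- as_case_logical(labels)
  if (all(case) || !any(case)) abort("Both classes must be present.")
  covariates <- as.data.frame(covariates)
  covariates <- covariates[setdiff(names(covariates), "sample_id")]
  if (nrow(covariates) != length(scores)) {
    abort("covariates must have one row per sample.")
  }
  keep <- vapply(covariates, function(v) length(unique(v)) > 1, logical(1))
  if (!all(keep)) {
    warn(paste0("Dropping constant covariate(s): ",
                paste(names(covariates)[!keep], collapse = ", ")))
    covariates <- covariates[keep]
  }
  if (ncol(covariates) == 0) {
    warn("No usable covariates; falling back to the unadjusted AUC.")
    return(roc_auc(scores, labels, n_boot = n_boot, seed = seed,
                   conf_level = conf_level))
  }

  adj_point <- function(sc, cs, cov) {
    dat <- cbind(data.frame(.score = sc), cov)
    fit <- lm(.score ~ ., data = dat[!cs, , drop = FALSE])
    res <- sc - predict(fit, newdata = dat)
    r0 <- res[!cs]
    pv <- vapply(res[cs], function(r) {
      (sum(r0 < r) + 0.5 * sum(r0 == r)) / length(r0)
    }, numeric(1))
    mean(pv)
  }

  est <- adj_point(scores, case, covariates)
  ci <- c(NA_real_, NA_real_)
  boot <- numeric(0)
  if (n_boot > 0) {
    local_seed_if(seed)
    i1 <- which(case)
    i0 <- which(!case)
    boot <- vapply(seq_len(n_boot), function(b) {
      j <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
      adj_point(scores[j], case[j], covariates[j, , drop = FALSE])
    }, numeric(1))
    alpha <- (1 - conf_level) / 2
    ci <- unname(quantile(boot, c(alpha, 1 - alpha), type = 7))
  }
  structure(
    list(auc = est, ci_low = ci[1], ci_high = ci[2], n_boot = n_boot,
         conf_level = conf_level, n_case = sum(case), n_control = sum(!case),
         method = "placement-adjusted", scores = scores, case = case,
         boot_auc = boot, seed = seed),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f", x$auc))
  if (x$n_boot > 0) {
    cat(sprintf(" (%.0f%% CI %.3f-%.3f, %d bootstrap resamples)",
                100 * x$conf_level, x$ci_low, x$ci_high, x$n_boot))
  }
  cat(sprintf(" [%s; %d cases / %d controls]\n",
              x$method, x$n_case, x$n_control))
  invisible(x)
}

#' Confusion metrics at a probability threshold
#'
#' @param p Probability vector.
#' @param labels Binary labels; both classes present.
#' @param threshold Decision threshold (default 0.33).
#' @return One-row tibble: `threshold`, `tp`, `fp`, `tn`, `fn`,
#'   `specificity`, `sensitivity`, `precision` (`NA` with a message when
#'   nothing is predicted positive).
#' @export
confusion_at_threshold <- function(p, labels, threshold = 0.33) {
  case <- as_case_logical(labels)
  if (all(case) || !any(case)) abort("Both classes must be present.")
  pred <- p >= threshold
  tp <- sum(pred & case); fp <- sum(pred & !case)
  tn <- sum(!pred & !case); fn <- sum(!pred & case)
  prec <- if (tp + fp == 0) {
    inform("No sample predicted positive; precision undefined.")
    NA_real_
  } else {
    tp / (tp + fp)
  }
  tibble::tibble(
    threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
    specificity = tn / (tn + fp),
    sensitivity = tp / (tp + fn),
    precision = prec
  )
}

#' Spearman rank concordance between two paired score vectors
#'
#' @param a,b Paired numeric vectors, `n >= 3`; ties take average ranks.
#' @return Spearman's rho (`NA` with a warning for constant input).
#' @export
spearman_concordance <- function(a, b) {
  if (length(a) != length(b)) abort("Vectors must be paired.")
  if (length(a) < 3) abort("Need at least 3 pairs.")
  if (length(unique(a)) == 1 || length(unique(b)) == 1) {
    warn("Constant vector: Spearman's rho is undefined.")
    return(NA_real_)
  }
  cor(a, b, method = "spearman")
}

#' PCA of a clr matrix
#'
#' Principal components of the column-centred clr matrix via singular value
#' decomposition ([stats::prcomp()]), with no per-taxon scaling: clr
#' coordinates already share a log scale.
#'
#' @param clr Wide clr table; at least 2 samples and 2 taxa.
#' @return A `clr_pca` object: `scores` tibble, `loadings` matrix, `center`,
#'   `explained` (variance fractions, non-increasing).
#' @export
clr_pca <- function(clr) {
  X <- as_abundance_matrix(clr, "clr")
  if (nrow(X) < 2 || ncol(X) < 2) abort("Need at least 2 samples and 2 taxa.")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      scores = tibble::as_tibble(pc$x, rownames = "sample_id"),
      loadings = pc$rotation,
      center = pc$center,
      explained = expl
    ),
    class = "clr_pca"
  )
}

#' @export
print.clr_pca <- function(x, ...) {
  cat("<clr_pca>", nrow(x$scores), "samples,", nrow(x$loadings), "taxa;",
      sprintf("PC1 %.1f%%, PC2 %.1f%%\n",
              100 * x$explained[1], 100 * x$explained[2]))
  invisible(x)
}

#' Project new samples onto an existing clr-PCA
#'
#' Centres the new clr rows with the training column means and applies the
#' training loadings. Projecting the training data reproduces its scores.
#'
#' @param pca A `clr_pca`.
#' @param new Wide clr table covering the PCA's taxon set.
#' @return Tibble of projected scores with `sample_id`.
#' @export
project_samples <- function(pca, new) {
  stopifnot(inherits(pca, "clr_pca"))
  X <- as_abundance_matrix(new, "new")
  taxa <- rownames(pca$loadings)
  missing <- setdiff(taxa, colnames(X))
  if (length(missing) > 0) {
    abort(paste0("New data lacks PCA taxa: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  S <- sweep(X[, taxa, drop = FALSE], 2, pca$center) %*% pca$loadings
  tibble::as_tibble(S, rownames = "sample_id")
}

score_matrix <- function(x, dims) {
  if (inherits(x, "clr_pca")) x <- x$scores
  m <- as_abundance_matrix(x, "scores")
  if (!is.null(dims)) m <- m[, seq_len(dims), drop = FALSE]
  m
}

#' Procrustes comparison of two ordinations
#'
#' Finds the translation, uniform scaling and orthogonal rotation of `y`
#' that best matches `x` (symmetric scaling: both configurations normalized
#' to unit sum of squares), and reports the minimized residual sum of
#' squares m12², the Procrustes correlation `r = sqrt(1 - m12²)`, and a
#' permutation p-value (protest). Delegates to [vegan::protest()].
#'
#' @param x,y Score tables (`sample_id` + coordinate columns), `clr_pca`
#'   objects, or matrices over the same samples.
#' @param dims Number of leading dimensions to compare (default 2).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed for the permutation test.
#' @return One-row tibble: `m12_squared`, `correlation`, `p_value`,
#'   `n_perm`, `n_samples`, `dims`.
#' @export
procrustes_compare <- function(x, y, dims = 2, n_perm = 999, seed = NULL) {
  X <- score_matrix(x, dims)
  Y <- score_matrix(y, dims)
  al <- align_paired_samples(X, Y)
  X <- al$a; Y <- al$b
  if (nrow(X) <= ncol(X)) {
    abort("Need more samples than dimensions for a Procrustes fit.")
  }
  local_seed_if(seed)
  pr <- vegan::protest(X, Y, permutations = n_perm)
  tibble::tibble(
    m12_squared = unname(pr$ss),
    correlation = unname(pr$t0),
    p_value = unname(pr$signif),
    n_perm = n_perm,
    n_samples = nrow(X),
    dims = ncol(X)
  )
}
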