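# broom-style tidiers and ggplot2 autoplot methods for the package's
# result objects.

#' Tidy a signature model
#'
#' @param x A `signature_model`.
#' @param ... Unused.
#' @return Tibble of terms: intercept, taxa, covariates.
#' @method tidy signature_model
#' @export
tidy.signature_model <- function(x, ...) {
  out <- tibble::tibble(term = "(Intercept)", type = "intercept",
                        estimate = x$intercept)
  out <- dplyr::bind_rows(
    out,
    tibble::tibble(term = x$taxa$name, type = "taxon", estimate = x$taxa$coef)
  )
  if (!is.null(x$covariates) && nrow(x$covariates) > 0) {
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(term = x$covariates$name, type = "covariate",
                     estimate = x$covariates$coef)
    )
  }
  out
}

#' One-row summary of a signature model
#'
#' @inheritParams tidy.signature_model
#' @return Tibble: `n_taxa`, `n_covariates`, `intercept`, `threshold`.
#' @method glance signature_model
#' @export
glance.signature_model <- function(x, ...) {
  tibble::tibble(
    n_taxa = nrow(x$taxa),
    n_covariates = if (is.null(x$covariates)) 0L else nrow(x$covariates),
    intercept = x$intercept,
    threshold = x$threshold
  )
}

#' One-row summary of an AUC result
#'
#' @param x A `roc_result` from [roc_auc()] or [adjusted_auc()].
#' @param ... Unused.
#' @return Tibble: `auc`, `ci_low`, `ci_high`, `n_boot`, `conf_level`,
#'   `n_case`, `n_control`, `method`.
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
    n_boot = x$n_boot, conf_level = x$conf_level,
    n_case = x$n_case, n_control = x$n_control, method = x$method
  )
}

#' ROC curve coordinates
#'
#' @inheritParams glance.roc_result
#' @return Tibble of `threshold`, `fpr`, `tpr`, ordered along the curve.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) {
  th <- c(Inf, sort(unique(x$scores), decreasing = TRUE), -Inf)
  coords <- purrr::map(th, function(t) {
    pred <- x$scores >= t
    tibble::tibble(
      threshold = t,
      fpr = sum(pred & !x$case) / sum(!x$case),
      tpr = sum(pred & x$case) / sum(x$case)
    )
  })
  dplyr::bind_rows(coords)
}

#' Tidy PCA scores
#'
#' @param x A `clr_pca`.
#' @param ... Unused.
#' @return Score tibble (`sample_id` + components).
#' @method tidy clr_pca
#' @export
tidy.clr_pca <- function(x, ...) {
  x$scores
}

#' Explained-variance summary of a clr-PCA
#'
#' @inheritParams tidy.clr_pca
#' @return Tibble: `component`, `explained_variance_fraction`.
#' @method glance clr_pca
#' @export
glance.clr_pca <- function(x, ...) {
  tibble::tibble(
    component = paste0("PC", seq_along(x$explained)),
    explained_variance_fraction = x$explained
  )
}

#' Plot a clr-PCA ordination
#'
#' @param object A `clr_pca`.
#' @param data Optional data frame with `sample_id` and a grouping column to
#'   colour by.
#' @param colour Name of the grouping column in `data`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot clr_pca
#' @export
autoplot.clr_pca <- function(object, data = NULL, colour = "group", ...) {
  df <- object$scores
  mapping <- ggplot2::aes(x = .data$PC1, y = .data$PC2)
  if (!is.null(data) && colour %in% names(data)) {
    df <- dplyr::left_join(df, data[, c("sample_id", colour)], by = "sample_id")
    mapping <- ggplot2::aes(x = .data$PC1, y = .data$PC2,
                            colour = .data[[colour]])
  }
  ggplot2::ggplot(df, mapping) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("AUC = %.3f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot mapping distances per signature taxon
#'
#' Bar height is the clr-profile distance between each shotgun signature
#' taxon and its mapped 16S partner; taxa whose partner is also the
#' absolute minimum over all 16S taxa are starred.
#'
#' @param object A `taxon_mapping`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot taxon_mapping
#' @export
autoplot.taxon_mapping <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- ifelse(df$absolute_min, paste0(df$shotgun_taxon, " *"),
                     df$shotgun_taxon)
  df$label <- stats::reorder(df$label, df$distance)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, y = .data$label,
                                   fill = .data$matched_rank)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "clr profile distance to mapped 16S taxon", y = NULL,
                  fill = "matched rank",
                  caption = "* distance is the absolute minimum over all 16S taxa") +
    ggplot2::theme_minimal()
}

#' Plot signature-taxon importance
#'
#' @param importance Output of [signature_importance()].
#' @return A ggplot, taxa ordered by importance magnitude, signed bars
#'   coloured by enrichment direction.
#' @export
plot_importance <- function(importance) {
  df <- importance
  df$taxon <- stats::reorder(df$taxon, abs(df$importance))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$taxon,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "coefficient x |mean clr abundance|", y = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}
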