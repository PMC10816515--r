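# Linear microbial-signature models (Lasso-style logistic): JSON I/O,
# prediction on clr features from either technology via a taxon mapping,
# classification at a probability threshold, and Fig-style importance.

#' Construct a signature model
#'
#' A fitted penalized logistic model reduced to what prediction needs: the
#' intercept, the per-taxon linear coefficients on clr features, optional
#' covariate coefficients, a decision threshold, and optional feature
#' scaling metadata (centre/scale applied to clr features before the linear
#' predictor, for models fitted on standardized features).
#'
#' @param intercept Scalar intercept.
#' @param taxa Data frame with columns `name`, `coef`.
#' @param covariates Optional data frame with columns `name`, `coef` and
#'   optionally `reference` (for factor covariates such as a study
#'   indicator: the coefficient applies when the value differs from the
#'   reference, and samples at — or without — the reference level
#'   contribute 0).
#' @param threshold Decision threshold in (0, 1); default 0.33.
#' @param scaling Optional list with named numeric vectors `center` and/or
#'   `scale`.
#' @return A `signature_model` object.
#' @export
signature_model <- function(intercept, taxa, covariates = NULL,
                            threshold = 0.33, scaling = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1)
  taxa <- tibble::as_tibble(taxa)
  stopifnot(all(c("name", "coef") %in% names(taxa)))
  if (anyDuplicated(taxa$name)) abort("Duplicated taxon names in the model.")
  if (!(threshold > 0 && threshold < 1)) {
    abort("`threshold` must lie strictly between 0 and 1.")
  }
  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    stopifnot(all(c("name", "coef") %in% names(covariates)))
    if (!"reference" %in% names(covariates)) {
      covariates$reference <- NA_character_
    }
  }
  structure(
    list(intercept = intercept, taxa = taxa, covariates = covariates,
         threshold = threshold, scaling = scaling, link = "logistic"),
    class = "signature_model"
  )
}

#' Read a signature model from JSON
#'
#' Layout: `{intercept, threshold, taxa: [{name, coef}], covariates:
#' [{name, coef, reference}], scaling: {center: {...}, scale: {...}}}`.
#'
#' @param path JSON file path.
#' @return A `signature_model`.
#' @export
read_signature_model <- function(path) {
  if (!file.exists(path)) abort(paste0("Model file not found: ", path))
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  scaling <- NULL
  if (!is.null(x$scaling)) {
    scaling <- purrr::map(x$scaling, unlist)
  }
  signature_model(
    intercept = x$intercept,
    taxa = x$taxa,
    covariates = x$covariates,
    threshold = x$threshold %||% 0.33,
    scaling = scaling
  )
}

#' Write a signature model to JSON
#'
#' @param model A `signature_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_model <- function(model, path) {
  x <- list(intercept = model$intercept, threshold = model$threshold,
            taxa = model$taxa)
  if (!is.null(model$covariates)) x$covariates <- model$covariates
  if (!is.null(model$scaling)) {
    x$scaling <- purrr::map(model$scaling, as.list)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @export
print.signature_model <- function(x, ...) {
  cat("<signature_model>", nrow(x$taxa), "taxa, intercept",
      signif(x$intercept, 4), ", threshold", x$threshold, "\n")
  invisible(x)
}

#' Predict case probabilities from clr features
#'
#' Computes `p = plogis(intercept + sum_k beta_k x_k + covariate terms)` for
#' every sample. With a `mapping`, each signature taxon's feature is taken
#' from its mapped 16S column, so a shotgun-trained model runs on 16S data.
#'
#' @param model A `signature_model`.
#' @param clr Wide clr table whose columns cover the signature taxa
#'   (directly, or through `mapping`).
#' @param covariates Optional data frame with `sample_id` plus one column
#'   per model covariate. Factor-style covariates with a `reference` in the
#'   model may be omitted (treated as at reference level).
#' @param mapping Optional `taxon_mapping` from [map_signature()].
#' @return Tibble `sample_id`, `linear_predictor`, `prob`, `class`.
#' @export
predict_signature <- function(model, clr, covariates = NULL, mapping = NULL) {
  stopifnot(inherits(model, "signature_model"))
  X <- as_abundance_matrix(clr, "clr")
  feat <- setNames(model$taxa$name, model$taxa$name)
  if (!is.null(mapping)) {
    idx <- match(model$taxa$name, mapping$shotgun_taxon)
    if (anyNA(idx)) {
      abort(paste0("Mapping lacks signature taxa: ",
                   paste(head(model$taxa$name[is.na(idx)], 5), collapse = ", ")))
    }
    feat <- setNames(mapping$s16_taxon[idx], model$taxa$name)
  }
  missing <- setdiff(unique(unname(feat)), colnames(X))
  if (length(missing) > 0) {
    abort(paste0("clr matrix lacks feature column(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  M <- X[, unname(feat), drop = FALSE] # one column per signature taxon
  if (!is.null(model$scaling)) {
    ctr <- model$scaling$center
    scl <- model$scaling$scale
    if (!is.null(ctr)) M <- sweep(M, 2, unname(ctr[names(feat)]), "-")
    if (!is.null(scl)) M <- sweep(M, 2, unname(scl[names(feat)]), "/")
  }
  lp <- model$intercept + drop(M %*% model$taxa$coef)

  if (!is.null(model$covariates) && nrow(model$covariates) > 0) {
    cv <- model$covariates
    if (is.null(covariates)) covariates <- tibble::tibble(sample_id = rownames(X))
    if (!"sample_id" %in% names(covariates)) names(covariates)[1] <- "sample_id"
    idx <- match(rownames(X), covariates$sample_id)
    if (anyNA(idx)) {
      abort(paste0("Covariate rows missing for sample(s): ",
                   paste(head(rownames(X)[is.na(idx)], 5), collapse = ", ")))
    }
    covariates <- covariates[idx, , drop = FALSE]
    for (j in seq_len(nrow(cv))) {
      nm <- cv$name[j]
      has_ref <- !is.na(cv$reference[j] %||% NA)
      if (!nm %in% names(covariates)) {
        if (has_ref) next # absent factor covariate: reference level, term 0
        abort(paste0("Covariate column missing: ", nm))
      }
      val <- covariates[[nm]]
      if (anyNA(val)) {
        abort(paste0("Missing values in covariate '", nm, "' for sample(s): ",
                     paste(head(covariates$sample_id[is.na(val)], 5), collapse = ", ")))
      }
      term <- if (has_ref) {
        cv$coef[j] * as.numeric(as.character(val) != cv$reference[j])
      } else {
        cv$coef[j] * as.numeric(val)
      }
      lp <- lp + term
    }
  }
  p <- stats::plogis(lp)
  tibble::tibble(
    sample_id = rownames(X),
    linear_predictor = unname(lp),
    prob = unname(p),
    class = classify_probs(p, model$threshold)
  )
}

#' Threshold classification of case probabilities
#'
#' A sample is called a case iff its probability reaches the threshold
#' (boundary `p == threshold` counts as case).
#'
#' @param p Probability vector.
#' @param threshold Decision threshold (default 0.33).
#' @return Factor with levels `control`, `case`.
#' @export
classify_probs <- function(p, threshold = 0.33) {
  factor(ifelse(p >= threshold, "case", "control"),
         levels = c("control", "case"))
}

#' Signature-taxon importance
#'
#' Importance of taxon k is its model coefficient times the absolute mean
#' clr abundance, `beta_k * |mean_i x_ik|`; the sign separates control- from
#' case-enriched taxa. Rows are sorted by descending importance magnitude.
#'
#' @param model A `signature_model`.
#' @param clr Wide clr table containing every signature taxon.
#' @return Tibble `taxon`, `coef`, `mean_clr`, `sd_clr`, `importance`,
#'   `direction`.
#' @export
signature_importance <- function(model, clr) {
  stopifnot(inherits(model, "signature_model"))
  X <- as_abundance_matrix(clr, "clr")
  missing <- setdiff(model$taxa$name, colnames(X))
  if (length(missing) > 0) {
    abort(paste0("clr matrix lacks signature taxa: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  M <- X[, model$taxa$name, drop = FALSE]
  out <- tibble::tibble(
    taxon = model$taxa$name,
    coef = model$taxa$coef,
    mean_clr = unname(colMeans(M)),
    sd_clr = unname(apply(M, 2, stats::sd)),
    importance = unname(model$taxa$coef * abs(colMeans(M))),
    direction = ifelse(model$taxa$coef >= 0, "case-enriched", "control-enriched")
  )
  out[order(-abs(out$importance)), ]
}
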