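# Step 2 of the harmonization algorithm: data-driven selection of the
# closest 16S taxon within the taxonomic candidate pool, and assembly of the
# one-to-one signature mapping.

#' Euclidean distance between two clr taxon profiles
#'
#' Treats samples as variables: the distance between taxon a's and taxon b's
#' clr abundance profiles across the shared, identically ordered paired
#' samples.
#'
#' @param a,b Numeric vectors (clr values across samples), with matching
#'   sample names if named.
#' @return Non-negative scalar distance.
#' @export
profile_distance <- function(a, b) {
  if (length(a) != length(b)) abort("Profiles have different lengths.")
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b))) {
    abort("Profiles are indexed by different (or differently ordered) samples.")
  }
  sqrt(sum((a - b)^2))
}

# distances from one shotgun taxon profile to every column of a clr matrix
profile_distances_to_all <- function(x, Y) {
  sqrt(colSums((Y - x)^2))
}

#' Closest 16S candidate by clr profile
#'
#' Among a candidate pool of 16S taxa, picks the one whose clr profile
#' across the paired samples is nearest (Euclidean, or Spearman-correlation
#' distance) to the target shotgun taxon's profile. Ties break to the
#' lexicographically smallest taxon ID for determinism.
#'
#' @param target Shotgun taxon ID (a column of `sg_clr`).
#' @param pool Non-empty character vector of 16S taxon IDs (columns of
#'   `ss_clr`).
#' @param sg_clr,ss_clr Wide clr tables over the same paired samples.
#' @param metric `"euclidean"` (default) or `"spearman"` (dissimilarity
#'   `1 - rho` between the two profiles).
#' @return List with `taxon` and `distance`.
#' @export
nearest_candidate <- function(target, pool, sg_clr, ss_clr,
                              metric = c("euclidean", "spearman")) {
  metric <- match.arg(metric)
  if (length(pool) == 0) abort("Candidate pool is empty.")
  X <- as_abundance_matrix(sg_clr, "sg_clr")
  Y <- as_abundance_matrix(ss_clr, "ss_clr")
  al <- align_paired_samples(X, Y)
  X <- al$a; Y <- al$b
  if (!target %in% colnames(X)) {
    abort(paste0("Target taxon not in sg_clr: ", target))
  }
  missing <- setdiff(pool, colnames(Y))
  if (length(missing) > 0) {
    abort(paste0("Pool taxa absent from ss_clr: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  d <- taxon_distances(X[, target], Y[, pool, drop = FALSE], metric)
  ord <- order(d, names(d)) # ties -> lexicographically smallest ID
  list(taxon = names(d)[ord[1]], distance = unname(d[ord[1]]))
}

taxon_distances <- function(x, Y, metric) {
  if (metric == "euclidean") {
    d <- profile_distances_to_all(x, Y)
  } else {
    d <- 1 - suppressWarnings(cor(x, Y, method = "spearman"))[1, ]
    d[is.na(d)] <- 2 # constant profiles: maximally dissimilar
  }
  setNames(d, colnames(Y))
}

#' Map a shotgun signature onto 16S taxa
#'
#' The full two-step algorithm. For each signature taxon, a rank-ladder
#' search against the 16S taxonomy yields a candidate pool; a singleton pool
#' is accepted as-is (purely taxonomic assignment), while larger pools go to
#' the data-driven step, which picks the candidate with the nearest clr
#' profile across the paired samples. Each pair also carries the
#' taxonomy-free check of [distance_rank_check()]: whether the chosen 16S
#' taxon would minimize the distance over *all* 16S taxa.
#'
#' Two shotgun taxa may map to the same 16S taxon (with a warning);
#' `strict = TRUE` instead assigns greedily in signature order, skipping 16S
#' taxa already used.
#'
#' @param signature Taxonomy-like tibble of signature lineages; `taxon_id`
#'   must name columns of `sg_clr`.
#' @param target_tax 16S taxonomy tibble; `taxon_id` must name columns of
#'   `ss_clr` (taxa dropped by filtering are ignored with a message).
#' @param sg_clr,ss_clr Wide clr tables over the same paired samples.
#' @param max_rank Ladder cap, see [rank_ladder_search()].
#' @param metric Distance metric, see [nearest_candidate()].
#' @param strict Enforce an injective mapping greedily (default FALSE).
#' @return A `taxon_mapping` tibble: `shotgun_taxon`, `s16_taxon`,
#'   `matched_rank`, `pool_size`, `distance`, `absolute_min`, `method`.
#' @export
map_signature <- function(signature, target_tax, sg_clr, ss_clr,
                          max_rank = "phylum",
                          metric = c("euclidean", "spearman"),
                          strict = FALSE) {
  metric <- match.arg(metric)
  signature <- validate_taxonomy(signature)
  target_tax <- validate_taxonomy(target_tax)
  X <- as_abundance_matrix(sg_clr, "sg_clr")
  Y <- as_abundance_matrix(ss_clr, "ss_clr")
  al <- align_paired_samples(X, Y)
  X <- al$a; Y <- al$b
  missing_sig <- setdiff(signature$taxon_id, colnames(X))
  if (length(missing_sig) > 0) {
    abort(paste0("Signature taxa absent from sg_clr: ",
                 paste(head(missing_sig, 5), collapse = ", ")))
  }
  dropped <- setdiff(target_tax$taxon_id, colnames(Y))
  if (length(dropped) > 0) {
    inform(sprintf(
      "%d taxa of the 16S taxonomy have no clr profile (filtered out) and are not candidates.",
      length(dropped)
    ))
    target_tax <- target_tax[target_tax$taxon_id %in% colnames(Y), ]
  }

  pools <- purrr::map(seq_len(nrow(signature)), function(i) {
    rank_ladder_search(signature[i, ], target_tax, max_rank = max_rank)
  })
  unmatched <- signature$taxon_id[purrr::map_int(pools, ~ length(.x$candidates)) == 0]
  if (length(unmatched) > 0) {
    abort(paste0("No 16S candidates at any rank for signature taxa: ",
                 paste(unmatched, collapse = ", ")))
  }

  used <- character(0)
  rows <- purrr::map(seq_len(nrow(signature)), function(i) {
    sg_id <- signature$taxon_id[i]
    pool <- pools[[i]]$candidates
    eff_pool <- if (strict) setdiff(pool, used) else pool
    if (length(eff_pool) == 0) {
      abort(paste0("Strict mode exhausted the candidate pool for ", sg_id))
    }
    d <- taxon_distances(X[, sg_id], Y[, eff_pool, drop = FALSE], metric)
    ord <- order(d, names(d))
    chosen <- names(d)[ord[1]]
    used <<- c(used, chosen)
    tibble::tibble(
      shotgun_taxon = sg_id,
      s16_taxon = chosen,
      matched_rank = pools[[i]]$matched_rank,
      pool_size = length(pool),
      distance = unname(d[ord[1]]),
      method = if (length(pool) == 1) "taxonomic" else "data-driven"
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!strict && anyDuplicated(out$s16_taxon)) {
    dup <- unique(out$s16_taxon[duplicated(out$s16_taxon)])
    warn(paste0("Several shotgun taxa share a 16S partner: ",
                paste(head(dup, 5), collapse = ", ")))
  }
  out$absolute_min <- distance_rank_check(out, X, Y, metric = metric)$absolute_min
  out <- out[, c("shotgun_taxon", "s16_taxon", "matched_rank", "pool_size",
                 "distance", "absolute_min", "method")]
  class(out) <- c("taxon_mapping", class(out))
  out
}

#' Taxonomy-free absolute-minimum check
#'
#' For each mapped pair, tests whether the chosen 16S taxon attains the
#' minimum profile distance over the entire 16S taxon set — i.e. whether the
#' data-driven step alone, without the taxonomic pre-filter, would have
#' picked it.
#'
#' @param mapping A `taxon_mapping` tibble (see [map_signature()]).
#' @param sg_clr,ss_clr Wide clr tables over the same paired samples.
#' @param metric Distance metric, see [nearest_candidate()].
#' @param tol Distance-equality tolerance.
#' @return Tibble `shotgun_taxon`, `s16_taxon`, `global_min_taxon`,
#'   `global_min_distance`, `absolute_min` (logical).
#' @export
distance_rank_check <- function(mapping, sg_clr, ss_clr,
                                metric = c("euclidean", "spearman"),
                                tol = 1e-9) {
  metric <- match.arg(metric)
  X <- as_abundance_matrix(sg_clr, "sg_clr")
  Y <- as_abundance_matrix(ss_clr, "ss_clr")
  al <- align_paired_samples(X, Y)
  X <- al$a; Y <- al$b
  rows <- purrr::map(seq_len(nrow(mapping)), function(i) {
    d <- taxon_distances(X[, mapping$shotgun_taxon[i]], Y, metric)
    ord <- order(d, names(d))
    dd <- unname(d[mapping$s16_taxon[i]])
    tibble::tibble(
      shotgun_taxon = mapping$shotgun_taxon[i],
      s16_taxon = mapping$s16_taxon[i],
      global_min_taxon = names(d)[ord[1]],
      global_min_distance = unname(d[ord[1]]),
      absolute_min = dd <= unname(d[ord[1]]) + tol
    )
  })
  dplyr::bind_rows(rows)
}
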