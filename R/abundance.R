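# Compositional preprocessing shared by the shotgun and 16S count matrices,
# plus the alpha-diversity / sparsity descriptives.
#
# All functions take a wide abundance table (sample_id column + one column
# per taxon; a matrix with sample rownames also works) and return a tibble
# of the same shape, so steps chain with the pipe:
#
#   counts |> normalize_genome_length(len) |> filter_prevalence() |>
#     replace_zeros_bm() |> clr_transform()

#' Normalize shotgun counts by genome length
#'
#' Divides each taxon's counts by its genome length in base pairs, turning
#' read counts into (unnormalized) genome copy numbers. Applies to shotgun
#' data only; 16S amplicon counts have no genome-length analogue.
#'
#' @param counts Wide abundance table (samples x taxa).
#' @param lengths Data frame with columns `taxon_id`, `length_bp`, or a named
#'   numeric vector.
#' @return Tibble of length-normalized abundances.
#' @export
normalize_genome_length <- function(counts, lengths) {
  m <- as_abundance_matrix(counts, "counts", require_counts = TRUE)
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length_bp, lengths$taxon_id)
  }
  len <- lengths[colnames(m)]
  bad <- colnames(m)[is.na(len) | len <= 0]
  if (length(bad) > 0) {
    abort(paste0("Missing or non-positive genome length for taxa: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  as_abundance_tbl(sweep(m, 2, len, "/"))
}

#' Prevalence/abundance filter
#'
#' Keeps a taxon if its within-sample relative abundance reaches
#' `min_rel_abundance` in at least `ceiling(min_prevalence * n_samples)`
#' samples. Relative abundance is computed per sample on the incoming
#' matrix (length-normalized counts for shotgun data). The sample set is
#' unchanged, and the filter is idempotent: dropping rare taxa only raises
#' the survivors' relative abundances.
#'
#' @param counts Wide abundance table (counts or length-normalized counts).
#' @param min_prevalence Minimum fraction of samples (default 0.05).
#' @param min_rel_abundance Minimum within-sample relative abundance
#'   (default 0.001, i.e. 0.1%).
#' @return Filtered tibble; taxa kept in their original order.
#' @export
filter_prevalence <- function(counts, min_prevalence = 0.05,
                              min_rel_abundance = 0.001) {
  m <- as_abundance_matrix(counts, "counts", require_counts = TRUE)
  if (nrow(m) == 0 || ncol(m) == 0) abort("`counts` is empty.")
  rs <- rowSums(m)
  if (any(rs == 0)) {
    abort(paste0("All-zero sample(s): ",
                 paste(head(rownames(m)[rs == 0], 5), collapse = ", ")))
  }
  rel <- m / rs
  n_needed <- ceiling(min_prevalence * nrow(m))
  keep <- colSums(rel >= min_rel_abundance) >= n_needed
  if (!any(keep)) abort("Prevalence filter removed every taxon.")
  as_abundance_tbl(m[, keep, drop = FALSE])
}

#' Square-root Bayesian-multiplicative zero replacement
#'
#' Replaces count zeros by their Dirichlet-posterior expected proportions
#' under a uniform prior with total strength equal to the square root of the
#' sample's depth: for sample i with depth n_i over D taxa, each zero becomes
#' `sqrt(n_i) * (1/D) / (n_i + sqrt(n_i))`, and the non-zero proportions are
#' multiplicatively rescaled so the row closes to 1. Ratios among originally
#' non-zero parts are preserved exactly, which is what makes the subsequent
#' log-ratio analysis well defined.
#'
#' @param counts Wide abundance table; every sample needs at least one
#'   positive entry.
#' @return Tibble of strictly positive proportions, rows summing to 1.
#' @export
replace_zeros_bm <- function(counts) {
  m <- as_abundance_matrix(counts, "counts", require_counts = TRUE)
  n <- rowSums(m)
  if (any(n == 0)) {
    abort(paste0("All-zero sample(s): ",
                 paste(head(rownames(m)[n == 0], 5), collapse = ", ")))
  }
  D <- ncol(m)
  s <- sqrt(n)
  repl <- s * (1 / D) / (n + s)          # per-row replacement proportion
  out <- m / n                           # closed proportions
  zero <- m == 0
  for (i in seq_len(nrow(m))) {
    zi <- zero[i, ]
    if (!any(zi)) next
    mass <- sum(zi) * repl[i]
    out[i, zi] <- repl[i]
    out[i, !zi] <- out[i, !zi] * (1 - mass)
  }
  as_abundance_tbl(out)
}

#' Centred log-ratio transform
#'
#' `clr(x)_j = ln(x_j / g(x))` with `g` the row geometric mean. Rows sum to
#' zero; the transform is invariant to rescaling a row (closure invariance).
#' Zeros must have been replaced first (see [replace_zeros_bm()]).
#'
#' @param comp Wide table of strictly positive compositions.
#' @return Tibble of clr coordinates.
#' @export
clr_transform <- function(comp) {
  m <- as_abundance_matrix(comp, "comp")
  if (any(m <= 0)) {
    abort("clr requires strictly positive entries; run replace_zeros_bm() first.")
  }
  lg <- log(m)
  as_abundance_tbl(lg - rowMeans(lg))
}

#' Full compositional preprocessing pipeline
#'
#' Genome-length normalization (if lengths given), prevalence filter,
#' square-root Bayesian-multiplicative zero replacement, clr transform —
#' in that order.
#'
#' @inheritParams filter_prevalence
#' @param genome_lengths Optional genome-length table for shotgun data, see
#'   [normalize_genome_length()].
#' @return Tibble of clr coordinates for the retained taxa.
#' @export
preprocess_counts <- function(counts, genome_lengths = NULL,
                              min_prevalence = 0.05,
                              min_rel_abundance = 0.001) {
  if (!is.null(genome_lengths)) {
    counts <- normalize_genome_length(counts, genome_lengths)
  }
  counts |>
    filter_prevalence(min_prevalence, min_rel_abundance) |>
    replace_zeros_bm() |>
    clr_transform()
}

#' Rarefy counts to a common depth
#'
#' Without-replacement subsampling of each sample's reads to `depth`,
#' delegated to [vegan::rrarefy()]; reproducible under `seed`.
#'
#' @param counts Wide table of integer counts.
#' @param depth Target depth; must not exceed any sample's total. Default:
#'   the minimum sample depth.
#' @param seed Optional integer seed.
#' @return Tibble of rarefied counts; every row sums to `depth`.
#' @export
rarefy_counts <- function(counts, depth = NULL, seed = NULL) {
  m <- as_abundance_matrix(counts, "counts", require_counts = TRUE)
  if (any(abs(m - round(m)) > 1e-8)) {
    abort("Rarefaction requires integer counts.")
  }
  rs <- rowSums(m)
  depth <- depth %||% min(rs)
  if (any(rs < depth)) {
    abort(paste0("Depth ", depth, " exceeds the total of sample(s): ",
                 paste(head(rownames(m)[rs < depth], 5), collapse = ", ")))
  }
  local_seed_if(seed)
  as_abundance_tbl(suppressWarnings(vegan::rrarefy(round(m), depth)))
}

#' Bias-corrected Chao1 richness
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, with F1/F2 the singleton and
#' doubleton counts; defined even when no doubletons are observed.
#'
#' @param counts Wide table of integer counts (or a single count vector).
#' @return Tibble with `sample_id` and `chao1` (or a scalar for a vector).
#' @export
chao1 <- function(counts) {
  if (is.numeric(counts) && is.null(dim(counts))) {
    return(chao1_one(counts))
  }
  m <- as_abundance_matrix(counts, "counts", require_counts = TRUE)
  tibble::tibble(sample_id = rownames(m),
                 chao1 = unname(apply(m, 1, chao1_one)))
}

chao1_one <- function(x) {
  if (any(abs(x - round(x)) > 1e-8)) abort("Chao1 requires integer counts.")
  x <- round(x)
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity
#'
#' `-sum(p log p)` over observed taxa, via [vegan::diversity()]; natural log
#' by default, base-2 available.
#'
#' @param counts Wide table of counts or relative abundances.
#' @param base Logarithm base (default `exp(1)` for nats).
#' @return Tibble with `sample_id` and `shannon`.
#' @export
shannon_diversity <- function(counts, base = exp(1)) {
  m <- as_abundance_matrix(counts, "counts", require_counts = TRUE)
  tibble::tibble(sample_id = rownames(m),
                 shannon = unname(vegan::diversity(m, index = "shannon", base = base)))
}

#' Per-sample fraction of zero entries
#'
#' @param counts Wide abundance table.
#' @return Tibble with `sample_id` and `zero_fraction` in \[0, 1\].
#' @export
zero_fraction <- function(counts) {
  m <- as_abundance_matrix(counts, "counts")
  tibble::tibble(sample_id = rownames(m),
                 zero_fraction = unname(rowMeans(m == 0)))
}

#' Alpha-diversity descriptives for one count matrix
#'
#' Chao1 on the filtered counts, Shannon on counts rarefied to the minimum
#' depth (the convention used for comparing technologies), and the zero
#' fraction.
#'
#' @param counts Wide table of integer counts (already prevalence-filtered,
#'   before zero replacement).
#' @param seed Seed for the rarefaction.
#' @return Tibble with `sample_id`, `chao1`, `shannon`, `zero_fraction`.
#' @export
alpha_descriptives <- function(counts, seed = NULL) {
  rar <- rarefy_counts(counts, seed = seed)
  chao1(counts) |>
    dplyr::left_join(shannon_diversity(rar), by = "sample_id") |>
    dplyr::left_join(zero_fraction(counts), by = "sample_id")
}
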