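# Generator of paired shotgun/16S datasets with known ground truth.
#
# A shared latent community (logistic-normal with genus-level correlation
# blocks) is observed twice: shotgun sees every species (multinomial at high
# depth); 16S sees per-taxon amplification bias, per-entry observation
# noise, loss of species-level resolution (affected species collapse into a
# genus-level taxon), and extra dropout thinning calibrated to a target
# zero fraction. A logistic case/control outcome is driven by a known
# 32-species signature plus covariates, so mapping recovery and downstream
# model performance can be benchmarked against the truth.

#' Configuration for the paired-data generator
#'
#' Defaults emulate the study conditions this generator is calibrated
#' against: 150 paired samples, 400 shotgun species, ~60% of species
#' nameable in 16S only at genus level, mean 16S zero fraction 0.61 versus a
#' dense shotgun matrix, lower 16S alpha diversity, and a 32-species
#' signature with covariates on epidemiological scales (sex ~ Bernoulli(0.5),
#' age ~ N(60, 8), BMI ~ N(27, 4)).
#'
#' @param n_samples Number of paired samples.
#' @param n_species Number of shotgun species.
#' @param genus_sizes Optional integer partition of `n_species` into genera;
#'   drawn (1 + Poisson(2)-sized genera) when `NULL`.
#' @param s16_resolution_loss Fraction of species observable in 16S only as
#'   part of a genus-level aggregate.
#' @param depth_shotgun,depth_16s Sequencing depths (reads per sample).
#' @param sparsity_target_16s Target mean zero fraction of the 16S matrix.
#' @param bias_sd Log-normal sd of the per-taxon 16S amplification bias.
#' @param noise_sd_16s Log-normal sd of the per-entry 16S observation noise
#'   (the noise scale of the 16S observation model).
#' @param n_signature Number of signature species.
#' @param signature_effect Typical magnitude of a signature coefficient on
#'   the clr scale; effects are drawn `±Uniform(0.5, 1.5) * signature_effect`.
#' @param covariate_effects Named vector of logistic coefficients for
#'   `sex` (0/1), `age` (years) and `bmi`.
#' @param sigma_species Sd of between-species mean log abundances.
#' @param sigma_genus Sd of the genus-block per-sample random effect (shared
#'   by genus mates; what makes genus-level profiles correlated).
#' @param sigma_sample Sd of the species-level per-sample effect (the
#'   species-specific signal the data-driven mapping step keys on).
#' @param threshold Decision threshold stored in the true model.
#' @param seed Integer seed; every stochastic step in [simulate_paired()]
#'   derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 150,
                       n_species = 400,
                       genus_sizes = NULL,
                       s16_resolution_loss = 0.6,
                       depth_shotgun = 1e5,
                       depth_16s = 2e4,
                       sparsity_target_16s = 0.61,
                       bias_sd = 0.3,
                       noise_sd_16s = 0.3,
                       n_signature = 32,
                       signature_effect = 0.5,
                       covariate_effects = c(sex = 0.3, age = 0.02, bmi = 0.02),
                       sigma_species = 1.5,
                       sigma_genus = 0.5,
                       sigma_sample = 1.0,
                       threshold = 0.33,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_samples > 0, cfg$n_species > 1,
            cfg$s16_resolution_loss >= 0, cfg$s16_resolution_loss <= 1,
            cfg$sparsity_target_16s >= 0, cfg$sparsity_target_16s <= 1,
            cfg$depth_shotgun > 0, cfg$depth_16s > 0,
            cfg$n_signature <= ceiling(cfg$n_species / 2))
  if (!is.null(cfg$genus_sizes) && sum(cfg$genus_sizes) != cfg$n_species) {
    abort("`genus_sizes` must sum to `n_species`.")
  }
  structure(cfg, class = "sim_config")
}

draw_genus_sizes <- function(n_species) {
  sizes <- integer(0)
  while (sum(sizes) < n_species) {
    sizes <- c(sizes, 1L + stats::rpois(50, 2))
  }
  excess <- sum(sizes) - n_species
  while (excess > 0) {
    i <- which(sizes > 1)[1]
    if (is.na(i)) {
      sizes <- sizes[-length(sizes)]
      excess <- excess - 1
    } else {
      take <- min(excess, sizes[i] - 1L)
      sizes[i] <- sizes[i] - take
      excess <- excess - take
    }
  }
  sizes[sizes > 0]
}

pad_id <- function(prefix, i, n) {
  sprintf(paste0(prefix, "%0", nchar(as.character(n)), "d"), i)
}

# Hierarchical lineages above genus: 4 genera / family, 4 families / order,
# 3 orders / class, 3 classes / phylum.
build_lineages <- function(genus_of_species, n_genera) {
  fam_of_genus <- ceiling(seq_len(n_genera) / 4)
  ord_of_fam <- ceiling(seq_len(max(fam_of_genus)) / 4)
  cls_of_ord <- ceiling(seq_len(max(ord_of_fam)) / 3)
  phy_of_cls <- ceiling(seq_len(max(cls_of_ord)) / 3)
  g <- genus_of_species
  f <- fam_of_genus[g]
  o <- ord_of_fam[f]
  cl <- cls_of_ord[o]
  ph <- phy_of_cls[cl]
  tibble::tibble(
    kingdom = "Bacteria",
    phylum = pad_id("Phylum", ph, max(phy_of_cls)),
    class = pad_id("Class", cl, max(cls_of_ord)),
    order = pad_id("Order", o, max(ord_of_fam)),
    family = pad_id("Family", f, max(fam_of_genus)),
    genus = pad_id("Genus", g, n_genera)
  )
}

softmax_rows <- function(eta) {
  e <- exp(eta - apply(eta, 1, max))
  e / rowSums(e)
}

multinomial_rows <- function(P, depth) {
  t(apply(P, 1, function(p) rmultinom(1, depth, p)[, 1]))
}

# Global dropout thinning: zero the smallest non-zero entries (random order
# within ties) until the overall zero fraction reaches `target`, never
# removing a sample's largest entry.
apply_dropout <- function(m, target) {
  n_total <- length(m)
  need <- round(target * n_total) - sum(m == 0)
  if (need <= 0) return(m)
  protect <- cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))
  prot_idx <- (protect[, 2] - 1) * nrow(m) + protect[, 1]
  nz <- setdiff(which(m > 0), prot_idx)
  ord <- nz[order(m[nz], runif(length(nz)))]
  kill <- ord[seq_len(min(need, length(ord)))]
  m[kill] <- 0
  m
}

#' Simulate a paired shotgun/16S dataset
#'
#' See [sim_config()] for the generative model and its knobs. Fully
#' reproducible under `config$seed`.
#'
#' @param config A `sim_config`.
#' @return A `paired_sim` list: `sg_counts`, `ss_counts` (wide count
#'   tibbles), `sg_tax`, `ss_tax` (taxonomy tibbles), `meta` (sample_id,
#'   group, sex, age, bmi), `truth` (list: `true_mapping` tibble over all
#'   species, `true_model` [signature_model()], `latent_clr` wide tibble of
#'   the latent composition's clr), and `config`.
#' @export
simulate_paired <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  local_seed_if(config$seed)
  n <- config$n_samples
  D <- config$n_species

  sizes <- config$genus_sizes %||% draw_genus_sizes(D)
  n_genera <- length(sizes)
  genus_of_species <- rep(seq_len(n_genera), times = sizes)
  sp_within <- stats::ave(genus_of_species, genus_of_species, FUN = seq_along)
  lineages <- build_lineages(genus_of_species, n_genera)
  species_names <- paste0(lineages$genus, " species", sp_within)
  sg_ids <- pad_id("sg", seq_len(D), D)
  sample_ids <- pad_id("S", seq_len(n), n)

  sg_tax <- dplyr::bind_cols(tibble::tibble(taxon_id = sg_ids), lineages,
                             tibble::tibble(species = species_names))

  # latent community
  mu <- rnorm(D, 0, config$sigma_species)
  g_eff <- matrix(rnorm(n * n_genera, 0, config$sigma_genus), n, n_genera)
  eps <- matrix(rnorm(n * D, 0, config$sigma_sample), n, D)
  eta <- sweep(eps + g_eff[, genus_of_species, drop = FALSE], 2, mu, "+")
  P <- softmax_rows(eta)
  dimnames(P) <- list(sample_ids, sg_ids)

  sg_counts <- multinomial_rows(P, config$depth_shotgun)
  dimnames(sg_counts) <- list(sample_ids, sg_ids)

  # 16S observation: amplification bias, per-entry noise, resolution collapse
  n_lost <- round(config$s16_resolution_loss * D)
  lost <- sort(sample.int(D, n_lost))
  is_lost <- seq_len(D) %in% lost
  bias <- exp(rnorm(D, 0, config$bias_sd))
  noise <- matrix(exp(rnorm(n * D, 0, config$noise_sd_16s)), n, D)
  W <- P * noise * rep(bias, each = n)

  retained <- which(!is_lost)
  ss_sp_ids <- setNames(pad_id("ss_sp", seq_len(D), D)[retained], sg_ids[retained])
  lost_genera <- sort(unique(genus_of_species[is_lost]))
  ss_g_ids <- setNames(pad_id("ss_g", lost_genera, n_genera),
                       as.character(lost_genera))

  Q <- cbind(
    W[, retained, drop = FALSE],
    vapply(lost_genera, function(g) {
      rowSums(W[, is_lost & genus_of_species == g, drop = FALSE])
    }, numeric(n))
  )
  colnames(Q) <- c(unname(ss_sp_ids), unname(ss_g_ids))
  rownames(Q) <- sample_ids
  Q <- Q / rowSums(Q)

  ss_counts <- multinomial_rows(Q, config$depth_16s)
  dimnames(ss_counts) <- dimnames(Q)
  if (config$sparsity_target_16s > 0) {
    ss_counts <- apply_dropout(ss_counts, config$sparsity_target_16s)
  }

  ss_tax <- dplyr::bind_rows(
    dplyr::bind_cols(
      tibble::tibble(taxon_id = unname(ss_sp_ids)),
      lineages[retained, ],
      tibble::tibble(species = species_names[retained])
    ),
    dplyr::bind_cols(
      tibble::tibble(taxon_id = unname(ss_g_ids)),
      lineages[match(lost_genera, genus_of_species), ],
      tibble::tibble(species = NA_character_)
    )
  )

  # ground-truth partner: itself if retained, else its genus aggregate
  true_partner <- ifelse(is_lost,
                         unname(ss_g_ids[as.character(genus_of_species)]),
                         pad_id("ss_sp", seq_len(D), D))
  true_mapping <- tibble::tibble(shotgun_taxon = sg_ids,
                                 s16_taxon = true_partner)

  # signature: species from the abundant half, with known effects
  abundant <- which(mu >= stats::median(mu))
  sig_idx <- sort(sample(abundant, config$n_signature))
  beta <- sample(c(-1, 1), config$n_signature, replace = TRUE) *
    runif(config$n_signature, 0.5, 1.5) * config$signature_effect

  latent_clr <- log(P) - rowMeans(log(P))
  sex <- rbinom(n, 1, 0.5)
  age <- rnorm(n, 60, 8)
  bmi <- rnorm(n, 27, 4)
  ce <- config$covariate_effects
  lp0 <- drop(latent_clr[, sig_idx, drop = FALSE] %*% beta) +
    ce[["sex"]] * sex + ce[["age"]] * age + ce[["bmi"]] * bmi
  intercept <- -mean(lp0)
  p_case <- stats::plogis(lp0 + intercept)
  y <- rbinom(n, 1, p_case)

  true_model <- signature_model(
    intercept = intercept,
    taxa = tibble::tibble(name = sg_ids[sig_idx], coef = beta),
    covariates = tibble::tibble(name = c("sex", "age", "bmi"),
                                coef = unname(ce[c("sex", "age", "bmi")])),
    threshold = config$threshold
  )

  meta <- tibble::tibble(
    sample_id = sample_ids,
    group = factor(ifelse(y == 1, "CRC", "control"),
                   levels = c("control", "CRC")),
    sex = sex, age = age, bmi = bmi
  )

  structure(
    list(
      sg_counts = as_abundance_tbl(sg_counts),
      ss_counts = as_abundance_tbl(ss_counts),
      sg_tax = sg_tax,
      ss_tax = ss_tax,
      meta = meta,
      truth = list(true_mapping = true_mapping,
                   true_model = true_model,
                   latent_clr = as_abundance_tbl(latent_clr)),
      config = config
    ),
    class = "paired_sim"
  )
}

#' @export
print.paired_sim <- function(x, ...) {
  cat("<paired_sim>", nrow(x$meta), "paired samples;",
      ncol(x$sg_counts) - 1, "shotgun taxa,",
      ncol(x$ss_counts) - 1, "16S taxa;",
      sum(x$meta$group != "control"), "cases\n")
  invisible(x)
}

#' Mapping recovery against simulation ground truth
#'
#' Fraction of mapped signature taxa whose chosen 16S partner equals the
#' generator's true partner.
#'
#' @param truth The `truth` element of a [simulate_paired()] result (or the
#'   whole `paired_sim`).
#' @param mapping A `taxon_mapping` from [map_signature()].
#' @return One-row tibble: `n_mapped`, `n_correct`, `recovery`.
#' @export
recovery_report <- function(truth, mapping) {
  if (inherits(truth, "paired_sim")) truth <- truth$truth
  tm <- truth$true_mapping
  idx <- match(mapping$shotgun_taxon, tm$shotgun_taxon)
  if (anyNA(idx)) abort("Mapping contains taxa unknown to the simulation truth.")
  correct <- mapping$s16_taxon == tm$s16_taxon[idx]
  tibble::tibble(
    n_mapped = nrow(mapping),
    n_correct = sum(correct),
    recovery = mean(correct)
  )
}
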