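# Shared fixtures and independent oracles, all built in code.

# Build a taxonomy tibble from genus/species vectors, filling the upper
# ranks from the genus so rank-ladder queries have somewhere to go.
make_tax <- function(ids, genus, species, family = NULL, order = NULL) {
  n <- length(ids)
  if (is.null(family)) family <- paste0(genus, "aceae")
  if (is.null(order)) order <- paste0(genus, "ales")
  tibble::tibble(
    taxon_id = ids,
    kingdom = "Bacteria",
    phylum = "Bacillota",
    class = "Clostridia",
    order = rep_len(order, n),
    family = rep_len(family, n),
    genus = genus,
    species = species
  )
}

toy_16s_tax <- function() {
  make_tax(
    ids = c("t1", "t2", "t3", "t4", "t5"),
    genus = c("Bacteroides", "Bacteroides", "Bacteroides", "Parvimonas", "Dialister"),
    species = c("Bacteroides fragilis", "Bacteroides vulgatus",
                "Bacteroides dorei", "Parvimonas micra", NA)
  )
}

# small random count table (samples x taxa), Poisson counts with a few zeros
rand_counts <- function(n = 50, d = 30, seed = 1, lambda = 5) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n * d, lambda), n, d)
  })
  dimnames(m) <- list(sprintf("S%03d", seq_len(n)), sprintf("T%03d", seq_len(d)))
  tibble::as_tibble(m, rownames = "sample_id")
}

# independent all-pairs AUC oracle
brute_auc <- function(scores, case) {
  s1 <- scores[case]
  s0 <- scores[!case]
  tot <- 0
  for (a in s1) for (b in s0) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(s1) * length(s0))
}

# independent Euclidean profile distance oracle (plain loop)
brute_profile_distance <- function(a, b) {
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  sqrt(acc)
}

# matrix form of a wide abundance tibble, for oracles
tbl_mat <- function(x) {
  m <- as.matrix(x[setdiff(names(x), "sample_id")])
  rownames(m) <- x$sample_id
  m
}

# a small fully-worked paired simulation used by several test files
quiet_map <- function(...) suppressMessages(map_signature(...))
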