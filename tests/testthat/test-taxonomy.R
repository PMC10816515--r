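# Rank-ladder search, name standardization, and the match census.

test_that("candidates_at_rank finds exact names, is empty otherwise", {
  tax <- toy_16s_tax()
  q <- make_tax("q", "Parvimonas", "Parvimonas micra")
  expect_identical(candidates_at_rank(q, tax, "species"), "t4")
  expect_identical(candidates_at_rank(q, tax, "genus"), "t4")

  qb <- make_tax("q", "Bacteroides", "Bacteroides caccae")
  expect_identical(candidates_at_rank(qb, tax, "genus"), c("t1", "t2", "t3"))
  expect_identical(candidates_at_rank(qb, tax, "species"), character(0))

  empty <- tax[0, ]
  expect_identical(candidates_at_rank(q, empty, "species"), character(0))
})

test_that("name comparison is case-insensitive and whitespace-normalized", {
  tax <- toy_16s_tax()
  q <- make_tax("q", "parvimonas", "  PARVIMONAS   micra ")
  expect_identical(candidates_at_rank(q, tax, "species"), "t4")
})

test_that("queries unnamed at a rank warn and return nothing", {
  tax <- toy_16s_tax()
  q <- make_tax("q", "Dialister", NA)
  expect_warning(out <- candidates_at_rank(q, tax, "species"), "unnamed")
  expect_identical(out, character(0))
})

test_that("rank ladder stops at the most specific non-empty rank", {
  tax <- toy_16s_tax()
  # direct species hit short-circuits the ladder
  hit <- rank_ladder_search(make_tax("q", "Parvimonas", "Parvimonas micra"), tax)
  expect_identical(hit$matched_rank, "species")
  expect_identical(hit$candidates, "t4")

  # species absent, genus shared by 3 target taxa
  hit <- rank_ladder_search(make_tax("q", "Bacteroides", "Bacteroides caccae"), tax)
  expect_identical(hit$matched_rank, "genus")
  expect_length(hit$candidates, 3)

  # species and genus absent, family present
  q <- make_tax("q", "Phocaeicola", "Phocaeicola caccae",
                family = "Bacteroidesaceae")
  hit <- rank_ladder_search(q, tax)
  expect_identical(hit$matched_rank, "family")
  expect_setequal(hit$candidates, c("t1", "t2", "t3"))

  # nothing anywhere: absence is a valid result
  alien <- make_tax("q", "Methanobrevibacter", "Methanobrevibacter smithii")
  alien$kingdom <- "Archaea"; alien$phylum <- "Euryarchaeota"
  alien$class <- "Methanobacteria"
  hit <- rank_ladder_search(alien, tax)
  expect_true(is.na(hit$matched_rank))
  expect_length(hit$candidates, 0)
})

test_that("ladder result rank is minimal: all more specific ranks are empty", {
  # exact oracle over a simulated taxonomy pair
  sim <- simulate_paired(sim_config(n_samples = 5, n_species = 60,
                                    depth_shotgun = 1e4, depth_16s = 1e4,
                                    sparsity_target_16s = 0, n_signature = 10,
                                    seed = 42))
  ladder <- rev(tax_ranks())
  for (i in sample(nrow(sim$sg_tax), 15)) {
    q <- sim$sg_tax[i, ]
    hit <- rank_ladder_search(q, sim$ss_tax)
    if (is.na(hit$matched_rank)) {
      for (r in ladder) {
        expect_length(suppressWarnings(candidates_at_rank(q, sim$ss_tax, r)), 0)
      }
    } else {
      k <- which(ladder == hit$matched_rank)
      for (r in ladder[seq_len(k - 1)]) {
        expect_length(suppressWarnings(candidates_at_rank(q, sim$ss_tax, r)), 0)
      }
      expect_gt(length(hit$candidates), 0)
    }
  }
})

test_that("ladder cap is honoured", {
  tax <- toy_16s_tax()
  q <- make_tax("q", "Phocaeicola", "Phocaeicola caccae",
                family = "Bacteroidesaceae")
  hit <- rank_ladder_search(q, tax, max_rank = "genus")
  expect_true(is.na(hit$matched_rank))
})

test_that("standardize_taxonomy renames only mapped names and reports the rest", {
  tax <- make_tax(c("a", "b", "c"),
                  genus = c("Lachnoclostridium", "Bacteroides", "Parvimonas"),
                  species = c("Lachnoclostridium scindens", "Bacteroides fragilis",
                              "Parvimonas micra"))
  nm <- tibble::tibble(rank = "genus",
                       source_name = "Lachnoclostridium",
                       ncbi_name = "Clostridium")
  out <- standardize_taxonomy(tax, nm, quiet = TRUE)
  expect_identical(out$genus, c("Clostridium", "Bacteroides", "Parvimonas"))
  # all other ranks intact
  expect_identical(out$species, tax$species)
  expect_identical(out$family, tax$family)
  # unmapped names pass through and are logged
  unres <- attr(out, "unresolved")
  expect_true("Bacteroides" %in% unres$name[unres$rank == "genus"])
  # identity map leaves the table unchanged
  idmap <- tibble::tibble(rank = "genus", source_name = "Bacteroides",
                          ncbi_name = "Bacteroides")
  same <- standardize_taxonomy(tax, idmap, quiet = TRUE)
  expect_identical(same$genus, tax$genus)
})

test_that("standardization is idempotent", {
  tax <- toy_16s_tax()
  nm <- tibble::tibble(rank = c("genus", "species"),
                       source_name = c("Bacteroides", "Bacteroides fragilis"),
                       ncbi_name = c("Phocaeicola", "Phocaeicola fragilis"))
  once <- standardize_taxonomy(tax, nm, quiet = TRUE)
  twice <- standardize_taxonomy(once, nm, quiet = TRUE)
  expect_identical(as.data.frame(lapply(once[tax_ranks()], identity)),
                   as.data.frame(lapply(twice[tax_ranks()], identity)))
})

test_that("standardization collisions error with offenders listed", {
  tax <- make_tax(c("a", "b"),
                  genus = c("GenusX", "GenusY"),
                  species = c(NA, NA),
                  family = "Fam", order = "Ord")
  nm <- tibble::tibble(rank = "genus", source_name = c("GenusX", "GenusY"),
                       ncbi_name = c("GenusZ", "GenusZ"))
  expect_error(standardize_taxonomy(tax, nm, quiet = TRUE), "collapsed")
})

test_that("lineage normalizer strips clade suffixes and blanks placeholders", {
  tax <- make_tax(
    c("a", "b", "c", "d"),
    genus = c("Bacteroides", "Blautia A", "Agathobacter", "MGYG-HGUT-00184"),
    species = c("Bacteroides fragilis A", "Blautia A sp000433815",
                "Agathobacter sp000434275", "MGYG-HGUT-00184")
  )
  out <- normalize_lineage_names(tax)
  expect_identical(out$species[1], "Bacteroides fragilis")
  expect_identical(out$genus[2], "Blautia")
  # placeholder species become unnamed so the ladder starts at genus
  expect_true(all(is.na(out$species[2:4])))
  # real binomials survive
  expect_identical(out$genus[1], "Bacteroides")
})

test_that("match census tabulates ranks and its percentages sum to 100", {
  target <- toy_16s_tax()
  sig <- make_tax(
    c("s1", "s2", "s3"),
    genus = c("Parvimonas", "Bacteroides", "Methanobrevibacter"),
    species = c("Parvimonas micra", "Bacteroides caccae",
                "Methanobrevibacter smithii")
  )
  sig$kingdom[3] <- "Archaea"; sig$phylum[3] <- "Euryarchaeota"
  sig$class[3] <- "Methanobacteria"
  census <- match_census(sig, target)
  expect_identical(as.character(census$matched_rank),
                   c("species", "genus", NA))
  expect_identical(census$n_candidates, c(1L, 3L, 0L))
  summ <- census_summary(census)
  expect_equal(sum(summ$pct), 100)
  # self-match: signature drawn from the target itself matches at species
  self <- match_census(target[!is.na(target$species), ], target)
  expect_true(all(as.character(self$matched_rank) == "species"))
})

test_that("duplicate taxon IDs and lineage gaps are caught", {
  tax <- toy_16s_tax()
  expect_error(validate_taxonomy(dplyr::bind_rows(tax, tax[1, ])), "Duplicated")
  gappy <- tax
  gappy$genus[5] <- NA # species named below unnamed genus? here species is NA too
  gappy$species[5] <- "Dialister invisus"
  expect_identical(lineage_gaps(gappy)$taxon_id, "t5")
})
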