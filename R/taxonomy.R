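# Taxonomy tables, name standardization, and the rank-ladder candidate
# search (step 1 of the shotgun -> 16S mapping algorithm).
#
# A taxonomy table is a tibble with a `taxon_id` column plus the seven
# canonical rank columns (see tax_ranks()); an absent name is NA, never "".

#' Validate a taxonomy tibble
#'
#' Checks column layout, uniqueness of taxon IDs, and converts empty strings
#' to `NA`. Lineages with a named rank below an unnamed one (common for 16S
#' placeholder taxa) are permitted but counted in a message.
#'
#' @param tax A data frame with `taxon_id` and the columns of [tax_ranks()].
#' @param quiet Suppress the lineage-gap message.
#' @return The validated taxonomy tibble.
#' @export
validate_taxonomy <- function(tax, quiet = TRUE) {
  ranks <- tax_ranks()
  missing_cols <- setdiff(c("taxon_id", ranks), names(tax))
  if (length(missing_cols) > 0) {
    abort(paste0("Taxonomy table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  tax <- tibble::as_tibble(tax)[, c("taxon_id", ranks)]
  tax <- dplyr::mutate(tax, dplyr::across(
    dplyr::everything(),
    ~ dplyr::if_else(is.na(.x) | trimws(as.character(.x)) == "",
                     NA_character_, as.character(.x))
  ))
  if (anyDuplicated(tax$taxon_id)) {
    dup <- unique(tax$taxon_id[duplicated(tax$taxon_id)])
    abort(paste0("Duplicated taxon IDs: ", paste(head(dup, 5), collapse = ", ")))
  }
  if (!quiet) {
    gaps <- lineage_gaps(tax)
    if (nrow(gaps) > 0) {
      inform(sprintf(
        "%d lineage(s) have a named rank below an unnamed rank (placeholder lineages).",
        nrow(gaps)
      ))
    }
  }
  tax
}

#' Taxa whose lineage has a named rank below an unnamed rank
#'
#' @param tax Taxonomy tibble.
#' @return Tibble of the offending rows.
#' @export
lineage_gaps <- function(tax) {
  ranks <- tax_ranks()
  named <- !is.na(as.matrix(tax[ranks]))
  # a gap: an unnamed rank with any named rank below (more specific than) it
  has_gap <- apply(named, 1, function(v) any(!v & rev(cumsum(rev(v))) - v > 0))
  tax[has_gap, , drop = FALSE]
}

# Comparison key: case-insensitive, whitespace-normalized.
norm_taxon_name <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Normalize shotgun-style lineage decorations
#'
#' Shotgun reference databases decorate names with single-letter clade
#' suffixes ("Bacteroides fragilis A") and use placeholder identifiers for
#' unnamed species ("MGYG-HGUT-00184", "Agathobacter sp000434275"). This
#' normalizer (a) strips interior/trailing single-capital-letter tokens from
#' genus and species names and (b) blanks species names that are placeholder
#' identifiers, so that rank-ladder matching proceeds from the genus or
#' family given by the lineage.
#'
#' @param tax Taxonomy tibble.
#' @param strip_clade_suffix Strip single-letter clade tokens (default TRUE).
#' @param placeholder_species Treat placeholder species identifiers as
#'   unnamed at species rank (default TRUE).
#' @return The normalized taxonomy tibble.
#' @export
normalize_lineage_names <- function(tax, strip_clade_suffix = TRUE,
                                    placeholder_species = TRUE) {
  tax <- validate_taxonomy(tax)
  strip1 <- function(x) {
    out <- x
    ok <- !is.na(out)
    # drop any non-leading token that is a single capital letter
    out[ok] <- gsub("(?<=.)\\s[A-Z](?=\\s|$)", "", out[ok], perl = TRUE)
    out
  }
  if (strip_clade_suffix) {
    tax$genus <- strip1(tax$genus)
    tax$species <- strip1(tax$species)
  }
  if (placeholder_species) {
    sp <- tax$species
    is_placeholder <- !is.na(sp) & (
      # an 'sp' + digits epithet anywhere, e.g. "Agathobacter sp000434275"
      grepl("(^|\\s)sp\\d", sp) |
        # bare identifier with no lowercase binomial structure,
        # e.g. "MGYG-HGUT-00184", "CAG-245 sp..." already caught above
        !grepl("[a-z]", sub("^\\S+\\s*", "", sp)) & grepl("[-0-9]", sp) &
          !grepl("^\\S+\\s+[a-z]+", sp)
    )
    tax$species[is_placeholder] <- NA_character_
  }
  tax
}

#' Apply a rank-qualified name map to a taxonomy table
#'
#' Standardizes lineage names to a reference nomenclature (e.g. an offline
#' snapshot of NCBI taxonomy) using a precomputed map. Names absent from the
#' map pass through unchanged and are reported. Application is idempotent
#' for maps whose standardized names are not themselves remapped.
#'
#' @param tax Taxonomy tibble.
#' @param name_map Tibble with columns `rank`, `source_name`, `ncbi_name`.
#' @param quiet Suppress the resolved/unresolved message.
#' @return The standardized taxonomy tibble, with attributes `n_resolved`,
#'   `n_unresolved` and `unresolved` (tibble of rank/name pairs seen in `tax`
#'   but absent from the map).
#' @export
standardize_taxonomy <- function(tax, name_map, quiet = FALSE) {
  tax <- validate_taxonomy(tax)
  stopifnot(all(c("rank", "source_name", "ncbi_name") %in% names(name_map)))
  bad_rank <- setdiff(unique(name_map$rank), tax_ranks())
  if (length(bad_rank) > 0) {
    abort(paste0("Unknown rank(s) in name map: ", paste(bad_rank, collapse = ", ")))
  }
  before <- do.call(paste, c(tax[tax_ranks()], sep = "\r"))
  n_resolved <- 0L
  unresolved <- list()
  for (r in intersect(unique(name_map$rank), tax_ranks())) {
    sub <- name_map[name_map$rank == r, ]
    key <- setNames(sub$ncbi_name, norm_taxon_name(sub$source_name))
    col <- tax[[r]]
    idx <- match(norm_taxon_name(col), names(key))
    hit <- !is.na(idx) & !is.na(col)
    n_resolved <- n_resolved + length(unique(col[hit]))
    tax[[r]] <- ifelse(hit, unname(key[idx]), col)
  }
  # names present in tax but never keyed in the map (per rank)
  for (r in tax_ranks()) {
    keys <- norm_taxon_name(name_map$source_name[name_map$rank == r])
    vals <- norm_taxon_name(name_map$ncbi_name[name_map$rank == r])
    nm <- unique(tax[[r]][!is.na(tax[[r]])])
    miss <- nm[!(norm_taxon_name(nm) %in% c(keys, vals))]
    if (length(miss) > 0) {
      unresolved[[r]] <- tibble::tibble(rank = r, name = miss)
    }
  }
  unresolved <- if (length(unresolved) > 0) {
    dplyr::bind_rows(unresolved)
  } else {
    tibble::tibble(rank = character(), name = character())
  }
  after <- do.call(paste, c(tax[tax_ranks()], sep = "\r"))
  new_dup <- duplicated(after) & !duplicated(before)
  collided <- after[after %in% after[new_dup]] |> unique()
  if (any(new_dup)) {
    abort(paste0(
      "Standardization collapsed distinct lineages onto the same name: ",
      paste(gsub("\r", " / ", head(collided, 3)), collapse = "; ")
    ))
  }
  if (!quiet) {
    inform(sprintf("standardize_taxonomy: %d name(s) resolved, %d left unresolved.",
                   n_resolved, nrow(unresolved)))
  }
  attr(tax, "n_resolved") <- n_resolved
  attr(tax, "n_unresolved") <- nrow(unresolved)
  attr(tax, "unresolved") <- unresolved
  tax
}

as_lineage_row <- function(query) {
  if (is.data.frame(query)) {
    if (nrow(query) != 1) abort("`query` must be a single lineage (one row).")
    query <- as.list(query)
  }
  query
}

#' Taxa carrying a given name at a given rank
#'
#' @param query A single lineage: one-row tibble or named list with rank
#'   entries.
#' @param target Taxonomy tibble to search.
#' @param rank One of [tax_ranks()].
#' @return Sorted character vector of matching taxon IDs (possibly empty).
#'   Queries unnamed at `rank` yield an empty set with a warning.
#' @export
candidates_at_rank <- function(query, target, rank) {
  rank <- match.arg(rank, tax_ranks())
  query <- as_lineage_row(query)
  target <- validate_taxonomy(target)
  qname <- query[[rank]]
  if (is.null(qname) || is.na(qname)) {
    warn(sprintf("Query lineage is unnamed at rank '%s'; returning no candidates.", rank))
    return(character(0))
  }
  hit <- !is.na(target[[rank]]) &
    norm_taxon_name(target[[rank]]) == norm_taxon_name(qname)
  sort(target$taxon_id[hit])
}

#' Rank-ladder candidate search
#'
#' Ascends species -> genus -> family -> order -> class -> phylum (capped at
#' `max_rank`) and returns the candidate set at the most specific rank where
#' the target table carries the query's name. Ranks at which the query is
#' unnamed are skipped. Absence at every rank is a valid result
#' (`matched_rank = NA`).
#'
#' @inheritParams candidates_at_rank
#' @param max_rank Most inclusive rank the ladder may reach (default
#'   `"phylum"`).
#' @return List with `matched_rank` (character or `NA`) and `candidates`
#'   (character vector of taxon IDs).
#' @export
rank_ladder_search <- function(query, target, max_rank = "phylum") {
  max_rank <- match.arg(max_rank, tax_ranks())
  query <- as_lineage_row(query)
  target <- validate_taxonomy(target)
  ladder <- rev(tax_ranks()) # species first
  ladder <- ladder[seq_len(which(ladder == max_rank))]
  for (r in ladder) {
    qname <- query[[r]]
    if (is.null(qname) || is.na(qname)) next
    cand <- suppressWarnings(candidates_at_rank(query, target, r))
    if (length(cand) > 0) {
      return(list(matched_rank = r, candidates = cand))
    }
  }
  list(matched_rank = NA_character_, candidates = character(0))
}

#' Census of rank-ladder matches for a signature
#'
#' Runs [rank_ladder_search()] for every signature lineage against a target
#' taxonomy and tabulates, per taxon, the matched rank and candidate-pool
#' size.
#'
#' @param signature Taxonomy-like tibble of signature lineages (`taxon_id` +
#'   rank columns).
#' @param target Target taxonomy tibble (e.g. the 16S table).
#' @param max_rank Ladder cap, see [rank_ladder_search()].
#' @return Tibble with `taxon_id`, `species`, `matched_rank` (factor ordered
#'   species -> phylum, `NA` = unmatched) and `n_candidates`.
#' @seealso [census_summary()]
#' @export
match_census <- function(signature, target, max_rank = "phylum") {
  signature <- validate_taxonomy(signature)
  target <- validate_taxonomy(target)
  res <- purrr::map(seq_len(nrow(signature)), function(i) {
    hit <- rank_ladder_search(signature[i, ], target, max_rank = max_rank)
    tibble::tibble(
      taxon_id = signature$taxon_id[i],
      species = signature$species[i],
      matched_rank = hit$matched_rank,
      n_candidates = length(hit$candidates)
    )
  })
  out <- dplyr::bind_rows(res)
  out$matched_rank <- factor(out$matched_rank, levels = rev(tax_ranks()))
  out
}

#' Summarize a match census by rank
#'
#' @param census Output of [match_census()].
#' @return Tibble with one row per matched rank (plus `unmatched` if any):
#'   `n`, `pct` (percentages sum to 100), and the median and range of the
#'   candidate-pool size.
#' @export
census_summary <- function(census) {
  total <- nrow(census)
  census$rank_chr <- ifelse(is.na(as.character(census$matched_rank)),
                            "unmatched", as.character(census$matched_rank))
  out <- census |>
    dplyr::group_by(.data$rank_chr) |>
    dplyr::summarise(
      n = dplyr::n(),
      pct = 100 * dplyr::n() / total,
      median_candidates = stats::median(.data$n_candidates),
      min_candidates = min(.data$n_candidates),
      max_candidates = max(.data$n_candidates),
      .groups = "drop"
    ) |>
    dplyr::rename(matched_rank = "rank_chr")
  lv <- c(rev(tax_ranks()), "unmatched")
  out[order(match(out$matched_rank, lv)), ]
}
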