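# Shared internal helpers: abundance tables <-> matrices, seeds, checks.

#' Canonical taxonomic ranks, most inclusive first
#'
#' @return Character vector `kingdom, phylum, class, order, family, genus,
#'   species`.
#' @export
tax_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

# Convert a wide abundance tibble (sample_id column + one column per taxon)
# or a matrix with rownames into a numeric matrix. All abundance-facing
# functions accept either form.
as_abundance_matrix <- function(x, arg = "x", require_counts = FALSE) {
  if (is.matrix(x)) {
    m <- x
    if (is.null(rownames(m))) {
      abort(sprintf("`%s` must have sample IDs as rownames.", arg))
    }
  } else if (is.data.frame(x)) {
    id_col <- if ("sample_id" %in% names(x)) "sample_id" else names(x)[1]
    vals <- x[setdiff(names(x), id_col)]
    m <- as.matrix(vals)
    rownames(m) <- as.character(x[[id_col]])
  } else {
    abort(sprintf("`%s` must be a data frame or a matrix.", arg))
  }
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m))) {
    abort(sprintf("`%s` has duplicated sample IDs.", arg))
  }
  if (anyDuplicated(colnames(m))) {
    abort(sprintf("`%s` has duplicated taxon IDs.", arg))
  }
  if (anyNA(m)) abort(sprintf("`%s` contains missing values.", arg))
  if (require_counts && any(m < 0)) {
    abort(sprintf("`%s` contains negative entries.", arg))
  }
  m
}

as_abundance_tbl <- function(m) {
  tibble::as_tibble(m, rownames = "sample_id")
}

# Set the RNG locally when a seed is given; leave the caller's stream alone
# otherwise.
local_seed_if <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(seed, .local_envir = env)
  invisible(NULL)
}

# Align two abundance matrices on an identical, identically ordered sample
# set; errors if the sample sets differ (paired samples are mandatory for
# profile distances).
align_paired_samples <- function(a, b) {
  if (!setequal(rownames(a), rownames(b))) {
    missing_a <- setdiff(rownames(b), rownames(a))
    missing_b <- setdiff(rownames(a), rownames(b))
    abort(paste0(
      "Sample sets differ between the two matrices; paired samples are ",
      "required. Missing from first: ",
      paste(head(missing_a, 5), collapse = ", "),
      "; missing from second: ",
      paste(head(missing_b, 5), collapse = ", ")
    ))
  }
  list(a = a, b = b[rownames(a), , drop = FALSE])
}

#' Read an abundance matrix from TSV/CSV (or BIOM)
#'
#' Expects samples in rows: first column (or a column named `sample_id`)
#' holds sample IDs, remaining columns are taxa. `.biom` files are read via
#' the biomformat package and transposed to samples-by-taxa.
#'
#' @param path File path; format chosen by extension (`.csv` vs `.tsv`/other;
#'   `.biom` if biomformat is installed).
#' @return A wide tibble with a `sample_id` column.
#' @export
read_abundance <- function(path) {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("Reading BIOM files requires the biomformat package.")
    }
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))
    return(as_abundance_tbl(m))
  }
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  x <- reader(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "sample_id"
  x
}

#' Write an abundance table to TSV
#'
#' @param x Wide abundance tibble or matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(x, path) {
  if (is.matrix(x)) x <- as_abundance_tbl(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a taxonomy table from TSV
#'
#' Columns `taxon_id, kingdom, phylum, class, order, family, genus, species`;
#' absent ranks are the literal `NA`.
#'
#' @param path File path.
#' @return A taxonomy tibble.
#' @export
read_taxonomy <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  validate_taxonomy(x)
}

#' Read sample metadata from TSV
#'
#' @param path File path; must contain a `sample_id` column.
#' @return A tibble.
#' @export
read_metadata <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(x)) names(x)[1] <- "sample_id"
  x
}
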