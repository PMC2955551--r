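#' Build a tidy genotype table
#'
#' The package's core container is an ordinary tibble in long form: one row
#' per (sample, locus) call, with the two allele codes of the diploid
#' genotype in `a1`/`a2` and per-sample metadata repeated along rows.
#' Genotypes are unordered pairs (no phase) of opaque integer allele codes,
#' typically microsatellite fragment sizes. A missing call has `NA` in both
#' allele columns; half-missing calls are rejected.
#'
#' @param sample_id character vector of sample identifiers.
#' @param locus character vector of locus names.
#' @param a1,a2 integer allele codes (both `NA` for a missing call).
#' @param population_label optional parental/reference population label.
#' @param declared_group optional self-declared ancestry label.
#' @param role `"reference"` or `"query"`; reference samples must carry a
#'   `population_label`.
#'
#' @return A validated genotype tibble with columns `sample_id`,
#'   `population_label`, `declared_group`, `role`, `locus`, `a1`, `a2`.
#' @export
#' @examples
#' genotype_tibble(
#'   sample_id = rep(c("s1", "s2"), each = 2),
#'   locus     = rep(c("L1", "L2"), 2),
#'   a1 = c(120L, 140L, 120L, 144L),
#'   a2 = c(124L, 140L, 124L, 140L),
#'   population_label = rep(c("popA", "popB"), each = 2)
#' )
genotype_tibble <- function(sample_id, locus, a1, a2,
                            population_label = NA_character_,
                            declared_group = NA_character_,
                            role = "reference") {
  g <- tibble::tibble(
    sample_id = as.character(sample_id),
    population_label = as.character(population_label),
    declared_group = as.character(declared_group),
    role = as.character(role),
    locus = as.character(locus),
    a1 = as.integer(a1),
    a2 = as.integer(a2)
  )
  validate_genotypes(g)
}

#' Validate a genotype table
#'
#' Checks the structural invariants of the long genotype tibble: required
#' columns, all-or-nothing missingness per call, one call per
#' (sample, locus), consistent per-sample metadata, and that reference
#' samples carry a population label.
#'
#' @param geno a genotype tibble (see [genotype_tibble()]).
#' @return `geno`, invisibly unchanged, as a tibble.
#' @export
validate_genotypes <- function(geno) {
  required <- c("sample_id", "locus", "a1", "a2")
  missing_cols <- setdiff(required, names(geno))
  if (length(missing_cols) > 0) {
    abort(paste0("genotype table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  geno <- tibble::as_tibble(geno)
  for (col in c("population_label", "declared_group")) {
    if (!col %in% names(geno)) geno[[col]] <- NA_character_
  }
  if (!"role" %in% names(geno)) geno$role <- "reference"

  half <- xor(is.na(geno$a1), is.na(geno$a2))
  if (any(half)) {
    abort(paste0("half-missing genotype call(s) at row(s) ",
                 paste(head(which(half), 5), collapse = ", "),
                 "; a missing call must blank both allele columns"))
  }
  dup <- duplicated(geno[, c("sample_id", "locus")])
  if (any(dup)) {
    abort("duplicated (sample_id, locus) call(s); one call per sample and locus")
  }
  meta <- dplyr::distinct(geno, .data$sample_id, .data$population_label,
                          .data$declared_group, .data$role)
  if (anyDuplicated(meta$sample_id)) {
    abort("inconsistent per-sample metadata: a sample_id maps to two labels")
  }
  bad_role <- !meta$role %in% c("reference", "query")
  if (any(bad_role)) abort("role must be 'reference' or 'query'")
  unlabelled <- meta$role == "reference" & is.na(meta$population_label)
  if (any(unlabelled)) {
    abort(paste0("reference sample(s) without population_label: ",
                 paste(head(meta$sample_id[unlabelled], 5), collapse = ", ")))
  }
  geno[, c("sample_id", "population_label", "declared_group", "role",
           "locus", "a1", "a2")]
}

#' Per-sample metadata of a genotype table
#'
#' @param geno a genotype tibble.
#' @return One row per sample: `sample_id`, `population_label`,
#'   `declared_group`, `role`.
#' @export
sample_metadata <- function(geno) {
  dplyr::distinct(tibble::as_tibble(geno), .data$sample_id,
                  .data$population_label, .data$declared_group, .data$role)
}

#' Observed alleles per locus
#'
#' @param geno a genotype tibble.
#' @return A tibble with one row per (locus, allele) observed anywhere in
#'   the data, allele codes sorted increasing within locus.
#' @export
locus_alleles <- function(geno) {
  tibble::as_tibble(geno) |>
    tidyr::pivot_longer(c("a1", "a2"), values_to = "allele") |>
    dplyr::filter(!is.na(.data$allele)) |>
    dplyr::distinct(.data$locus, .data$allele) |>
    dplyr::arrange(.data$locus, .data$allele)
}

#' Allele counts by population
#'
#' Tallies gene copies per (population, locus, allele), excluding missing
#' calls locus by locus. Counts sum to twice the number of non-missing
#' individuals for every population-locus combination.
#'
#' @param geno a genotype tibble.
#' @param by name of the grouping column, default `"population_label"`.
#' @return A tibble with columns `population`, `locus`, `allele`, `count`.
#' @export
#' @seealso [heterozygote_counts()] for the companion per-(population, locus)
#'   sample sizes and heterozygote tallies.
allele_counts <- function(geno, by = "population_label") {
  geno <- grouped_genotypes(geno, by)
  geno |>
    tidyr::pivot_longer(c("a1", "a2"), values_to = "allele") |>
    dplyr::filter(!is.na(.data$allele)) |>
    dplyr::count(.data$population, .data$locus, .data$allele,
                 name = "count") |>
    dplyr::arrange(.data$population, .data$locus, .data$allele)
}

#' Heterozygote and sample-size counts by population
#'
#' @inheritParams allele_counts
#' @return A tibble with columns `population`, `locus`, `n` (non-missing
#'   individuals) and `n_het` (observed heterozygotes among them).
#' @export
heterozygote_counts <- function(geno, by = "population_label") {
  geno <- grouped_genotypes(geno, by)
  geno |>
    dplyr::filter(!is.na(.data$a1)) |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(n = dplyr::n(),
                     n_het = sum(.data$a1 != .data$a2),
                     .groups = "drop")
}

# restrict to grouped samples and normalise the grouping column name
grouped_genotypes <- function(geno, by) {
  geno <- tibble::as_tibble(geno)
  if (!by %in% names(geno)) abort(paste0("no column '", by, "' to group by"))
  geno$population <- geno[[by]]
  geno <- dplyr::filter(geno, !is.na(.data$population))
  if (nrow(geno) == 0) abort("no samples carry a grouping label")
  empty <- geno |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(all_missing = all(is.na(.data$a1)), .groups = "drop") |>
    dplyr::filter(.data$all_missing)
  if (nrow(empty) > 0) {
    abort(paste0("population(s) with no observed genotypes: ",
                 paste(empty$population, collapse = ", ")))
  }
  geno
}
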