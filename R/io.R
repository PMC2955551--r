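#' Read genotypes in STRUCTURE two-row format
#'
#' Parses the two-row-per-individual text layout used by the Bayesian
#' clustering ecosystem: an optional header line of locus names, then two
#' lines per individual (one per allele copy), each line holding an optional
#' sample label, an optional population column, and one allele code per
#' locus. The canonical dialect written by [write_structure_file()] is
#' tab-separated with both leading columns and a locus-name header.
#'
#' @param path path to the text file.
#' @param label_col,pop_col does each data line start with a sample label /
#'   population column?
#' @param missing integer sentinel for a missing allele (default `-9`).
#' @param sep field separator (default tab; use `"[ \t]+"` regex via
#'   `whitespace = TRUE` for space-run-separated files).
#' @param whitespace if `TRUE`, split fields on any whitespace run.
#' @param loci locus names to use when the file has no header line; also
#'   checked against the header when both are present.
#' @param header does the first line carry locus names?
#' @return A genotype tibble (see [genotype_tibble()]); population labels
#'   read from the file, `role` set to `"reference"` where a population
#'   label is present and `"query"` otherwise.
#' @export
read_structure_file <- function(path, label_col = TRUE, pop_col = TRUE,
                                missing = -9L, sep = "\t",
                                whitespace = FALSE, loci = NULL,
                                header = TRUE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  split1 <- function(x) {
    if (whitespace) strsplit(trimws(x), "[ \t]+") else strsplit(x, sep, fixed = TRUE)
  }
  row0 <- 0L
  if (header) {
    if (length(lines) < 1) abort("empty file: no header line")
    file_loci <- split1(lines[1])[[1]]
    if (!is.null(loci) && !identical(as.character(loci), file_loci)) {
      abort("locus names in header do not match the supplied panel list")
    }
    loci <- file_loci
    row0 <- 1L
  }
  if (is.null(loci)) abort("locus names required: supply `loci` or a header line")
  loci <- as.character(loci)
  L <- length(loci)
  offset <- as.integer(label_col) + as.integer(pop_col)

  body <- lines[seq.int(row0 + 1L, length.out = length(lines) - row0)]
  toks <- lapply(body, function(x) split1(x)[[1]])
  ragged <- which(vapply(toks, length, 1L) != offset + L)
  if (length(ragged) > 0) {
    abort(paste0("ragged row at line ", row0 + ragged[1], ": expected ",
                 offset + L, " fields, found ", length(toks[[ragged[1]]])))
  }
  if (length(body) %% 2L != 0L) {
    abort(paste0("odd number of data lines (", length(body),
                 "): each individual needs exactly two rows"))
  }
  alle <- lapply(toks, function(tk) tk[(offset + 1L):(offset + L)])
  bad <- which(vapply(alle, function(a) !all(grepl("^-?[0-9]+$", a)), TRUE))
  if (length(bad) > 0) {
    tok <- alle[[bad[1]]][!grepl("^-?[0-9]+$", alle[[bad[1]]])][1]
    abort(paste0("unknown allele token '", tok, "' at line ", row0 + bad[1]))
  }

  n <- length(body) %/% 2L
  r1 <- seq(1L, by = 2L, length.out = n)
  ids <- if (label_col) vapply(toks, `[[`, "", 1L)[r1] else paste0("ind", seq_len(n))
  if (label_col) {
    ids2 <- vapply(toks, `[[`, "", 1L)[r1 + 1L]
    if (!identical(ids, ids2)) {
      abort("the two rows of an individual carry different sample labels")
    }
  }
  pops <- if (pop_col) {
    p <- vapply(toks, `[[`, "", 1L + as.integer(label_col))[r1]
    dplyr::na_if(p, "NA")
  } else rep(NA_character_, n)

  a_mat <- matrix(as.integer(unlist(alle)), nrow = length(body), ncol = L,
                  byrow = TRUE)
  a1 <- a_mat[r1, , drop = FALSE]
  a2 <- a_mat[r1 + 1L, , drop = FALSE]
  a1[a1 == missing] <- NA_integer_
  a2[a2 == missing] <- NA_integer_

  genotype_tibble(
    sample_id = rep(ids, each = L),
    locus = rep(loci, times = n),
    a1 = as.vector(t(a1)),
    a2 = as.vector(t(a2)),
    population_label = rep(pops, each = L),
    role = rep(ifelse(is.na(pops), "query", "reference"), each = L)
  )
}

#' Write genotypes in the canonical STRUCTURE dialect
#'
#' Tab-separated; a header line of locus names; two rows per individual,
#' each `sample_id`, `population_label`, then one allele per locus, with
#' missing alleles written as the sentinel. `read_structure_file()` on the
#' result round-trips token for token.
#'
#' @param geno a genotype tibble.
#' @param path output path.
#' @param missing integer sentinel to write for missing alleles.
#' @return `path`, invisibly.
#' @export
write_structure_file <- function(geno, path, missing = -9L) {
  geno <- validate_genotypes(geno)
  loci <- unique(geno$locus)
  meta <- sample_metadata(geno)
  wide <- geno |>
    dplyr::select("sample_id", "locus", "a1", "a2") |>
    tidyr::pivot_wider(names_from = "locus", values_from = c("a1", "a2"),
                       names_glue = "{locus}.{.value}")
  fmt <- function(x) {
    x <- as.integer(x)
    x[is.na(x)] <- as.integer(missing)
    as.character(x)
  }
  out <- character(2L * nrow(meta))
  pop <- ifelse(is.na(meta$population_label), "NA", meta$population_label)
  for (i in seq_len(nrow(meta))) {
    row <- wide[wide$sample_id == meta$sample_id[i], ]
    lead <- paste(meta$sample_id[i], pop[i], sep = "\t")
    out[2L * i - 1L] <- paste(c(lead, fmt(row[paste0(loci, ".a1")])), collapse = "\t")
    out[2L * i]      <- paste(c(lead, fmt(row[paste0(loci, ".a2")])), collapse = "\t")
  }
  writeLines(c(paste(loci, collapse = "\t"), out), path)
  invisible(path)
}

#' Read genotypes from a wide CSV
#'
#' One row per individual: `sample_id`, `population_label`, then two columns
#' per locus named `<locus>.1` and `<locus>.2`. The companion writer is
#' [write_genotype_csv()].
#'
#' @param path path to the CSV file.
#' @param missing integer sentinel for missing alleles.
#' @param panel optional character vector of expected locus names; a
#'   mismatch with the header is an error.
#' @return A genotype tibble.
#' @export
read_genotype_csv <- function(path, missing = -9L, panel = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          sample_id = readr::col_character(),
                          population_label = readr::col_character(),
                          .default = readr::col_integer()))
  ac <- grep("\\.[12]$", names(df), value = TRUE)
  loci <- unique(sub("\\.[12]$", "", ac))
  want <- as.vector(rbind(paste0(loci, ".1"), paste0(loci, ".2")))
  if (!all(want %in% names(df))) {
    abort("malformed header: every locus needs both <locus>.1 and <locus>.2")
  }
  if (!is.null(panel) && !setequal(loci, panel)) {
    abort("locus names in header do not match the supplied panel list")
  }
  long <- df |>
    tidyr::pivot_longer(dplyr::all_of(ac), names_to = c("locus", "copy"),
                        names_pattern = "(.*)\\.([12])", values_to = "allele") |>
    tidyr::pivot_wider(names_from = "copy", values_from = "allele",
                       names_prefix = "a")
  long$a1[long$a1 == missing] <- NA_integer_
  long$a2[long$a2 == missing] <- NA_integer_
  genotype_tibble(
    sample_id = long$sample_id,
    locus = long$locus,
    a1 = long$a1, a2 = long$a2,
    population_label = long$population_label,
    role = ifelse(is.na(long$population_label), "query", "reference")
  )
}

#' Write genotypes to a wide CSV
#'
#' @inheritParams write_structure_file
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(geno, path, missing = -9L) {
  geno <- validate_genotypes(geno)
  loci <- unique(geno$locus)
  wide <- geno |>
    dplyr::mutate(a1 = ifelse(is.na(.data$a1), as.integer(missing), .data$a1),
                  a2 = ifelse(is.na(.data$a2), as.integer(missing), .data$a2)) |>
    dplyr::select("sample_id", "population_label", "locus", "a1", "a2") |>
    tidyr::pivot_wider(names_from = "locus", values_from = c("a1", "a2"),
                       names_glue = "{locus}.{ifelse(.value == 'a1', 1, 2)}")
  ord <- c("sample_id", "population_label",
           as.vector(rbind(paste0(loci, ".1"), paste0(loci, ".2"))))
  readr::write_csv(wide[, ord], path, na = "")
  invisible(path)
}

#' Read a sample-metadata CSV
#'
#' Columns `sample_id`, `population_label`, `declared_group`, `role`.
#'
#' @param path path to the CSV file.
#' @return A metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  need <- c("sample_id", "population_label", "declared_group", "role")
  if (!all(need %in% names(m))) {
    abort(paste0("metadata CSV needs columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(m$sample_id)) abort("duplicate sample_id in metadata")
  tibble::as_tibble(m[, need])
}

#' Attach external metadata to a genotype table
#'
#' Replaces the metadata columns of `geno` with those of `meta`, matching
#' on `sample_id`.
#'
#' @param geno a genotype tibble.
#' @param meta a metadata tibble from [read_sample_metadata()].
#' @return The genotype tibble with updated metadata, re-validated.
#' @export
attach_metadata <- function(geno, meta) {
  geno <- tibble::as_tibble(geno)
  missing_ids <- setdiff(unique(geno$sample_id), meta$sample_id)
  if (length(missing_ids) > 0) {
    abort(paste0("metadata lacks sample(s): ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  out <- geno |>
    dplyr::select(-dplyr::any_of(c("population_label", "declared_group", "role"))) |>
    dplyr::left_join(meta, by = "sample_id")
  validate_genotypes(out)
}
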