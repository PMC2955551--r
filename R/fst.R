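#' Weir-Cockerham variance components and theta for one locus
#'
#' Computes the moment estimator of F_st for a single multi-allelic locus
#' from per-population counts. For each allele u the estimator forms the
#' among-population (`a`), among-individual-within-population (`b`) and
#' within-individual (`c`) variance components from the weighted allele
#' frequency mean and variance and the frequency of heterozygotes carrying
#' that allele; theta is the ratio of sums over alleles,
#' `sum(a) / sum(a + b + c)`. The estimator is unbiased rather than
#' range-constrained: estimates can fall slightly below zero and are
#' reported as computed.
#'
#' @param counts population x allele matrix of gene-copy counts (rownames =
#'   populations, colnames = allele codes).
#' @param het population x allele matrix: number of individuals in each
#'   population heterozygous at this locus whose genotype carries the
#'   allele. (At a biallelic locus both columns equal the per-population
#'   heterozygote count.)
#' @param n vector of non-missing individuals per population.
#' @return A list of class `fst_components`: `components`, a tibble with one
#'   row per allele (columns `allele`, `nbar`, `nc`, `pbar`, `s2`, `hbar`,
#'   `a`, `b`, `c`), `theta` (the per-locus estimate, `NaN` when the locus
#'   is monomorphic), and `r` (number of populations).
#' @export
#' @examples
#' cnt <- rbind(p1 = c(18, 2), p2 = c(2, 18))
#' het <- rbind(p1 = c(2, 2), p2 = c(2, 2))
#' locus_theta(cnt, het, n = c(p1 = 10, p2 = 10))$theta
locus_theta <- function(counts, het, n) {
  counts <- as.matrix(counts)
  het <- as.matrix(het)
  n <- as.numeric(n)
  r <- nrow(counts)
  if (r < 2) abort("locus_theta needs at least 2 populations")
  if (any(n < 1)) abort("every population needs at least 2 gene copies (n >= 1)")
  stopifnot(nrow(het) == r, ncol(het) == ncol(counts), length(n) == r)

  nbar <- mean(n)
  if (nbar <= 1) abort("mean sample size nbar <= 1: components undefined")
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)

  p <- counts / (2 * n)         # population allele frequencies, rows recycle n
  h <- het / n                  # per-allele heterozygote frequencies
  per_allele <- purrr::map_dfr(seq_len(ncol(counts)), function(u) {
    pbar <- sum(n * p[, u]) / (r * nbar)
    s2 <- sum(n * (p[, u] - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h[, u]) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    tibble::tibble(allele = colnames(counts)[u] %||% as.character(u),
                   nbar = nbar, nc = nc, pbar = pbar, s2 = s2, hbar = hbar,
                   a = a, b = b, c = cc)
  })
  denom <- sum(per_allele$a + per_allele$b + per_allele$c)
  theta <- if (denom == 0) NaN else sum(per_allele$a) / denom
  structure(list(components = per_allele, theta = theta, r = r),
            class = "fst_components")
}

# per-locus count matrices (counts, per-allele het counts, n) for one locus,
# restricted to populations with data at that locus
locus_count_matrices <- function(geno_locus) {
  obs <- geno_locus[!is.na(geno_locus$a1), ]
  pops <- sort(unique(obs$population))
  alleles <- sort(unique(c(obs$a1, obs$a2)))
  cnt <- matrix(0, length(pops), length(alleles),
                dimnames = list(pops, alleles))
  het <- cnt
  pi_ <- match(obs$population, pops)
  i1 <- match(obs$a1, alleles); i2 <- match(obs$a2, alleles)
  for (k in seq_len(nrow(obs))) {
    cnt[pi_[k], i1[k]] <- cnt[pi_[k], i1[k]] + 1
    cnt[pi_[k], i2[k]] <- cnt[pi_[k], i2[k]] + 1
    if (i1[k] != i2[k]) {
      het[pi_[k], i1[k]] <- het[pi_[k], i1[k]] + 1
      het[pi_[k], i2[k]] <- het[pi_[k], i2[k]] + 1
    }
  }
  n <- as.numeric(table(factor(obs$population, levels = pops)))
  list(counts = cnt, het = het, n = setNames(n, pops))
}

#' Multi-locus Weir-Cockerham F_st
#'
#' Estimates theta across all loci as a ratio of sums: the variance
#' components of every (locus, allele) pair are summed before the ratio is
#' taken (never averaged per-locus ratios). Loci monomorphic across the
#' grouped populations, or observed in fewer than two populations, are
#' flagged uninformative and excluded from the sums. Per-population sample
#' sizes are per-locus non-missing counts, so missing data reweight each
#' locus as in the cited estimator.
#'
#' @param geno a genotype tibble.
#' @param by grouping column, default `"population_label"`; samples with
#'   `NA` in this column are ignored.
#' @return An object of class `fst_result` with elements `theta`
#'   (multi-locus estimate), `per_locus` (tibble: `locus`, `theta`,
#'   `informative`), `populations`, and `by`. Use [tidy()] for the
#'   per-locus table and [glance()] for the one-row summary.
#' @export
#' @examples
#' g <- sim_dataset(sim_config(k = 2, loci = 8, n_ref = 30, fst = 0.2,
#'                             seed = 1))$genotypes
#' fst_global(g)$theta
fst_global <- function(geno, by = "population_label") {
  geno <- grouped_genotypes(validate_genotypes(geno), by)
  pops <- sort(unique(geno$population))
  if (length(pops) < 2) abort("F_st needs at least 2 populations")

  per_locus <- geno |>
    dplyr::group_by(.data$locus) |>
    dplyr::group_map(function(gl, key) {
      mats <- locus_count_matrices(gl)
      ok <- nrow(mats$counts) >= 2 && ncol(mats$counts) >= 2 &&
        mean(mats$n) > 1
      if (!ok) {
        return(tibble::tibble(locus = key$locus, theta = NA_real_,
                              a = 0, abc = 0, informative = FALSE))
      }
      lt <- locus_theta(mats$counts, mats$het, mats$n)
      a_sum <- sum(lt$components$a)
      abc_sum <- sum(lt$components$a + lt$components$b + lt$components$c)
      tibble::tibble(locus = key$locus, theta = lt$theta,
                     a = a_sum, abc = abc_sum,
                     informative = is.finite(lt$theta))
    }) |>
    dplyr::bind_rows()

  used <- per_locus[per_locus$informative, ]
  if (nrow(used) == 0) abort("no informative loci: F_st undefined")
  theta <- sum(used$a) / sum(used$abc)
  structure(list(
    theta = theta,
    per_locus = per_locus[, c("locus", "theta", "informative")],
    populations = pops,
    loci_used = used$locus,
    by = by
  ), class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("Multi-locus Weir-Cockerham F_st\n")
  cat("  populations:", paste(x$populations, collapse = ", "), "\n")
  cat(sprintf("  loci: %d used of %d\n", length(x$loci_used),
              nrow(x$per_locus)))
  cat(sprintf("  theta = %.4f\n", x$theta))
  invisible(x)
}

#' @method tidy fst_result
#' @export
tidy.fst_result <- function(x, ...) x$per_locus

#' @method glance fst_result
#' @export
glance.fst_result <- function(x, ...) {
  tibble::tibble(theta = x$theta,
                 n_loci = nrow(x$per_locus),
                 n_loci_used = length(x$loci_used),
                 n_populations = length(x$populations))
}

#' Pairwise F_st between all population pairs
#'
#' For each pair of populations, the multi-locus theta is recomputed on the
#' samples of that pair alone; loci monomorphic within a pair drop out of
#' that pair's sums. Estimates are reported as computed (identical
#' populations give values at or slightly below zero).
#'
#' @inheritParams fst_global
#' @return An object of class `fst_pairwise`: `pairs`, a tibble with
#'   columns `pop_a`, `pop_b`, `theta` (one row per unordered pair), and
#'   `populations`. `as.matrix()` gives the symmetric matrix with an `NA`
#'   diagonal; [tidy()] returns the pair tibble.
#' @export
fst_pairwise <- function(geno, by = "population_label") {
  geno <- grouped_genotypes(validate_genotypes(geno), by)
  pops <- sort(unique(geno$population))
  if (length(pops) < 2) abort("pairwise F_st needs at least 2 populations")
  pairs <- tibble::as_tibble(t(combn(pops, 2)), .name_repair = ~c("pop_a", "pop_b"))
  pairs$theta <- purrr::map2_dbl(pairs$pop_a, pairs$pop_b, function(a, b) {
    sub <- geno[geno$population %in% c(a, b), ]
    fst_global(sub, by = by)$theta
  })
  structure(list(pairs = pairs, populations = pops, by = by),
            class = "fst_pairwise")
}

#' @export
as.matrix.fst_pairwise <- function(x, ...) {
  pops <- x$populations
  m <- matrix(NA_real_, length(pops), length(pops),
              dimnames = list(pops, pops))
  idx_a <- match(x$pairs$pop_a, pops)
  idx_b <- match(x$pairs$pop_b, pops)
  m[cbind(idx_a, idx_b)] <- x$pairs$theta
  m[cbind(idx_b, idx_a)] <- x$pairs$theta
  m
}

#' @method tidy fst_pairwise
#' @export
tidy.fst_pairwise <- function(x, ...) x$pairs

#' @export
print.fst_pairwise <- function(x, ...) {
  cat("Pairwise multi-locus F_st (", length(x$populations),
      " populations)\n", sep = "")
  print(round(as.matrix(x), 3))
  invisible(x)
}
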