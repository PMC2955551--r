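#' Re-code multi-allelic genotypes as binary "false SNP" columns
#'
#' Each (locus, allele) pair becomes one binary column scoring the
#' presence (1) or absence (0) of that allele in the individual's diploid
#' genotype — the standard trick for feeding multi-allelic markers to
#' SNP-oriented PCA. A missing call masks all of that locus's columns
#' (`NA`) for the individual. Set `dosage = TRUE` to count allele copies
#' (0/1/2) instead, for sensitivity checks.
#'
#' @param geno a genotype tibble.
#' @param dosage count copies instead of presence/absence?
#' @return An object of class `false_snp`: `x`, the samples x columns
#'   numeric matrix (rownames sample ids, colnames `"locus:allele"`), and
#'   `columns`, a tibble mapping columns to `locus` and `allele`.
#' @export
#' @examples
#' g <- genotype_tibble(sample_id = c("s1", "s1"), locus = c("L1", "L2"),
#'                      a1 = c(120L, 100L), a2 = c(124L, 100L),
#'                      population_label = "p")
#' recode_false_snp(g)$x
recode_false_snp <- function(geno, dosage = FALSE) {
  geno <- validate_genotypes(geno)
  samples <- unique(geno$sample_id)
  cols <- locus_alleles(geno)
  key <- paste(cols$locus, cols$allele, sep = ":")
  x <- matrix(NA_real_, length(samples), nrow(cols),
              dimnames = list(samples, key))
  obs <- geno[!is.na(geno$a1), ]
  # observed loci start at 0 in every column of that locus, then score alleles
  loc_cols <- split(seq_len(nrow(cols)), cols$locus)
  si <- match(obs$sample_id, samples)
  for (l in names(loc_cols)) {
    rows <- which(obs$locus == l)
    x[cbind(rep(si[rows], each = length(loc_cols[[l]])),
            rep(loc_cols[[l]], times = length(rows)))] <- 0
  }
  j1 <- match(paste(obs$locus, obs$a1, sep = ":"), key)
  j2 <- match(paste(obs$locus, obs$a2, sep = ":"), key)
  if (dosage) {
    for (r in seq_along(si)) {
      x[si[r], j1[r]] <- x[si[r], j1[r]] + 1
      x[si[r], j2[r]] <- x[si[r], j2[r]] + 1
    }
  } else {
    x[cbind(si, j1)] <- 1
    x[cbind(si, j2)] <- 1
  }
  structure(list(x = x, columns = cols), class = "false_snp")
}

#' @export
print.false_snp <- function(x, ...) {
  cat("False-SNP matrix:", nrow(x$x), "samples x", ncol(x$x),
      "(locus, allele) columns\n")
  invisible(x)
}

#' PCA of a false-SNP matrix
#'
#' Masked entries are imputed to their column mean, columns are
#' mean-centered, and (optionally) scaled by `1 / sqrt(p * (1 - p))` with
#' `p` the column carrier frequency, dropping monomorphic columns. The
#' spectral decomposition of the individual-by-individual covariance gives
#' the coordinates; each PC's variance fraction is its eigenvalue over the
#' trace, so the fractions over all PCs sum to 1.
#'
#' @param x a [recode_false_snp()] object or a numeric samples x columns
#'   matrix (NA = masked).
#' @param normalize scale columns by the binomial standard deviation?
#' @param n_pcs number of PCs to report coordinates for.
#' @return An object of class `pca_result`: `scores` (tibble: `sample_id`,
#'   `PC1..PCn`), `eigenvalues` (all), `var_frac` (all; sums to 1), and
#'   `n_pcs`. [tidy()] returns the scores, [glance()] the leading variance
#'   fractions.
#' @export
run_pca <- function(x, normalize = FALSE, n_pcs = 10) {
  m <- if (inherits(x, "false_snp")) x$x else as.matrix(x)
  if (nrow(m) < 2) abort("PCA needs at least 2 individuals")
  if (is.null(rownames(m))) rownames(m) <- paste0("ind", seq_len(nrow(m)))
  mu <- colMeans(m, na.rm = TRUE)
  for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- mu[j]
  keep <- rep(TRUE, ncol(m))
  if (normalize) {
    p <- mu
    keep <- p > 0 & p < 1
    if (!any(keep)) abort("all columns monomorphic: nothing to analyze")
  }
  mc <- sweep(m[, keep, drop = FALSE], 2, mu[keep])
  if (normalize) mc <- sweep(mc, 2, sqrt(mu[keep] * (1 - mu[keep])), "/")
  if (all(abs(mc) < 1e-12)) abort("all columns monomorphic: nothing to analyze")
  eg <- eigen(tcrossprod(mc), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  vf <- ev / sum(ev)
  n_pcs <- min(n_pcs, length(ev))
  sc <- eg$vectors[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(n_pcs)]), n_pcs)
  scores <- tibble::as_tibble(sc, .name_repair = ~paste0("PC", seq_len(n_pcs)))
  scores <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)), scores)
  structure(list(scores = scores, eigenvalues = ev, var_frac = vf,
                 n_pcs = n_pcs, normalized = normalize),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA of false-SNP genotypes:", nrow(x$scores), "samples\n")
  shown <- head(x$var_frac, min(3, x$n_pcs))
  cat("  variance fractions:",
      paste(sprintf("PC%d %.1f%%", seq_along(shown), 100 * shown),
            collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy pca_result
#' @export
tidy.pca_result <- function(x, ...) x$scores

#' @method glance pca_result
#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(pc1_var = x$var_frac[1],
                 pc2_var = if (length(x$var_frac) > 1) x$var_frac[2] else NA_real_,
                 n_pcs = x$n_pcs)
}
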