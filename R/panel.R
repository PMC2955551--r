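#' Select loci whose per-locus F_st clears a threshold
#'
#' The first stage of building an ancestry-informative panel: keep every
#' locus whose global per-locus theta is at or above the threshold
#' (inclusive), sorted by decreasing theta with ties broken by locus name.
#'
#' @param per_locus tibble with columns `locus` and `theta` (e.g.
#'   `tidy(fst_global(...))`), or an `fst_result`.
#' @param threshold minimum theta, default 0.1.
#' @return A panel tibble (`locus`, `theta`) of class `panel_candidate`,
#'   with a `provenance` attribute; empty (with a warning) when nothing
#'   clears the threshold.
#' @export
threshold_filter <- function(per_locus, threshold = 0.1) {
  if (inherits(per_locus, "fst_result")) per_locus <- tidy(per_locus)
  if (anyNA(per_locus$theta)) {
    per_locus <- per_locus[!is.na(per_locus$theta), ]
  }
  out <- per_locus[per_locus$theta >= threshold, c("locus", "theta")]
  out <- dplyr::arrange(out, dplyr::desc(.data$theta), .data$locus)
  if (nrow(out) == 0) warn("no locus clears the threshold: empty panel")
  structure(tibble::as_tibble(out), class = c("panel_candidate",
                                              class(tibble::tibble())),
            provenance = sprintf("threshold >= %g", threshold))
}

#' Step-wise reduction of a marker panel
#'
#' Mirrors the cascade used to distil large candidate sets into compact
#' panels: at each target size, per-locus global theta is recomputed on the
#' current panel's loci and the top-N loci by theta are retained (ties by
#' locus name). Each step emits a [evaluate_panel()] report. Output panels
#' are nested: every step's panel is a subset of the previous one.
#'
#' @param geno a genotype tibble.
#' @param panel a `panel_candidate` (or tibble with a `locus` column).
#' @param target_sizes strictly decreasing panel sizes, each no larger
#'   than the current panel.
#' @param by grouping column for theta.
#' @param evaluate compute a pairwise-F_st report per step?
#' @return An object of class `panel_reduction`: `panels`, a named list of
#'   `panel_candidate` tibbles (one per target size), and `reports`, the
#'   per-step [evaluate_panel()] reports (when `evaluate`).
#' @export
stepwise_reduce <- function(geno, panel, target_sizes,
                            by = "population_label", evaluate = TRUE) {
  geno <- validate_genotypes(geno)
  loci <- panel$locus
  target_sizes <- as.integer(target_sizes)
  if (any(diff(target_sizes) >= 0)) {
    abort("target_sizes must be strictly decreasing")
  }
  panels <- list(); reports <- list()
  for (tg in target_sizes) {
    if (tg > length(loci)) {
      abort(sprintf("target size %d exceeds current panel size %d",
                    tg, length(loci)))
    }
    sub <- geno[geno$locus %in% loci, ]
    per_locus <- tidy(fst_global(sub, by = by))
    per_locus <- dplyr::arrange(per_locus, dplyr::desc(.data$theta),
                                .data$locus)
    step <- per_locus[seq_len(tg), c("locus", "theta")]
    step <- structure(tibble::as_tibble(step),
                      class = c("panel_candidate", class(tibble::tibble())),
                      provenance = sprintf("reduced to %d", tg))
    loci <- step$locus
    panels[[as.character(tg)]] <- step
    if (evaluate) {
      reports[[as.character(tg)]] <- evaluate_panel(geno, step, by = by)
    }
  }
  structure(list(panels = panels, reports = reports),
            class = "panel_reduction")
}

#' Evaluate a marker panel
#'
#' Computes the pairwise F_st matrix on the panel's loci, and optionally a
#' clustering K sweep and a false-SNP PCA, summarizing how much
#' population-distinguishing signal the panel retains.
#'
#' @param geno a genotype tibble.
#' @param panel tibble with a `locus` column.
#' @param by grouping column.
#' @param k_sweep `NULL`, or a list of arguments to [run_k_sweep()]
#'   (e.g. `list(k_range = 1:6, replicates = 3, seed = 1, burn_in = 500,
#'   iterations = 500)`).
#' @param pca also run [run_pca()] on the panel?
#' @return An object of class `panel_report`: `size`, `pairwise` (an
#'   `fst_pairwise`), `best_k` (or `NA`), `pca_var_frac` (or `NULL`).
#' @export
evaluate_panel <- function(geno, panel, by = "population_label",
                           k_sweep = NULL, pca = FALSE) {
  geno <- validate_genotypes(geno)
  sub <- geno[geno$locus %in% panel$locus, ]
  if (nrow(sub) == 0) abort("panel loci absent from the genotype table")
  pw <- fst_pairwise(sub, by = by)
  best_k <- NA_integer_
  if (!is.null(k_sweep)) {
    sw <- do.call(run_k_sweep, c(list(geno = sub), k_sweep))
    best_k <- delta_k(sw)$best_k
  }
  pca_vf <- NULL
  if (pca) pca_vf <- run_pca(recode_false_snp(sub))$var_frac
  structure(list(size = nrow(panel), pairwise = pw, best_k = best_k,
                 pca_var_frac = pca_vf),
            class = "panel_report")
}

#' @export
print.panel_report <- function(x, ...) {
  cat("Panel of", x$size, "loci\n")
  print(x$pairwise)
  if (!is.na(x$best_k)) cat("best K:", x$best_k, "\n")
  if (!is.null(x$pca_var_frac)) {
    cat(sprintf("PC1/PC2 variance: %.1f%% / %.1f%%\n",
                100 * x$pca_var_frac[1], 100 * x$pca_var_frac[2]))
  }
  invisible(x)
}
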