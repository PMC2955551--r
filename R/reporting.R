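#' Summarize inferred ancestry proportions by declared group
#'
#' For every (declared group, ancestry) pair: mean, sd, median,
#' interquartile range (25th-75th), 10th and 90th percentiles, and group
#' size — the cohort-level view of admixture estimates for self-declared
#' cohorts.
#'
#' @param props labelled proportions tibble (`sample_id`, `ancestry`,
#'   `proportion`), e.g. from [labelled_proportions()].
#' @param meta metadata tibble with `sample_id` and the grouping column.
#' @param group metadata column to summarize by (default
#'   `"declared_group"`); samples with `NA` are dropped.
#' @return A tibble: `group`, `ancestry`, `mean`, `sd`, `median`, `q25`,
#'   `q75`, `p10`, `p90`, `n`.
#' @export
summarize_groups <- function(props, meta, group = "declared_group") {
  joined <- dplyr::inner_join(props, meta[, c("sample_id", group)],
                              by = "sample_id")
  joined$group <- joined[[group]]
  joined <- joined[!is.na(joined$group), ]
  if (nrow(joined) == 0) abort("no samples carry the grouping label")
  joined |>
    dplyr::group_by(.data$group, .data$ancestry) |>
    dplyr::summarise(
      mean = mean(.data$proportion),
      sd = sd(.data$proportion),
      median = median(.data$proportion),
      q25 = quantile(.data$proportion, 0.25, names = FALSE),
      q75 = quantile(.data$proportion, 0.75, names = FALSE),
      p10 = quantile(.data$proportion, 0.10, names = FALSE),
      p90 = quantile(.data$proportion, 0.90, names = FALSE),
      n = dplyr::n(),
      .groups = "drop")
}

#' Welch t-test of an ancestry proportion between two groups
#'
#' Compares the per-individual inferred proportions of one ancestry
#' between two declared groups with the unequal-variance two-sample
#' t-test. When both groups are constant with equal means the comparison
#' carries no evidence: `t = 0`, `p = 1`, flagged `degenerate`.
#'
#' @inheritParams summarize_groups
#' @param group_a,group_b the two group labels to compare.
#' @param ancestry the ancestry label whose proportions are compared.
#' @return A one-row tibble: `ancestry`, `group_a`, `group_b`, `mean_a`,
#'   `mean_b`, `n_a`, `n_b`, `statistic`, `p_value`, `degenerate`.
#' @export
compare_groups <- function(props, meta, group_a, group_b, ancestry,
                           group = "declared_group") {
  joined <- dplyr::inner_join(props, meta[, c("sample_id", group)],
                              by = "sample_id")
  joined$group <- joined[[group]]
  joined <- joined[joined$ancestry == ancestry &
                     joined$group %in% c(group_a, group_b), ]
  xa <- joined$proportion[joined$group == group_a]
  xb <- joined$proportion[joined$group == group_b]
  if (length(xa) < 2 || length(xb) < 2) {
    abort("both groups need at least 2 individuals")
  }
  degenerate <- sd(xa) == 0 && sd(xb) == 0
  if (degenerate) {
    if (mean(xa) != mean(xb)) {
      abort("zero variance in both groups with unequal means: t undefined")
    }
    stat <- 0; pval <- 1
  } else {
    tt <- t.test(xa, xb, var.equal = FALSE)
    stat <- unname(tt$statistic); pval <- tt$p.value
  }
  tibble::tibble(ancestry = ancestry, group_a = group_a, group_b = group_b,
                 mean_a = mean(xa), mean_b = mean(xb),
                 n_a = length(xa), n_b = length(xb),
                 statistic = stat, p_value = pval, degenerate = degenerate)
}

#' Flag samples whose genetic ancestry contradicts their declared group
#'
#' A sample is flagged when its dominant inferred ancestry reaches the
#' cutoff *and* differs from the ancestry its declared group maps to —
#' the pattern of a mislabelled biospecimen (e.g. a sample declared in one
#' group showing near-total ancestry from another).
#'
#' @inheritParams summarize_groups
#' @param mapping named character vector: declared group -> expected
#'   ancestry label. Groups absent from the mapping are never flagged.
#' @param cutoff dominant-proportion threshold (default 0.95).
#' @return A tibble of flags: `sample_id`, `declared_group`,
#'   `dominant_ancestry`, `dominant_proportion` (empty when nothing is
#'   discordant).
#' @export
flag_discordant <- function(props, meta, mapping, cutoff = 0.95) {
  dom <- props |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::arrange(dplyr::desc(.data$proportion), .data$ancestry,
                   .by_group = TRUE) |>
    dplyr::summarise(dominant_ancestry = .data$ancestry[1],
                     dominant_proportion = .data$proportion[1],
                     .groups = "drop")
  dom <- dplyr::inner_join(dom, meta[, c("sample_id", "declared_group")],
                           by = "sample_id")
  dom <- dom[!is.na(dom$declared_group) &
               dom$declared_group %in% names(mapping), ]
  expected <- unname(mapping[dom$declared_group])
  out <- dom[dom$dominant_proportion >= cutoff &
               dom$dominant_ancestry != expected, ]
  out[, c("sample_id", "declared_group", "dominant_ancestry",
          "dominant_proportion")]
}

#' Run the full ancestry pipeline on a simulated dataset
#'
#' End-to-end orchestration: simulate genotypes, estimate global and
#' pairwise F_st, optionally reduce the panel, sweep K with replicates,
#' pick K by delta-K, refit replicates at the chosen K, align and average
#' them, label clusters by the reference panels, run the false-SNP PCA,
#' and summarize cohort ancestry proportions. Deterministic given
#' `master_seed`.
#'
#' @param sim a [sim_config()] (simulated input) or a `sim_dataset`.
#' @param k_range K values for the sweep (`NULL` skips selection and uses
#'   `k_fixed`).
#' @param k_fixed K to use when `k_range` is `NULL`; defaults to the
#'   simulation's true K.
#' @param replicates replicate runs per K.
#' @param burn_in,iterations MCMC size for every run.
#' @param master_seed seed from which all run seeds derive.
#' @param panel_sizes optional decreasing sizes for [stepwise_reduce()].
#' @param discordance_cutoff cutoff for [flag_discordant()]; cohort labels
#'   map to the ancestry with the largest true mean, for flagging.
#' @return A list of class `pipeline_result`: `genotypes`, `meta`, `fst`,
#'   `pairwise`, `panels`, `sweep`, `delta_k`, `best_k`, `alignment`,
#'   `labels`, `proportions`, `pca`, `summary`, `flags`, `master_seed`.
#' @export
run_pipeline <- function(sim, k_range = NULL, k_fixed = NULL,
                         replicates = 3, burn_in = 1000, iterations = 1000,
                         master_seed = 1, panel_sizes = NULL,
                         discordance_cutoff = 0.95) {
  ds <- if (inherits(sim, "sim_dataset")) sim else sim_dataset(sim)
  geno <- ds$genotypes
  meta <- sample_metadata(geno)

  fst <- fst_global(geno)
  pairwise <- fst_pairwise(geno)
  panels <- NULL
  if (!is.null(panel_sizes)) {
    full <- threshold_filter(fst, threshold = -Inf)
    panels <- stepwise_reduce(geno, full, panel_sizes)
    geno <- geno[geno$locus %in%
                   panels$panels[[length(panels$panels)]]$locus, ]
  }

  sweep <- NULL; dk <- NULL
  if (!is.null(k_range)) {
    sweep <- run_k_sweep(geno, k_range, replicates = replicates,
                         seed = master_seed, burn_in = burn_in,
                         iterations = iterations)
    dk <- delta_k(sweep)
    best_k <- dk$best_k
    if (is.na(best_k)) abort("delta-K left K unresolved; widen the sweep")
  } else {
    best_k <- as.integer(k_fixed %||% ds$config$k)
  }

  fits <- purrr::map(seq_len(replicates), function(r) {
    run_admixture(geno, config = admixture_config(
      best_k, burn_in = burn_in, iterations = iterations,
      seed = as.integer(master_seed + 10007L * best_k + 101L * r)))
  })
  aln <- align_runs(fits)
  avg_fit <- fits[[1]]
  avg_fit$Q[, -1] <- tibble::as_tibble(aln$average)
  labels <- label_clusters_by_reference(avg_fit, meta)
  props <- labelled_proportions(avg_fit, meta)

  pca <- run_pca(recode_false_snp(geno))
  summary <- if (any(!is.na(meta$declared_group))) {
    summarize_groups(props, meta)
  } else NULL

  flags <- NULL
  if (length(ds$config$cohorts) > 0) {
    mapping <- vapply(ds$config$cohorts, function(co) {
      law <- co$q %||% (co$alpha / sum(co$alpha))
      ds$config$pop_names[which.max(law)]
    }, "")
    names(mapping) <- vapply(ds$config$cohorts, `[[`, "", "label")
    flags <- flag_discordant(props, meta, mapping,
                             cutoff = discordance_cutoff)
  }

  structure(list(genotypes = geno, meta = meta, fst = fst,
                 pairwise = pairwise, panels = panels, sweep = sweep,
                 delta_k = dk, best_k = best_k, alignment = aln,
                 fits = fits, labels = labels, proportions = props,
                 pca = pca, summary = summary, flags = flags,
                 master_seed = master_seed),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Ancestry pipeline result\n")
  cat(sprintf("  multi-locus F_st: %.3f\n", x$fst$theta))
  cat("  chosen K:", x$best_k, "\n")
  if (!is.null(x$summary)) {
    cat("  cohort summaries for",
        dplyr::n_distinct(x$summary$group), "group(s)\n")
  }
  if (!is.null(x$flags) && nrow(x$flags) > 0) {
    cat("  discordant samples flagged:", nrow(x$flags), "\n")
  }
  invisible(x)
}
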