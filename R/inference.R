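#' PERMANOVA: permutational multivariate ANOVA on a distance matrix
#'
#' Partitions the total sum of squared dissimilarities sequentially by the
#' terms of `formula` (type-I sums of squares, in the order written) and
#' tests each pseudo-F against a permutation null. With repeated measures,
#' pass `strata` (e.g. host id) to permute labels only within strata.
#'
#' @param dm A `dist` object.
#' @param formula Right-hand-side formula over columns of `data`,
#'   e.g. `~ timepoint + breed`.
#' @param data data.frame aligned with the samples of `dm`.
#' @param n_perm Number of permutations (default 10000).
#' @param strata Optional factor restricting permutations within its levels.
#' @param seed Optional integer seed.
#' @return data.frame of class `permutation_test` with one row per term
#'   plus `Residual` and `Total`: columns `term`, `df`, `ss`, `r2`
#'   (effect size, SS_term / SS_total), `statistic` (pseudo-F), `p_value`.
#' @export
permanova <- function(dm, formula, data, n_perm = 10000, strata = NULL,
                      seed = NULL) {
  data <- as.data.frame(data)
  for (v in all.vars(formula)) {
    x <- data[[v]]
    if (is.null(x)) stop("term '", v, "' not found in data")
    if ((is.factor(x) || is.character(x)) && length(unique(x)) < 2)
      stop("term '", v, "' has a single level")
  }
  if (!is.null(seed)) set.seed(seed)
  f <- stats::as.formula(paste("dm ~", paste(deparse(formula[[2]]),
                                             collapse = "")))
  env <- list2env(list(dm = dm), parent = environment(formula))
  environment(f) <- env
  fit <- vegan::adonis2(f, data = data, permutations = n_perm,
                        by = "terms", strata = strata)
  out <- data.frame(term = rownames(fit),
                    df = fit$Df,
                    ss = fit$SumOfSqs,
                    r2 = fit$R2,
                    statistic = fit$F,
                    p_value = fit$`Pr(>F)`,
                    row.names = NULL)
  attr(out, "n_perm") <- n_perm
  class(out) <- c("permutation_test", "data.frame")
  out
}

#' ANOSIM: analysis of similarity
#'
#' Rank-based contrast of between- versus within-group dissimilarities:
#' `R = (mean rank between - mean rank within) / (n(n-1)/4)`, with midranks
#' for ties. R is 0 in expectation under the null and 1 when all
#' between-group dissimilarities exceed all within-group ones. The p-value
#' uses the add-one permutation estimator.
#'
#' @param dm A `dist` object.
#' @param groups Factor of group labels (>= 2 groups of >= 2 samples).
#' @param n_perm Number of permutations (default 999).
#' @param strata Optional factor restricting permutations.
#' @param seed Optional integer seed.
#' @return data.frame of class `permutation_test` with columns `term`,
#'   `statistic` (R), `p_value`.
#' @export
anosim_test <- function(dm, groups, n_perm = 999, strata = NULL,
                        seed = NULL) {
  groups <- as.factor(groups)
  tab <- table(groups)
  if (nlevels(groups) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 samples each")
  if (!is.null(seed)) set.seed(seed)
  fit <- if (is.null(strata))
    vegan::anosim(dm, groups, permutations = n_perm)
  else vegan::anosim(dm, groups, permutations = n_perm, strata = strata)
  out <- data.frame(term = "groups",
                    statistic = unname(fit$statistic),
                    p_value = fit$signif,
                    row.names = NULL)
  attr(out, "n_perm") <- n_perm
  class(out) <- c("permutation_test", "data.frame")
  out
}

#' SIMPER: per-taxon contributions to between-group dissimilarity
#'
#' Decomposes the average between-group Bray-Curtis dissimilarity into
#' per-taxon contributions: for taxon k, the average over between-group
#' sample pairs (i, j) of `|x_ik - x_jk| / sum_m (x_im + x_jm)`, normalized
#' so the contributions sum to 1. Entries are sorted by decreasing
#' contribution with a running cumulative sum.
#'
#' @param table A [feature_table()] or [normalized_table()].
#' @param groups Factor with exactly two levels.
#' @return data.frame with columns `taxon`, `contribution`, `cumulative`,
#'   `mean_a`, `mean_b` (per-group mean abundances).
#' @export
simper_contrib <- function(table, groups) {
  m <- abundance_matrix(table)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2)
    stop("SIMPER requires exactly 2 groups; call pairwise for more")
  if (any(table(groups) < 1)) stop("empty group")
  sp <- vegan::simper(m, groups, permutations = 0)[[1]]
  contrib <- sp$average
  total <- sum(contrib)
  if (total <= 0) stop("zero between-group dissimilarity")
  contrib <- contrib / total
  ord <- order(contrib, decreasing = TRUE)
  data.frame(taxon = sp$species[ord],
             contribution = unname(contrib[ord]),
             cumulative = cumsum(unname(contrib[ord])),
             mean_a = unname(sp$ava[ord]),
             mean_b = unname(sp$avb[ord]),
             row.names = NULL)
}

#' Non-metric multidimensional scaling (NMDS)
#'
#' Minimizes Kruskal stress-1 between monotone-regressed dissimilarities
#' and configuration distances, keeping the best of `n_starts` random
#' initializations. Non-convergence is flagged, not thrown.
#'
#' @param dm A `dist` object.
#' @param k Number of dimensions (default 2).
#' @param n_starts Random starts (default 20).
#' @param max_iter Iterations per start (default 200).
#' @param seed Optional integer seed.
#' @return List of class `nmds_ordination`: `scores` (n x k, centered per
#'   axis), `stress` (in \[0, 1\]), `converged`, `k`.
#' @export
nmds <- function(dm, k = 2, n_starts = 20, max_iter = 200, seed = NULL) {
  n <- attr(dm, "Size")
  if (n < k + 2) stop("need at least k + 2 samples")
  if (!is.null(seed)) set.seed(seed)
  # degenerate, perfectly representable configurations make vegan warn
  # about (near) zero stress; that outcome is legitimate here
  fit <- withCallingHandlers(
    vegan::metaMDS(dm, k = k, try = n_starts, trymax = n_starts,
                   maxit = max_iter, trace = 0, autotransform = FALSE,
                   wascores = FALSE),
    warning = function(w) {
      if (grepl("zero", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  scores <- sweep(fit$points, 2, colMeans(fit$points))
  colnames(scores) <- paste0("NMDS", seq_len(k))
  structure(list(scores = scores, stress = fit$stress,
                 converged = isTRUE(fit$converged > 0), k = k),
            class = "nmds_ordination")
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat("NMDS ordination: ", nrow(x$scores), " samples, k = ", x$k,
      ", stress = ", signif(x$stress, 4),
      if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}

#' Fit covariates onto an ordination
#'
#' For each metadata column, measures how much of the ordination-score
#' variation it explains: continuous covariates get the r-squared of the
#' best-fitting direction in score space; categorical covariates get
#' `1 - SS_within / SS_total` of the scores by level (centroid fit).
#' Significance is assessed by row permutation, adjusted across covariates
#' by Benjamini-Hochberg, and the combined effect size is the sum of
#' r-squared over covariates with adjusted p < 0.05 (non-orthogonal: the
#' covariates may be correlated, so the sum is an upper-bound style
#' summary, not an exact variance partition).
#'
#' @param ord An [nmds()] result (or any list with a `scores` matrix).
#' @param metadata data.frame of covariates aligned with the ordination.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @return data.frame of class `covariate_fit`: `covariate`, `type`, `r2`,
#'   `p_value`, `p_adjusted`; attribute `combined_effect_size`.
#' @export
fit_covariates <- function(ord, metadata, n_perm = 10000, seed = NULL) {
  scores <- if (is.list(ord) && !is.null(ord$scores)) ord$scores else
    as.matrix(ord)
  metadata <- as.data.frame(metadata)
  stopifnot(nrow(metadata) == nrow(scores))
  const <- vapply(metadata, function(x) length(unique(x)) < 2, TRUE)
  if (any(const)) {
    warning("constant covariate(s), r2 set to 0: ",
            paste(names(metadata)[const], collapse = ", "))
  }
  use <- metadata[!const]
  rows <- list()
  if (ncol(use)) {
    if (!is.null(seed)) set.seed(seed)
    ef <- vegan::envfit(scores, use, permutations = n_perm)
    if (!is.null(ef$vectors))
      rows <- c(rows, list(data.frame(covariate = rownames(ef$vectors$arrows),
                                      type = "continuous",
                                      r2 = unname(ef$vectors$r),
                                      p_value = unname(ef$vectors$pvals))))
    if (!is.null(ef$factors))
      rows <- c(rows, list(data.frame(covariate = names(ef$factors$r),
                                      type = "categorical",
                                      r2 = unname(ef$factors$r),
                                      p_value = unname(ef$factors$pvals))))
  }
  if (any(const))
    rows <- c(rows, list(data.frame(covariate = names(metadata)[const],
                                    type = "constant", r2 = 0,
                                    p_value = NA_real_)))
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[match(names(metadata), out$covariate), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "combined_effect_size") <-
    sum(out$r2[!is.na(out$p_adjusted) & out$p_adjusted < 0.05])
  attr(out, "n_perm") <- n_perm
  class(out) <- c("covariate_fit", "data.frame")
  out
}

#' Within-host temporal deltas
#'
#' Builds, per host, the difference of every numeric phenotype between two
#' time points (by default T2 - T1, end of study minus baseline), removing
#' inter-individual level differences. Columns identical at both time
#' points (e.g. breed) are carried through unchanged; hosts missing either
#' time point are dropped with a message.
#'
#' @param metadata data.frame with one row per sample.
#' @param host Name of the host-id column (default `"host_id"`).
#' @param time Name of the time-point column (default `"timepoint"`).
#' @param order Length-2 vector: difference is `order[1] - order[2]`
#'   (default `c("T2", "T1")`).
#' @return data.frame with one row per complete host.
#' @export
delta_phenotypes <- function(metadata, host = "host_id", time = "timepoint",
                             order = c("T2", "T1")) {
  metadata <- as.data.frame(metadata)
  stopifnot(host %in% names(metadata), time %in% names(metadata),
            length(order) == 2)
  tt <- as.character(metadata[[time]])
  if (!all(order %in% tt)) stop("time points ", paste(order, collapse = ", "),
                                " not both present")
  a <- metadata[tt == order[1], , drop = FALSE]
  b <- metadata[tt == order[2], , drop = FALSE]
  common <- intersect(a[[host]], b[[host]])
  incomplete <- setdiff(unique(metadata[[host]]), common)
  if (length(incomplete))
    message("delta_phenotypes: dropped host(s) missing a time point: ",
            paste(incomplete, collapse = ", "))
  a <- a[match(common, a[[host]]), , drop = FALSE]
  b <- b[match(common, b[[host]]), , drop = FALSE]
  out <- data.frame(row.names = seq_along(common))
  out[[host]] <- common
  for (cn in setdiff(names(metadata), c(host, time))) {
    if (is.numeric(metadata[[cn]])) {
      out[[paste0("delta_", cn)]] <- a[[cn]] - b[[cn]]
    } else if (identical(a[[cn]], b[[cn]])) {
      out[[cn]] <- a[[cn]]
    }
  }
  out
}

#' Cross-correlation of taxa and host phenotypes
#'
#' Pearson (or Spearman) correlation of every (taxon, phenotype) pair with
#' two-sided p-values, Benjamini-Hochberg adjusted over the full grid.
#' Cells with fewer than 3 complete pairs or zero variance are flagged
#' `NA` and excluded from the adjustment family. Two significance tiers
#' are reported: adjusted p < 0.05 and < 0.10.
#'
#' @param table A [normalized_table()] (e.g. relative genus abundances).
#' @param phenotypes data.frame of numeric phenotype columns aligned with
#'   the table's samples.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame of class `cross_correlation`: `taxon`, `phenotype`,
#'   `r`, `p_value`, `p_adjusted`, `sig_05`, `sig_10`.
#' @export
cross_correlate <- function(table, phenotypes, method = "pearson") {
  m <- abundance_matrix(table)
  phenotypes <- as.data.frame(phenotypes)
  num <- vapply(phenotypes, is.numeric, TRUE)
  phenotypes <- phenotypes[num]
  stopifnot(nrow(phenotypes) == nrow(m), ncol(phenotypes) > 0)
  grid <- expand.grid(taxon = colnames(m), phenotype = names(phenotypes),
                      stringsAsFactors = FALSE)
  rp <- mapply(function(tx, ph) {
    x <- m[, tx]
    y <- phenotypes[[ph]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(c(NA_real_, NA_real_))
    ct <- stats::cor.test(x[ok], y[ok], method = method, exact = FALSE)
    c(unname(ct$estimate), ct$p.value)
  }, grid$taxon, grid$phenotype)
  out <- data.frame(grid, r = rp[1, ], p_value = rp[2, ])
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$sig_05 <- !is.na(out$p_adjusted) & out$p_adjusted < 0.05
  out$sig_10 <- !is.na(out$p_adjusted) & out$p_adjusted < 0.10
  class(out) <- c("cross_correlation", "data.frame")
  out
}
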