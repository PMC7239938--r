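#' Alpha-diversity indices
#'
#' Computes, per sample, the observed richness, the bias-corrected Chao1
#' estimator `S + F1(F1-1)/(2(F2+1))` (F1, F2 = singleton and doubleton
#' counts), the Shannon entropy (natural log) and Fisher's alpha, the
#' solution of `S = alpha * log(1 + N / alpha)`.
#'
#' The indices are defined on counts, so the input must be integer-valued
#' (typically a rarefied table).
#'
#' @param table A [feature_table()] or integer-valued rarefied
#'   [normalized_table()].
#' @return data.frame with columns `sample_id`, `observed`, `chao1`,
#'   `shannon`, `fisher_alpha`.
#' @export
alpha_diversity <- function(table) {
  m <- abundance_matrix(table)
  if (any(m != round(m)))
    stop("alpha diversity is defined on counts; table has non-integer values")
  data.frame(
    sample_id = rownames(m),
    observed = apply(m, 1, function(x) sum(x > 0)),
    chao1 = apply(m, 1, .chao1),
    shannon = apply(m, 1, .shannon),
    fisher_alpha = apply(m, 1, .fisher_alpha),
    row.names = NULL)
}

.chao1 <- function(x) {
  s <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

.shannon <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

.fisher_alpha <- function(x, tol = 1e-10) {
  s <- sum(x > 0)
  n <- sum(x)
  if (s == 0) return(NA_real_)
  if (s >= n) {
    warning("all taxa are singletons; Fisher's alpha diverges")
    return(Inf)
  }
  f <- function(a) a * log1p(n / a) - s
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(hi / 2, hi), tol = tol)$root
}

#' Bray-Curtis dissimilarity
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)`: 0 for identical samples,
#' 1 for samples with disjoint taxa. A pair of all-zero samples has an
#' undefined dissimilarity; it is reported as 0 with a warning.
#'
#' @param table A [feature_table()] or [normalized_table()].
#' @return A `dist` object with attribute `metric = "bray_curtis"`.
#' @export
bray_curtis <- function(table) {
  m <- abundance_matrix(table)
  # vegan's empty-row warnings are superseded by the explicit NA handling
  # below, which reports the undefined pairs itself
  d <- withCallingHandlers(
    vegan::vegdist(m, method = "bray"),
    warning = function(w) {
      if (grepl("empty rows|missing values", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (anyNA(d)) {
    warning("pair(s) of all-zero samples: dissimilarity undefined, set to 0")
    d[is.na(d)] <- 0
  }
  attr(d, "metric") <- "bray_curtis"
  d
}

#' UniFrac distances
#'
#' Phylogeny-aware beta diversity. Unweighted UniFrac is the fraction of
#' total branch length leading only to taxa present in one of the two
#' samples; weighted (normalized) UniFrac weights each branch by the
#' absolute difference in the relative abundance of its subtree,
#' `sum b_l |p_l(i) - p_l(j)| / sum b_l (p_l(i) + p_l(j))`, and lies in
#' \[0, 1\].
#'
#' @param table A [feature_table()].
#' @param tree A rooted `phylo` tree (or newick string / file path) whose
#'   tip labels cover the table's taxa; branch lengths must be positive.
#' @param weighted Logical; abundance-weighted variant.
#' @param normalized Logical; divide the weighted variant by its maximum
#'   (ignored when `weighted = FALSE`).
#' @return A `dist` object with a `metric` attribute.
#' @export
unifrac <- function(table, tree, weighted = FALSE, normalized = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  tree <- .as_phylo(tree)
  missing <- setdiff(colnames(table$counts), tree$tip.label)
  if (length(missing))
    stop("taxa missing from tree: ", paste(missing, collapse = ", "))
  tree <- ape::keep.tip(tree, colnames(table$counts))
  if (!ape::is.rooted(tree) || !ape::is.binary(tree)) {
    # polytomies (incl. a basal one, which counts as unrooted) are
    # resolved deterministically with zero-length branches; zero-length
    # edges leave every UniFrac variant unchanged
    tree <- ape::multi2di(tree, random = FALSE)
  }
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(table$counts, taxa_are_rows = FALSE),
    phyloseq::phy_tree(tree))
  d <- phyloseq::UniFrac(ps, weighted = weighted, normalized = normalized)
  # restore input sample order
  d <- stats::as.dist(as.matrix(d)[rownames(table$counts),
                                   rownames(table$counts)])
  attr(d, "metric") <- if (weighted) "weighted_unifrac" else
    "unweighted_unifrac"
  d
}

.as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1) {
    if (grepl(";", tree)) return(ape::read.tree(text = tree))
    return(ape::read.tree(tree))
  }
  stop("tree must be a phylo object, newick string or file path")
}

#' Read / write a distance matrix as square TSV
#'
#' The layout is a square numeric matrix with sample ids as both header
#' row and first column.
#'
#' @param dm A `dist` object.
#' @param path File path.
#' @return `read_distance_matrix`: a `dist` with a `metric` attribute
#'   when one was stored; `write_distance_matrix`: `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  m <- as.matrix(dm)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (!identical(rownames(m), colnames(m)))
    stop("row and column sample ids differ")
  if (max(abs(m - t(m))) > 1e-12) stop("matrix is not symmetric")
  stats::as.dist(m)
}

#' Multivariate dispersion around group centroids
#'
#' Embeds the distance matrix by principal coordinates (with the standard
#' correction for negative eigenvalues of non-Euclidean dissimilarities),
#' computes each sample's distance to its group's spatial centroid, and
#' tests homogeneity of dispersion with a one-way ANOVA F whose null
#' distribution is obtained by permutation. This is the usual device for
#' asking whether one group (e.g. a later time point) is more heterogeneous
#' than another.
#'
#' @param dm A `dist` object.
#' @param groups Factor of group labels (>= 2 groups of >= 2 samples).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return List of class `dispersion_test`: per-sample `distances`,
#'   `group_means`, `F`, `p_value` (permutation), `n_perm`.
#' @export
dispersion <- function(dm, groups, n_perm = 999, seed = NULL) {
  groups <- as.factor(groups)
  tab <- table(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(tab < 2))
    stop("group(s) of size 1: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  bd <- vegan::betadisper(dm, groups, type = "centroid")
  pt <- vegan::permutest(bd, permutations = n_perm)
  res <- list(distances = bd$distances,
              group_means = tapply(bd$distances, groups, mean),
              F = unname(pt$tab$F[1]),
              p_value = unname(pt$tab$`Pr(>F)`[1]),
              n_perm = n_perm,
              groups = groups)
  class(res) <- "dispersion_test"
  res
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat("Multivariate dispersion (distance to group centroid)\n")
  print(round(x$group_means, 4))
  cat("F =", signif(x$F, 4), " permutation p =", signif(x$p_value, 4),
      "(", x$n_perm, "permutations )\n")
  invisible(x)
}
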