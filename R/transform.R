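#' Rarefy a feature table to even depth
#'
#' Each sample is subsampled without replacement (multivariate
#' hypergeometric) down to `depth` reads, the usual device for comparing
#' richness across libraries of unequal size. Samples with fewer than
#' `depth` reads are dropped, reported via a message and recorded in the
#' `dropped` attribute -- never silently removed.
#'
#' @param table A [feature_table()].
#' @param depth Target depth (reads per sample), >= 1.
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @return A [normalized_table()] with tag `"rarefied"`; every row sums
#'   exactly to `depth`. Attribute `dropped` lists removed sample ids.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (length(depth) != 1 || depth < 1 || depth != round(depth))
    stop("depth must be a single integer >= 1")
  m <- table$counts
  tot <- rowSums(m)
  keep <- tot >= depth
  if (!any(keep))
    stop("rarefaction depth ", depth, " exceeds every sample total (max ",
         max(tot), "); output would be empty")
  dropped <- rownames(m)[!keep]
  if (length(dropped))
    message("rarefy: dropped ", length(dropped),
            " sample(s) below depth ", depth, ": ",
            paste(dropped, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  # vegan warns when no singleton is present (a heuristic for non-count
  # data); our input is validated integer counts, so silence that one
  sub <- withCallingHandlers(
    vegan::rrarefy(m[keep, , drop = FALSE], depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  out <- normalized_table(sub, "rarefied", taxonomy = table$taxonomy)
  attr(out, "dropped") <- dropped
  attr(out, "depth") <- depth
  out
}

#' Aggregate a feature table at a taxonomic rank
#'
#' Counts are summed over taxa sharing the same lineage down to `rank`.
#' Taxa unclassified at that rank are pooled into one
#' `unclassified_<parent>` bucket per deepest classified parent, so no
#' reads are ever discarded: column sums are conserved.
#'
#' @param table A [feature_table()].
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`.
#' @return A [feature_table()] whose taxa are the lineages at `rank`.
#' @export
aggregate_taxa <- function(table, rank) {
  stopifnot(inherits(table, "feature_table"))
  if (!rank %in% .tax_ranks)
    stop("unknown rank '", rank, "'; must be one of ",
         paste(.tax_ranks, collapse = ", "))
  tax <- table$taxonomy
  upto <- seq_len(match(rank, .tax_ranks))
  key <- character(nrow(tax))
  newtax <- vector("list", nrow(tax))
  for (i in seq_len(nrow(tax))) {
    lin <- as.character(tax[i, upto])
    if (is.na(lin[length(lin)])) {
      classified <- lin[!is.na(lin)]
      parent <- if (length(classified)) classified[length(classified)] else "root"
      name <- paste0("unclassified_", parent)
      lin[is.na(lin)] <- name
    } else {
      name <- lin[length(lin)]
    }
    key[i] <- paste(lin, collapse = ";")
    newtax[[i]] <- lin
  }
  groups <- !duplicated(key)
  agg <- t(rowsum(t(table$counts + 0), group = key, reorder = FALSE))
  # name aggregated columns by their rank-level label, disambiguating
  # identical labels arising under different parents
  labs <- vapply(newtax[groups], function(l) l[length(l)], "")
  if (anyDuplicated(labs)) {
    d <- duplicated(labs) | duplicated(labs, fromLast = TRUE)
    labs[d] <- key[groups][d]
  }
  txdf <- as.data.frame(do.call(rbind, newtax[groups]),
                        stringsAsFactors = FALSE)
  names(txdf) <- .tax_ranks[upto]
  rownames(txdf) <- labs
  colnames(agg) <- labs
  storage.mode(agg) <- "integer"
  feature_table(agg, taxonomy = txdf)
}

#' Cumulative sum scaling (CSS) with log transform
#'
#' Per-sample scaling factor `s_j` is the sum of that sample's counts at or
#' below the `quantile`-th quantile of its nonzero counts; values are
#' `log2(count / s_j * S + 1)` where `S` is the median of the `s_j` across
#' samples. CSS damps the influence of a few dominant taxa on library-size
#' normalization; the +1 pseudo-count keeps zeros at exactly 0.
#'
#' @param table A [feature_table()].
#' @param quantile Quantile of the nonzero counts defining the scaling
#'   factor (default 0.5, the median).
#' @return A [normalized_table()] with tag `"css_log"`; attribute
#'   `scaling_factors` holds the per-sample `s_j` and `S`.
#' @export
css_log <- function(table, quantile = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  m <- table$counts + 0
  if (any(rowSums(m) == 0))
    stop("all-zero sample(s): ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  s <- css_factors(table, quantile)
  S <- stats::median(s)
  out <- log2(sweep(m, 1, s, "/") * S + 1)
  nt <- normalized_table(out, "css_log", taxonomy = table$taxonomy)
  attr(nt, "scaling_factors") <- s
  attr(nt, "reference_scale") <- S
  nt
}

#' @rdname css_log
#' @details `css_factors` exposes the raw per-sample scaling factors
#'   `s_j`; the internal quantities `count / s_j` are exactly invariant to
#'   rescaling a sample's counts by a constant.
#' @export
css_factors <- function(table, quantile = 0.5) {
  m <- abundance_matrix(table)
  apply(m, 1, function(x) {
    nz <- x[x > 0]
    if (!length(nz)) stop("all-zero sample")
    q <- stats::quantile(nz, quantile, names = FALSE)
    sum(x[x <= q])
  })
}

#' Core-microbiota detection
#'
#' Returns the taxa whose relative abundance is at least `detection` in at
#' least a `prevalence` fraction of samples. When `timepoints` is given the
#' rule is evaluated within each time point and the per-time-point sets are
#' intersected, so a core taxon must be consistently present at every time
#' point.
#'
#' @param table A [feature_table()], typically aggregated at genus level.
#' @param detection Relative-abundance detection threshold (default 0.001,
#'   i.e. 0.1%).
#' @param prevalence Fraction of samples in which the taxon must reach
#'   `detection` (default 0.99; 0.999 reproduces the strictest reading).
#' @param timepoints Optional factor over samples (e.g. `"T1"`/`"T2"`).
#' @return Character vector of core taxon ids, in table column order.
#' @export
core_microbiota <- function(table, detection = 0.001, prevalence = 0.99,
                            timepoints = NULL) {
  m <- abundance_matrix(table)
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty table")
  rel <- m / ifelse(rowSums(m) > 0, rowSums(m), 1)
  hit <- rel >= detection
  sets <- if (is.null(timepoints)) list(rep(TRUE, nrow(m))) else
    split(seq_len(nrow(m)), timepoints)
  core <- Reduce(intersect, lapply(sets, function(idx) {
    prev <- colMeans(hit[idx, , drop = FALSE])
    colnames(m)[prev >= prevalence]
  }))
  intersect(colnames(m), core)
}
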