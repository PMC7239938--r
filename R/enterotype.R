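#' PAM (k-medoids) clustering of a distance matrix
#'
#' Partitioning Around Medoids: a BUILD phase seeds k medoids, then SWAP
#' iterations exchange medoids and non-medoids while the total
#' within-cluster distance-to-medoid decreases, terminating at a local
#' optimum. The algorithm is deterministic for a given distance matrix.
#'
#' Because SWAP only exchanges one medoid at a time, a single run can stall
#' in a local optimum; the deterministic BUILD start is therefore
#' complemented by `n_starts` seeded random initializations and the best
#' local optimum is kept.
#'
#' @param dm A `dist` object.
#' @param k Number of clusters, `2 <= k < n`.
#' @param n_starts Additional random initializations beyond the BUILD
#'   start (default 10).
#' @param seed Optional integer seed for the random starts.
#' @return List of class `community_typing`: `k`, `medoids` (sample ids),
#'   `labels` (named integer vector in 1..k), `objective` (total distance
#'   to assigned medoid), `silhouette` (per-sample widths), `SC` (mean
#'   silhouette), `reasonable` (`SC > 0.5`).
#' @export
pam_clusters <- function(dm, k, n_starts = 10, seed = NULL) {
  n <- attr(dm, "Size")
  if (k < 2 || k >= n) stop("need 2 <= k < n (n = ", n, ")")
  if (!is.null(seed)) set.seed(seed)
  fit <- cluster::pam(dm, k, diss = TRUE)
  for (i in seq_len(n_starts)) {
    cand <- cluster::pam(dm, k, diss = TRUE, medoids = sample(n, k))
    if (cand$objective[["swap"]] < fit$objective[["swap"]]) fit <- cand
  }
  labels <- fit$clustering
  md <- as.matrix(dm)
  objective <- sum(md[cbind(seq_len(n), match(fit$medoids, rownames(md))[labels])])
  sil <- silhouette_widths(dm, labels)
  structure(list(k = k, medoids = fit$medoids, labels = labels,
                 objective = objective, silhouette = sil$widths,
                 SC = sil$SC, reasonable = sil$SC > 0.5),
            class = "community_typing")
}

#' @export
print.community_typing <- function(x, ...) {
  cat("PAM community typing: k =", x$k,
      " sizes:", paste(table(x$labels), collapse = "/"), "\n")
  cat("silhouette coefficient SC =", round(x$SC, 3),
      if (x$reasonable) "(reasonable structure, SC > 0.5)"
      else "(no reasonable structure, SC <= 0.5)", "\n")
  invisible(x)
}

#' Silhouette widths for a clustering
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with a(i) the mean distance of
#' sample i to its own cluster and b(i) the smallest mean distance to
#' another cluster. Samples in singleton clusters get `s(i) = 0` (the
#' usual convention). SC is the mean silhouette over all samples.
#'
#' @param dm A `dist` object.
#' @param labels Cluster labels (>= 2 non-empty clusters).
#' @return List: `widths` (named per-sample), `SC`.
#' @export
silhouette_widths <- function(dm, labels) {
  labels <- as.integer(as.factor(labels))
  if (length(unique(labels)) < 2)
    stop("silhouette requires at least 2 clusters")
  sil <- cluster::silhouette(labels, dm)
  widths <- sil[, "sil_width"]
  names(widths) <- attr(dm, "Labels")
  list(widths = widths, SC = mean(widths))
}

#' Silhouette-guided selection of the number of community types
#'
#' Runs [pam_clusters()] for each k in `k_range`, scores each partition by
#' its silhouette coefficient and returns the argmax. A cohort "has"
#' community types (enterotype-like structure) only when the best SC
#' exceeds 0.5; `reasonable = FALSE` is the negative finding of a
#' structure-free cohort.
#'
#' @param dm A `dist` object.
#' @param k_range Candidate cluster numbers (default `2:10`, truncated to
#'   `n - 1`).
#' @param seed Optional integer seed for the PAM random starts.
#' @return The best `community_typing`, with an extra element `sc_table`
#'   (data.frame of k vs SC).
#' @export
select_k <- function(dm, k_range = 2:10, seed = NULL) {
  n <- attr(dm, "Size")
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("k_range empty after truncation to [2, n-1]")
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(k_range, function(k) pam_clusters(dm, k))
  sc <- vapply(fits, `[[`, 0, "SC")
  best <- fits[[which.max(sc)]]
  best$sc_table <- data.frame(k = k_range, SC = sc)
  best
}
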