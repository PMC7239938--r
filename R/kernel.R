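#' Build the microbial relationship matrix
#'
#' The microbial analogue of the genomic relationship matrix: from the
#' CSS-normalized log abundance matrix `W` (n samples x k taxa), taxa are
#' column-centered (optionally unit-scaled) and the kernel is
#' `M = W W' / k`, rescaled so its mean diagonal is 1 so that the
#' associated variance component is on the phenotype-variance scale.
#' `M` is positive semidefinite by construction; if numerical rounding
#' leaves a slightly negative eigenvalue, a minimal diagonal jitter is
#' added and recorded.
#'
#' @param css_table A [css_log()] table (any [normalized_table()] or
#'   numeric matrix is accepted).
#' @param center Column-center the matrix (default TRUE).
#' @param scale Also unit-scale columns (default FALSE; zero-variance
#'   columns are left unscaled).
#' @return List of class `microbial_kernel`: `M` (n x n), `sample_ids`,
#'   `source` (normalization tag), `jitter`.
#' @export
microbial_kernel <- function(css_table, center = TRUE, scale = FALSE) {
  W <- abundance_matrix(css_table)
  if (ncol(W) == 0) stop("kernel requires at least one taxon")
  src <- if (inherits(css_table, "normalized_table"))
    css_table$normalization else "matrix"
  if (center) W <- sweep(W, 2, colMeans(W))
  if (scale) {
    s <- apply(W, 2, stats::sd)
    s[s == 0] <- 1
    W <- sweep(W, 2, s, "/")
  }
  M <- tcrossprod(W) / ncol(W)
  dbar <- mean(diag(M))
  if (dbar <= 0) stop("kernel has zero mean diagonal; no sample variation")
  M <- M / dbar
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  jitter <- 0
  if (min(ev) < 0) {
    if (min(ev) < -1e-8 * max(ev))
      stop("kernel unexpectedly far from PSD (min eigenvalue ", min(ev), ")")
    jitter <- -min(ev) + 1e-10
    diag(M) <- diag(M) + jitter
  }
  structure(list(M = M, sample_ids = rownames(W), source = src,
                 jitter = jitter),
            class = "microbial_kernel")
}

#' @export
print.microbial_kernel <- function(x, ...) {
  cat("microbial_kernel:", nrow(x$M), "samples, source:", x$source,
      " mean diag:", round(mean(diag(x$M)), 4), "\n")
  if (x$jitter > 0) cat("diagonal jitter applied:", x$jitter, "\n")
  invisible(x)
}

#' Expand a host-level kinship matrix to sample level
#'
#' Repeated measures share their host's genetic effect, so the sample-level
#' covariance is `K[host_i, host_j]`.
#'
#' @param K Square host x host matrix with host ids as dimnames.
#' @param hosts Host id per sample (names or a vector aligned to samples).
#' @param sample_ids Optional sample ids for the output dimnames.
#' @return Sample x sample matrix.
#' @export
expand_kinship <- function(K, hosts, sample_ids = names(hosts)) {
  hosts <- as.character(hosts)
  missing <- setdiff(hosts, rownames(K))
  if (length(missing))
    stop("hosts missing from kinship: ", paste(unique(missing), collapse = ", "))
  out <- K[hosts, hosts, drop = FALSE]
  if (!is.null(sample_ids)) dimnames(out) <- list(sample_ids, sample_ids)
  out
}
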