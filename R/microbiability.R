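#' Bayesian microbiability model
#'
#' Fits, by Gibbs sampling, the mixed model
#' `y = X beta + u_m (+ u_g) + e` with `u_m ~ N(0, sigma2_m M)` for a
#' microbial relationship matrix `M` (see [microbial_kernel()]) and an
#' optional host-genetic term `u_g ~ N(0, sigma2_H K)`. Microbiability is
#' the share of phenotypic variance carried by the microbial term:
#' `m2 = sigma2_m / (sigma2_m + sigma2_H + sigma2_e)` (the bounded
#' "total" definition, the default; see [m2_summary()] for the
#' alternative).
#'
#' Fixed effects get a flat prior; each variance component gets a
#' scaled-inverse-chi-squared prior with `prior_df` degrees of freedom and
#' scale set from `prior_var_share * var(y)` split equally across the
#' components (weakly informative). The random effects are sampled in the
#' eigenbasis of their kernel, where the full conditional factorizes into
#' independent scalar normals, which makes chains of tens of thousands of
#' iterations cheap even for hundreds of samples.
#'
#' @param formula Model formula, e.g. `y ~ breed + discipline + timepoint`.
#' @param data data.frame with the phenotype and fixed-effect columns, one
#'   row per sample, rownames = sample ids matching the kernel.
#' @param kernel A [microbial_kernel()] (or PSD matrix with sample ids).
#' @param kinship Optional sample-level PSD matrix for the host-genetic
#'   term (see [expand_kinship()]).
#' @param iterations Total Gibbs iterations (default 30000).
#' @param burnin Burn-in iterations discarded (default 2000).
#' @param thin Keep every `thin`-th post-burn-in draw (default 10).
#' @param prior_df Prior degrees of freedom nu for each variance (default 5).
#' @param prior_var_share Share of `var(y)` allocated to the variance
#'   priors (default 0.5, split equally across components).
#' @param seed Optional integer seed.
#' @return Object of class `microbiability`: retained draws of the fixed
#'   effects, variance components and per-draw m2, posterior means, and
#'   chain metadata. Methods: [print.microbiability()],
#'   [summary.microbiability()], `coef`, `fitted`, `residuals`, `plot`.
#' @seealso [m2_summary()], [run_microbiability()]
#' @export
microbiability <- function(formula, data, kernel, kinship = NULL,
                           iterations = 30000, burnin = 2000, thin = 10,
                           prior_df = 5, prior_var_share = 0.5,
                           seed = NULL) {
  stopifnot(iterations > burnin, thin >= 1, prior_df > 0)
  data <- as.data.frame(data)
  M <- if (inherits(kernel, "microbial_kernel")) kernel$M else as.matrix(kernel)
  ids <- rownames(M)
  if (!is.null(ids) && !is.null(rownames(data)) &&
      all(rownames(data) %in% ids) && nrow(data) == nrow(M)) {
    M <- M[rownames(data), rownames(data)]
    if (!is.null(kinship)) kinship <- kinship[rownames(data), rownames(data)]
  } else if (nrow(data) != nrow(M)) {
    stop("data rows and kernel samples do not align")
  }

  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  ok <- stats::complete.cases(mf)
  n_dropped <- sum(!ok)
  if (n_dropped) {
    message("microbiability: dropped ", n_dropped,
            " incomplete case(s) for ", deparse(formula[[2]]))
    mf <- mf[ok, , drop = FALSE]
    y <- y[ok]
    M <- M[ok, ok]
    if (!is.null(kinship)) kinship <- kinship[ok, ok]
  }
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design matrix rank deficient; aliased columns: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
               collapse = ", "))
  n <- length(y)

  eig_basis <- function(A, what) {
    e <- eigen(A, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(abs(e$values)))
      stop(what, " kernel is not positive semidefinite; ",
           "rebuild it with microbial_kernel() so jitter is applied")
    keep <- e$values > 1e-10 * max(e$values)
    list(W = e$vectors[, keep, drop = FALSE] %*%
           diag(sqrt(e$values[keep]), sum(keep)),
         d = e$values[keep])
  }
  em <- eig_basis(M, "microbial")
  eg <- if (!is.null(kinship)) eig_basis(as.matrix(kinship), "kinship")
        else NULL

  ncomp <- 2L + !is.null(eg)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy == 0) stop("phenotype has zero variance")
  S2 <- prior_var_share * vy / ncomp   # prior scale per component
  nu <- prior_df

  if (!is.null(seed)) set.seed(seed)
  # initial values
  beta <- qr.coef(qrX, y)
  XtXi_chol <- chol(crossprod(X))
  am <- rep(0, ncol(em$W))
  ag <- if (!is.null(eg)) rep(0, ncol(eg$W)) else numeric(0)
  s2m <- s2e <- S2
  s2g <- if (!is.null(eg)) S2 else 0

  n_keep <- floor((iterations - burnin) / thin)
  draws_beta <- matrix(NA_real_, n_keep, ncol(X),
                       dimnames = list(NULL, colnames(X)))
  draws_var <- matrix(NA_real_, n_keep, 3,
                      dimnames = list(NULL, c("sigma2_m", "sigma2_H",
                                              "sigma2_e")))
  um_sum <- rep(0, n)
  ug_sum <- rep(0, n)
  kept <- 0L

  Wm <- em$W; dm <- em$d
  Wg <- if (!is.null(eg)) eg$W else NULL
  dg <- if (!is.null(eg)) eg$d else NULL
  um <- drop(Wm %*% am)
  ug <- rep(0, n)

  for (it in seq_len(iterations)) {
    # beta | rest : N((X'X)^-1 X'(y - um - ug), s2e (X'X)^-1)
    r <- y - um - ug
    bhat <- qr.coef(qrX, r)
    beta <- bhat + backsolve(XtXi_chol,
                             stats::rnorm(ncol(X), 0, sqrt(s2e)))
    xb <- drop(X %*% beta)

    # microbial effects in eigenbasis: a | rest independent normals
    r <- y - xb - ug
    t_m <- drop(crossprod(Wm, r))
    v_m <- 1 / (dm / s2e + 1 / s2m)
    am <- v_m * t_m / s2e + sqrt(v_m) * stats::rnorm(length(dm))
    um <- drop(Wm %*% am)

    if (!is.null(Wg)) {
      r <- y - xb - um
      t_g <- drop(crossprod(Wg, r))
      v_g <- 1 / (dg / s2e + 1 / s2g)
      ag <- v_g * t_g / s2e + sqrt(v_g) * stats::rnorm(length(dg))
      ug <- drop(Wg %*% ag)
      s2g <- (sum(ag^2) + nu * S2) / stats::rchisq(1, nu + length(ag))
    }

    s2m <- (sum(am^2) + nu * S2) / stats::rchisq(1, nu + length(am))
    res <- y - xb - um - ug
    s2e <- (sum(res^2) + nu * S2) / stats::rchisq(1, nu + n)

    if (it > burnin && (it - burnin) %% thin == 0) {
      kept <- kept + 1L
      draws_beta[kept, ] <- beta
      draws_var[kept, ] <- c(s2m, s2g, s2e)
      um_sum <- um_sum + um
      ug_sum <- ug_sum + ug
    }
  }

  draws_m2 <- draws_var[, "sigma2_m"] / rowSums(draws_var)
  out <- list(call = match.call(), formula = formula,
              n = n, n_dropped = n_dropped,
              has_kinship = !is.null(eg),
              draws_beta = draws_beta, draws_var = draws_var,
              draws_m2 = draws_m2,
              posterior_mean = c(colMeans(draws_beta), colMeans(draws_var),
                                 m2 = mean(draws_m2)),
              u_microbial = um_sum / kept, u_genetic = ug_sum / kept,
              y = y, X = X,
              chain = list(iterations = iterations, burnin = burnin,
                           thin = thin, kept = kept),
              prior = list(df = nu, scale = S2))
  class(out) <- "microbiability"
  out
}

#' Summarize microbiability draws
#'
#' Posterior mean, SD and central 95% credible interval of m2 under one of
#' two definitions: `"total"` divides sigma2_m by the total phenotypic
#' variance `sigma2_m + sigma2_H + sigma2_e` (bounded in \[0, 1\]);
#' `"literal"` divides by `sigma2_H + sigma2_e` only, a
#' heritability-style denominator that omits the focal component and can
#' exceed 1. The literal form is always at least as large as the total
#' form.
#'
#' @param fit A [microbiability()] fit.
#' @param definition `"total"` (default) or `"literal"`.
#' @return Named numeric: `mean`, `sd`, `ci_lo`, `ci_hi`.
#' @export
m2_summary <- function(fit, definition = c("total", "literal")) {
  definition <- match.arg(definition)
  v <- fit$draws_var
  if (is.null(v) || nrow(v) == 0) stop("fit contains no retained draws")
  m2 <- switch(definition,
    total = v[, "sigma2_m"] / rowSums(v),
    literal = v[, "sigma2_m"] / (v[, "sigma2_H"] + v[, "sigma2_e"]))
  ci <- unname(stats::quantile(m2, c(0.025, 0.975)))
  c(mean = mean(m2), sd = stats::sd(m2), ci_lo = ci[1], ci_hi = ci[2])
}

#' @export
print.microbiability <- function(x, ...) {
  s <- m2_summary(x)
  cat("Bayesian microbiability model:",
      deparse(x$formula), "\n")
  cat("n =", x$n, " chain:", x$chain$kept, "retained draws (",
      x$chain$iterations, "iterations, burn-in", x$chain$burnin,
      ", thin", x$chain$thin, ")\n")
  cat(sprintf("m2 = %.1f%% +/- %.1f%% (95%% CI %.1f%% - %.1f%%)\n",
              100 * s["mean"], 100 * s["sd"], 100 * s["ci_lo"],
              100 * s["ci_hi"]))
  invisible(x)
}

#' @export
summary.microbiability <- function(object, ...) {
  v <- object$draws_var
  comp <- rbind(
    sigma2_m = c(mean(v[, 1]), stats::sd(v[, 1])),
    sigma2_H = c(mean(v[, 2]), stats::sd(v[, 2])),
    sigma2_e = c(mean(v[, 3]), stats::sd(v[, 3])))
  colnames(comp) <- c("post_mean", "post_sd")
  if (!object$has_kinship) comp <- comp[-2, , drop = FALSE]
  b <- object$draws_beta
  betas <- cbind(post_mean = colMeans(b), post_sd = apply(b, 2, stats::sd),
                 ci_lo = apply(b, 2, stats::quantile, 0.025),
                 ci_hi = apply(b, 2, stats::quantile, 0.975))
  diag_m2 <- c(ess = effective_size(object$draws_m2),
               rhat = split_rhat(object$draws_m2))
  out <- list(call = object$call, n = object$n,
              m2_total = m2_summary(object, "total"),
              m2_literal = m2_summary(object, "literal"),
              components = comp, fixed_effects = betas,
              diagnostics = diag_m2, chain = object$chain)
  class(out) <- "summary.microbiability"
  out
}

#' @export
print.summary.microbiability <- function(x, ...) {
  cat("Call:", deparse(x$call), "\n\n")
  s <- x$m2_total
  cat(sprintf("Microbiability (total definition): %.1f%% +/- %.1f%% (95%% CI %.1f%% - %.1f%%)\n",
              100 * s["mean"], 100 * s["sd"], 100 * s["ci_lo"],
              100 * s["ci_hi"]))
  s <- x$m2_literal
  cat(sprintf("Microbiability (literal ratio):    %.1f%% +/- %.1f%%\n\n",
              100 * s["mean"], 100 * s["sd"]))
  cat("Variance components:\n")
  print(round(x$components, 4))
  cat("\nFixed effects (posterior):\n")
  print(round(x$fixed_effects, 4))
  cat(sprintf("\nm2 chain diagnostics: ESS = %.0f, split-Rhat = %.3f\n",
              x$diagnostics["ess"], x$diagnostics["rhat"]))
  if (x$diagnostics["ess"] < 100)
    cat("warning: low effective sample size; the variance split may be weakly identified\n")
  invisible(x)
}

#' @export
coef.microbiability <- function(object, ...) colMeans(object$draws_beta)

#' @export
fitted.microbiability <- function(object, ...) {
  drop(object$X %*% coef(object)) + object$u_microbial + object$u_genetic
}

#' @export
residuals.microbiability <- function(object, ...) {
  object$y - fitted(object)
}

#' @export
plot.microbiability <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$draws_m2, type = "l", xlab = "retained draw",
                 ylab = expression(m^2), main = "trace", ...)
  graphics::plot(stats::density(x$draws_m2), main = "posterior",
                 xlab = expression(m^2), ...)
  invisible(x)
}

# Effective sample size from the autocorrelation function, truncated at
# the first non-positive lag (initial positive sequence estimator).
effective_size <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(ifelse(stats::sd(x) == 0, 0, n))
  rho <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  cut <- which(rho <= 0)[1]
  if (!is.na(cut)) rho <- rho[seq_len(cut - 1)]
  n / (1 + 2 * sum(rho))
}

# Split-chain potential scale reduction on a single chain split in halves.
split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  if (n < 2) return(NA_real_)
  halves <- list(x[seq_len(n)], x[seq_len(n) + n])
  W <- mean(vapply(halves, stats::var, 0))
  if (W == 0) return(1)
  B <- n * stats::var(vapply(halves, mean, 0))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Microbiability of a phenotype panel
#'
#' Orchestrates the full path of the headline analysis: CSS-log
#' normalization of the count table, microbial kernel construction, one
#' Gibbs-sampled mixed model per phenotype, and a report of m2 (as a
#' percentage of phenotypic variance) with chain diagnostics.
#'
#' @param table A [feature_table()] of counts (samples aligned with
#'   `metadata` rows).
#' @param metadata data.frame with the fixed-effect columns and the
#'   phenotypes; rownames = sample ids.
#' @param phenotypes Character vector of phenotype column names.
#' @param fixed Right-hand-side formula of fixed effects
#'   (default `~ breed + discipline + timepoint`).
#' @param kinship Optional host-level kinship with a `host` column name in
#'   `metadata` (see `host`), or a sample-level matrix.
#' @param host Host-id column used to expand a host-level kinship.
#' @param definition m2 definition passed to [m2_summary()].
#' @param quantile CSS quantile (see [css_log()]).
#' @param ... Passed to [microbiability()] (`iterations`, `burnin`,
#'   `thin`, `seed`, ...).
#' @return data.frame with one row per phenotype: `phenotype`, `m2_mean`,
#'   `m2_sd`, `ci95_lo`, `ci95_hi` (all percentages), `ess`, `rhat`,
#'   `n_used`.
#' @export
run_microbiability <- function(table, metadata, phenotypes,
                               fixed = ~ breed + discipline + timepoint,
                               kinship = NULL, host = "host_id",
                               definition = c("total", "literal"),
                               quantile = 0.5, ...) {
  definition <- match.arg(definition)
  metadata <- as.data.frame(metadata)
  missing <- setdiff(phenotypes, names(metadata))
  if (length(missing))
    stop("phenotype(s) not in metadata: ", paste(missing, collapse = ", "))
  norm <- css_log(table, quantile = quantile)
  kern <- microbial_kernel(norm)
  if (!is.null(kinship) && !is.null(rownames(kinship)) &&
      !all(rownames(metadata) %in% rownames(kinship))) {
    kinship <- expand_kinship(kinship, metadata[[host]],
                              sample_ids = rownames(metadata))
  }
  rows <- lapply(phenotypes, function(ph) {
    f <- stats::as.formula(paste(ph, "~", deparse(fixed[[2]])))
    fit <- microbiability(f, metadata, kern, kinship = kinship, ...)
    s <- m2_summary(fit, definition)
    data.frame(phenotype = ph,
               m2_mean = 100 * s[["mean"]], m2_sd = 100 * s[["sd"]],
               ci95_lo = 100 * s[["ci_lo"]], ci95_hi = 100 * s[["ci_hi"]],
               ess = effective_size(fit$draws_m2),
               rhat = split_rhat(fit$draws_m2),
               n_used = fit$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
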