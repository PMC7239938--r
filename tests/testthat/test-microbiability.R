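# --- kernel ----------------------------------------------------------------

test_that("kernel equals hand-computed W W' / k after centering and rescaling", {
  W <- matrix(c(1, 2, 0,
                3, 0, 1,
                0, 1, 4,
                2, 2, 2), 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
  got <- microbial_kernel(normalized_table(W, "css_log"))
  # independent computation with explicit loops
  Wc <- W
  for (j in 1:3) Wc[, j] <- W[, j] - mean(W[, j])
  M <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) M[i, j] <- sum(Wc[i, ] * Wc[j, ]) / 3
  M <- M / mean(diag(M))
  # a minimal diagonal jitter (~1e-10) may be recorded when numerical
  # rounding leaves the smallest eigenvalue marginally below zero
  expect_equal(unname(got$M), M, tolerance = 1e-8)
  expect_equal(mean(diag(got$M)), 1, tolerance = 1e-8)
  expect_lte(got$jitter, 1e-9)
  expect_identical(got$sample_ids, paste0("s", 1:4))
})

test_that("identical samples reach maximal similarity, orthogonal profiles none", {
  W <- rbind(s1 = c(2, 4, 6), s2 = c(2, 4, 6),
             s3 = c(6, 4, 2), s4 = c(6, 4, 2))
  colnames(W) <- paste0("t", 1:3)
  k <- microbial_kernel(normalized_table(W, "css_log"))
  expect_equal(k$M["s1", "s2"], k$M["s1", "s1"], tolerance = 1e-9)

  # centered profiles of s1/s2 vs s3/s4 are exact opposites here, so the
  # cross-block entries are the negated diagonal; build orthogonal case:
  W2 <- rbind(s1 = c(1, -1, 0, 0), s2 = c(-1, 1, 0, 0),
              s3 = c(0, 0, 1, -1), s4 = c(0, 0, -1, 1)) + 5
  colnames(W2) <- paste0("t", 1:4)
  k2 <- microbial_kernel(normalized_table(W2, "css_log"))
  expect_equal(k2$M["s1", "s3"], 0, tolerance = 1e-12)
  expect_error(microbial_kernel(matrix(0, 2, 0)), "at least one taxon")
})

test_that("kernel matrices are symmetric PSD with unit mean diagonal", {
  co <- simulate_cohort(quick_config(seed = 12))
  k <- microbial_kernel(css_log(co$table))
  expect_equal(k$M, t(k$M), tolerance = 1e-12)
  ev <- eigen(k$M, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(mean(diag(k$M)), 1, tolerance = 1e-9)
})

# --- m2 definitions --------------------------------------------------------

test_that("m2 summaries follow both definitions on fixed draws", {
  fake <- list(draws_var = cbind(sigma2_m = c(1, 1), sigma2_H = c(1, 1),
                                 sigma2_e = c(2, 2)))
  expect_equal(unname(m2_summary(fake, "total")["mean"]), 0.25)
  expect_equal(unname(m2_summary(fake, "literal")["mean"]), 1 / 3)

  null <- list(draws_var = cbind(sigma2_m = 0, sigma2_H = 1, sigma2_e = 2))
  expect_equal(unname(m2_summary(null, "total")["mean"]), 0)
  expect_equal(unname(m2_summary(null, "literal")["mean"]), 0)
  expect_error(m2_summary(list(draws_var = NULL)), "no retained draws")
})

test_that("the total definition never exceeds the literal ratio", {
  co <- simulate_cohort(quick_config(seed = 13))
  fit <- microbiability(pheno_1 ~ breed + timepoint, co$metadata,
                        microbial_kernel(css_log(co$table)),
                        iterations = 1500, burnin = 300, thin = 2, seed = 1)
  v <- fit$draws_var
  lit <- v[, "sigma2_m"] / (v[, "sigma2_H"] + v[, "sigma2_e"])
  expect_true(all(fit$draws_m2 <= lit + 1e-12))
  expect_true(all(fit$draws_m2 >= 0 & fit$draws_m2 <= 1))
  expect_true(all(v[, c("sigma2_m", "sigma2_e")] > 0))
})

# --- Gibbs sampler ---------------------------------------------------------

test_that("the gibbs chain is reproducible and rejects bad designs", {
  co <- simulate_cohort(quick_config(seed = 14))
  kern <- microbial_kernel(css_log(co$table))
  f1 <- microbiability(pheno_1 ~ breed, co$metadata, kern,
                       iterations = 800, burnin = 100, thin = 2, seed = 3)
  f2 <- microbiability(pheno_1 ~ breed, co$metadata, kern,
                       iterations = 800, burnin = 100, thin = 2, seed = 3)
  expect_identical(f1$draws_var, f2$draws_var)
  expect_identical(f1$draws_beta, f2$draws_beta)

  md <- co$metadata
  md$dup <- md$breed  # perfectly aliased factor
  expect_error(microbiability(pheno_1 ~ breed + dup, md, kern,
                              iterations = 200, burnin = 50),
               "rank deficient")
})

test_that("posterior m2 agrees with an independent marginal-likelihood sampler", {
  set.seed(21)
  n <- 40
  co <- simulate_cohort(quick_config(n_hosts = n / 2, seed = 15))
  kern <- microbial_kernel(css_log(co$table))
  y <- co$metadata$pheno_1
  X <- model.matrix(~ timepoint, co$metadata)
  md <- data.frame(y = y, timepoint = co$metadata$timepoint,
                   row.names = rownames(co$metadata))
  fit <- microbiability(y ~ timepoint, md, kern,
                        iterations = 20000, burnin = 2000, thin = 2,
                        seed = 4)
  S2 <- 0.5 * var(y) / 2
  want <- bf_marginal_m2(y, X, kern$M, nu = 5, S2 = S2, n_iter = 30000,
                         seed = 5)
  expect_lt(abs(mean(fit$draws_m2) - want), 0.04)
})

test_that("scaling the phenotype leaves m2 invariant draw by draw", {
  co <- simulate_cohort(quick_config(seed = 16))
  kern <- microbial_kernel(css_log(co$table))
  md <- co$metadata
  md$double <- 2 * md$pheno_1
  f1 <- microbiability(pheno_1 ~ breed + timepoint, md, kern,
                       iterations = 1000, burnin = 200, thin = 2, seed = 6)
  f2 <- microbiability(double ~ breed + timepoint, md, kern,
                       iterations = 1000, burnin = 200, thin = 2, seed = 6)
  expect_equal(f1$draws_m2, f2$draws_m2, tolerance = 1e-9)
  expect_equal(4 * f1$draws_var, f2$draws_var, tolerance = 1e-9)
})

test_that("incomplete phenotypes are fitted on complete cases with a message", {
  co <- simulate_cohort(quick_config(seed = 17))
  kern <- microbial_kernel(css_log(co$table))
  md <- co$metadata
  md$pheno_1[c(2, 5)] <- NA
  expect_message(fit <- microbiability(pheno_1 ~ breed, md, kern,
                                       iterations = 500, burnin = 100),
                 "2 incomplete")
  expect_equal(fit$n, nrow(md) - 2)
  expect_equal(fit$n_dropped, 2)
})

test_that("an identity kernel is unidentifiable and flagged by low ESS", {
  set.seed(30)
  n <- 60
  I_kern <- diag(n)
  dimnames(I_kern) <- list(paste0("s", 1:n), paste0("s", 1:n))
  md <- data.frame(y = rnorm(n), g = gl(2, n / 2),
                   row.names = paste0("s", 1:n))
  fit <- microbiability(y ~ g, md, I_kern, iterations = 4000, burnin = 500,
                        thin = 2, seed = 7)
  s <- summary(fit)
  expect_lt(s$diagnostics[["ess"]], 100)
})

test_that("summary, coef, fitted and residuals are coherent", {
  co <- simulate_cohort(quick_config(seed = 18))
  kern <- microbial_kernel(css_log(co$table))
  fit <- microbiability(pheno_1 ~ breed + timepoint, co$metadata, kern,
                        iterations = 1200, burnin = 200, thin = 2, seed = 8)
  expect_named(coef(fit), colnames(fit$X))
  expect_equal(fitted(fit) + residuals(fit), fit$y, tolerance = 1e-12)
  s <- summary(fit)
  expect_s3_class(s, "summary.microbiability")
  expect_output(print(s), "Microbiability")
  expect_output(print(fit), "m2 =")
})

# --- orchestration ---------------------------------------------------------

test_that("run_microbiability ranks phenotypes by their true microbiability", {
  cfg <- cohort_config(n_hosts = 120, n_taxa = 80, n_core_taxa = 20,
                       depth_range = c(2000, 4000),
                       true_m2 = c(0.05, 0.45), true_h2 = 0.1, seed = 19)
  co <- simulate_cohort(cfg)
  rep <- run_microbiability(co$table, co$metadata,
                            c("pheno_1", "pheno_2"),
                            kinship = co$kinship,
                            iterations = 4000, burnin = 800, thin = 4,
                            seed = 9)
  expect_equal(rep$phenotype, c("pheno_1", "pheno_2"))
  expect_lt(rep$m2_mean[1], rep$m2_mean[2])  # rank order recovered
  expect_true(all(rep$m2_mean >= 0 & rep$m2_mean <= 100))
  expect_true(all(rep$ci95_lo <= rep$m2_mean & rep$m2_mean <= rep$ci95_hi))
  expect_error(run_microbiability(co$table, co$metadata, "nope"),
               "not in metadata")
})
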