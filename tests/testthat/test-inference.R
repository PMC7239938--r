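# --- PERMANOVA -------------------------------------------------------------

test_that("permanova partitions variance: effect sizes sum to one", {
  cfg <- quick_config(seed = 2)
  co <- simulate_cohort(cfg)
  d <- bray_curtis(co$table)
  res <- permanova(d, ~ timepoint + breed, co$metadata, n_perm = 99,
                   seed = 1)
  expect_equal(sum(res$r2[res$term != "Total"]), 1, tolerance = 1e-10)
  expect_equal(res$r2[res$term == "Total"], 1, tolerance = 1e-10)
  expect_true(all(res$p_value > 0 & res$p_value <= 1, na.rm = TRUE))
})

test_that("groups that duplicate each other give pseudo-F near 0 and p near 1", {
  set.seed(1)
  pts <- matrix(rnorm(10 * 3), 10)
  m <- rbind(pts, pts)
  rownames(m) <- paste0("s", 1:20)
  md <- data.frame(g = rep(c("A", "B"), each = 10))
  res <- permanova(dist(m), ~ g, md, n_perm = 199, seed = 1)
  expect_lt(res$statistic[1], 1e-8)
  expect_gt(res$p_value[1], 0.9)
})

test_that("permanova validates its design", {
  d <- dist(matrix(rnorm(12), 6))
  expect_error(permanova(d, ~ g, data.frame(g = rep("A", 6))),
               "single level")
  expect_error(permanova(d, ~ nope, data.frame(g = rep("A", 6))),
               "not found")
})

test_that("strata restrict permutations to within-host label swaps", {
  cfg <- quick_config(seed = 4)
  co <- simulate_cohort(cfg)
  d <- bray_curtis(co$table)
  res <- permanova(d, ~ timepoint, co$metadata, n_perm = 199,
                   strata = co$metadata$host_id, seed = 1)
  expect_true(res$p_value[1] > 0 && res$p_value[1] <= 1)
})

# --- ANOSIM ----------------------------------------------------------------

test_that("anosim R is 1 for perfectly separated groups", {
  m <- rbind(matrix(rnorm(8, 0, 0.1), 4), matrix(rnorm(8, 10, 0.1), 4))
  rownames(m) <- paste0("s", 1:8)
  res <- anosim_test(dist(m), rep(c("A", "B"), each = 4), n_perm = 99,
                     seed = 1)
  expect_equal(res$statistic, 1)
})

test_that("anosim R equals the definition-based oracle on random instances", {
  for (s in 1:8) {
    set.seed(s)
    n <- sample(5:8, 1)
    m <- matrix(rnorm(n * 3), n)
    rownames(m) <- paste0("s", 1:n)
    g <- sample(rep(c("A", "B"), length.out = n))
    if (min(table(g)) < 2) next
    d <- dist(m)
    res <- anosim_test(d, g, n_perm = 49, seed = s)
    expect_equal(res$statistic, bf_anosim_R(d, g), tolerance = 1e-12)
    expect_true(res$statistic >= -1 && res$statistic <= 1)
  }
})

test_that("anosim p-values use the add-one permutation estimator", {
  set.seed(9)
  m <- matrix(rnorm(12 * 2), 12)
  rownames(m) <- paste0("s", 1:12)
  res <- anosim_test(dist(m), rep(c("A", "B"), each = 6), n_perm = 199,
                     seed = 2)
  # p = (1 + #{perm >= obs}) / (1 + n_perm) is a multiple of 1/200
  expect_equal(res$p_value * 200, round(res$p_value * 200))
  expect_gt(res$p_value, 0)
})

# --- SIMPER ----------------------------------------------------------------

test_that("simper limits: single taxon gets contribution 1, constant taxon 0", {
  one <- matrix(c(3, 8, 2, 9), 4, dimnames = list(paste0("s", 1:4), "a"))
  res <- simper_contrib(normalized_table(one, "relative"),
                        rep(c("A", "B"), 2))
  expect_equal(res$contribution, 1)

  m <- cbind(a = c(5, 5, 5, 5), b = c(1, 9, 4, 6))
  rownames(m) <- paste0("s", 1:4)
  res <- simper_contrib(normalized_table(m, "relative"),
                        rep(c("A", "B"), 2))
  expect_equal(res$contribution[res$taxon == "a"], 0)
})

test_that("simper matches exhaustive pair-by-pair computation on a toy table", {
  m <- rbind(s1 = c(8, 1, 1), s2 = c(6, 3, 1),
             s3 = c(1, 7, 2), s4 = c(2, 5, 3))
  colnames(m) <- c("a", "b", "c")
  g <- c("T1", "T1", "T2", "T2")
  res <- simper_contrib(normalized_table(m, "relative"), g)
  want <- bf_simper(m, g)
  expect_equal(res$contribution,
               unname(want[res$taxon]), tolerance = 1e-12)
  expect_equal(sum(res$contribution), 1, tolerance = 1e-9)
  expect_equal(res$cumulative, cumsum(res$contribution))
  expect_error(simper_contrib(normalized_table(m, "relative"),
                              c("A", "B", "C", "A")), "2 groups")
})

test_that("dropping a constant taxon preserves the other contribution ratios", {
  # relative-abundance rows (equal totals) with one constant taxon; the
  # pairwise denominators are then equal and the invariance is exact
  set.seed(12)
  m <- matrix(runif(6 * 3, 1, 10), 6,
              dimnames = list(paste0("s", 1:6), c("t1", "t3", "t4")))
  m <- 0.8 * m / rowSums(m)
  m <- cbind(m, t2 = 0.2)[, c("t1", "t2", "t3", "t4")]
  g <- rep(c("A", "B"), each = 3)
  full <- simper_contrib(normalized_table(m, "relative"), g)
  red <- simper_contrib(normalized_table(m[, -2], "relative"), g)
  keep <- full[full$taxon != "t2", ]
  ratio <- keep$contribution / red$contribution[match(keep$taxon, red$taxon)]
  expect_equal(ratio, rep(ratio[1], 3), tolerance = 1e-9)
})

# --- NMDS ------------------------------------------------------------------

test_that("nmds embeds line-like data with near-zero stress", {
  x <- matrix(c(seq(0, 10, length.out = 12), rep(0, 12)), ncol = 2)
  rownames(x) <- paste0("s", 1:12)
  ord <- nmds(dist(x), k = 2, n_starts = 5, seed = 1)
  expect_lt(ord$stress, 0.01)
  expect_equal(unname(colMeans(ord$scores)), c(0, 0), tolerance = 1e-8)
})

test_that("duplicated samples land on coincident scores", {
  set.seed(3)
  base <- matrix(rnorm(8 * 3), 8)
  m <- rbind(base, base[1, , drop = FALSE])
  rownames(m) <- paste0("s", 1:9)
  ord <- nmds(dist(m), n_starts = 5, seed = 2)
  expect_lt(sqrt(sum((ord$scores[1, ] - ord$scores[9, ])^2)), 1e-3)
})

test_that("nmds is deterministic under a seed", {
  set.seed(11)
  m <- matrix(rnorm(10 * 4), 10)
  rownames(m) <- paste0("s", 1:10)
  o1 <- nmds(dist(m), n_starts = 3, seed = 5)
  o2 <- nmds(dist(m), n_starts = 3, seed = 5)
  expect_identical(o1$scores, o2$scores)
  expect_identical(o1$stress, o2$stress)
})

# --- covariate fitting -----------------------------------------------------

test_that("a covariate equal to an axis has r2 near 1; constants warn", {
  set.seed(4)
  m <- matrix(rnorm(20 * 3), 20)
  rownames(m) <- paste0("s", 1:20)
  ord <- nmds(dist(m), n_starts = 5, seed = 1)
  md <- data.frame(axis = ord$scores[, 1], noise = rnorm(20),
                   flat = rep(1, 20))
  expect_warning(res <- fit_covariates(ord, md, n_perm = 99, seed = 1),
                 "constant")
  expect_gt(res$r2[res$covariate == "axis"], 0.999)
  expect_equal(res$r2[res$covariate == "flat"], 0)
  expect_true(is.na(res$p_value[res$covariate == "flat"]))
})

test_that("a factor whose levels are duplicated point sets fits r2 near 1", {
  set.seed(5)
  centers <- matrix(c(0, 0, 8, 0, 0, 8), 3, byrow = TRUE)
  pts <- centers[rep(1:3, each = 6), ] + matrix(rnorm(36, sd = 0.05), 18)
  rownames(pts) <- paste0("s", 1:18)
  ord <- nmds(dist(pts), n_starts = 5, seed = 1)
  res <- fit_covariates(ord, data.frame(g = factor(rep(1:3, each = 6))),
                        n_perm = 99, seed = 1)
  expect_gt(res$r2, 0.99)
  expect_lt(res$p_adjusted, 0.05)
  expect_equal(attr(res, "combined_effect_size"), res$r2)
})

# --- temporal deltas -------------------------------------------------------

test_that("delta phenotypes are hand-checkable differences T2 - T1", {
  md <- data.frame(
    sample_id = c("h1_T1", "h1_T2", "h2_T1", "h2_T2"),
    host_id = c("h1", "h1", "h2", "h2"),
    timepoint = c("T1", "T2", "T1", "T2"),
    breed = c("x", "x", "y", "y"),
    ph = c(1.5, 4.0, 10, 7))
  d <- delta_phenotypes(md)
  expect_equal(d$delta_ph, c(4.0 - 1.5, 7 - 10))
  expect_equal(d$breed, c("x", "y"))  # time-invariant carried through

  flipped <- delta_phenotypes(md, order = c("T1", "T2"))
  expect_equal(flipped$delta_ph, -d$delta_ph)  # antisymmetry
})

test_that("hosts missing a time point are dropped and logged", {
  md <- data.frame(host_id = c("h1", "h1", "h2"),
                   timepoint = c("T1", "T2", "T1"),
                   ph = c(1, 2, 3))
  expect_message(d <- delta_phenotypes(md), "h2")
  expect_equal(nrow(d), 1)
})

# --- cross correlation -----------------------------------------------------

test_that("cross correlation recovers exact and hand-computed coefficients", {
  m <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 1, 4, 3, 6))
  rownames(m) <- paste0("s", 1:5)
  nt <- normalized_table(m, "relative")
  ph <- data.frame(self = m[, "a"], other = c(5, 1, 4, 2, 3))
  res <- cross_correlate(nt, ph)
  expect_equal(res$r[res$taxon == "a" & res$phenotype == "self"], 1)

  # closed-form Pearson r on a printed triple
  x <- c(1, 2, 4); y <- c(2, 1, 5)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  m3 <- cbind(a = x)
  rownames(m3) <- paste0("s", 1:3)
  res3 <- cross_correlate(normalized_table(m3, "relative"),
                          data.frame(y = y))
  expect_equal(res3$r, r_hand)
})

test_that("zero-variance cells are flagged and excluded from the BH family", {
  m <- cbind(a = c(1, 2, 3, 4), flat = c(2, 2, 2, 2))
  rownames(m) <- paste0("s", 1:4)
  res <- cross_correlate(normalized_table(m, "relative"),
                         data.frame(y = c(4, 3, 2, 1)))
  expect_true(is.na(res$r[res$taxon == "flat"]))
  expect_true(is.na(res$p_adjusted[res$taxon == "flat"]))
  expect_false(res$sig_05[res$taxon == "flat"])
})
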