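#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a longitudinal sport-horse cohort: 185 hosts sampled
#' at two time points eight months apart, 10,000-60,000 16S reads per
#' sample, a stable prevalent core of 29 genera carrying most of the
#' reads, a volatile rare fraction with host-specific signatures and
#' presence turnover between time points, categorical husbandry factors,
#' and phenotypes generated under the microbiability mixed model with a
#' known true m2.
#'
#' @param n_hosts Number of hosts (default 185).
#' @param n_timepoints Time points per host (default 2).
#' @param n_taxa Number of taxa (default 150).
#' @param n_core_taxa Number of designated core taxa (default 29).
#' @param depth_range Min/max reads per sample (default `c(10000, 60000)`).
#' @param host_sd Log-scale SD of host-specific taxon intercepts for rare
#'   taxa (core taxa get a quarter of it; default 1).
#' @param time_shift_sd Log-scale SD of per-taxon time effects (default 0.3).
#' @param rare_turnover Probability a rare taxon flips presence between
#'   time points within a host (default 0.3).
#' @param overdispersion Dirichlet-multinomial concentration; `Inf` gives
#'   pure multinomial sampling (default 500).
#' @param n_breeds,n_disciplines Category counts (default 4 each).
#' @param fixed_effect_sizes Named SDs of the phenotype fixed effects
#'   (`breed`, `discipline`, `time`).
#' @param true_m2 True microbiability of each generated phenotype (vector
#'   allowed; default 0.25).
#' @param true_h2 True host-genetic fraction (default 0.1).
#' @param seed Integer seed; expands to independent sub-seeds for the
#'   counts / tree / phenotype stages.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_hosts = 185, n_timepoints = 2, n_taxa = 150,
                          n_core_taxa = 29,
                          depth_range = c(10000, 60000),
                          host_sd = 1, time_shift_sd = 0.3,
                          rare_turnover = 0.3, overdispersion = 500,
                          n_breeds = 4, n_disciplines = 4,
                          fixed_effect_sizes = c(breed = 0.3,
                                                 discipline = 0.3,
                                                 time = 0.25),
                          true_m2 = 0.25, true_h2 = 0.1, seed = 1) {
  cfg <- list(n_hosts = n_hosts, n_timepoints = n_timepoints,
              n_taxa = n_taxa, n_core_taxa = n_core_taxa,
              depth_range = depth_range, host_sd = host_sd,
              time_shift_sd = time_shift_sd, rare_turnover = rare_turnover,
              overdispersion = overdispersion, n_breeds = n_breeds,
              n_disciplines = n_disciplines,
              fixed_effect_sizes = fixed_effect_sizes,
              true_m2 = true_m2, true_h2 = true_h2, seed = seed)
  if (any(cfg$true_m2 + cfg$true_h2 >= 1))
    stop("invalid config: true_m2 + true_h2 must be < 1")
  if (any(cfg$true_m2 < 0) || cfg$true_h2 < 0)
    stop("invalid config: true_m2 and true_h2 must be >= 0")
  if (n_core_taxa > n_taxa)
    stop("invalid config: n_core_taxa exceeds n_taxa")
  if (length(depth_range) != 2 || depth_range[1] < 1 ||
      depth_range[2] < depth_range[1])
    stop("invalid config: depth_range must be an increasing pair with min >= 1")
  if (rare_turnover < 0 || rare_turnover > 1)
    stop("invalid config: rare_turnover must be in [0, 1]")
  if (n_hosts < 1 || n_timepoints < 1 || n_taxa < 1)
    stop("invalid config: n_hosts, n_timepoints, n_taxa must be >= 1")
  class(cfg) <- "cohort_config"
  cfg
}

# one global seed -> reproducible per-stage sub-seeds
.stage_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1, 3)
  names(s) <- c("counts", "tree", "phenotypes")
  s
}

#' Simulate a cohort count table with known structure
#'
#' Counts are Dirichlet-multinomial draws around a per-sample expected
#' composition built from (i) log-uniform base weights under which the
#' designated core taxa carry most of the reads, (ii) host-specific
#' log-normal signatures (full `host_sd` for rare taxa, a quarter of it
#' for the stable core), (iii) per-taxon log-scale time shifts applied
#' after baseline, and (iv) presence/absence of rare taxa per host that
#' flips between time points with probability `rare_turnover`. Depth is
#' drawn uniformly from `depth_range`.
#'
#' @param config A [cohort_config()].
#' @return List: `table` (a [feature_table()], rows `<host>_T<t>`),
#'   `truth` (class `cohort_truth`: `core_taxa`, `host_signatures`,
#'   `time_effects`, `base_weights`, `presence`, `metadata` with host,
#'   timepoint, breed, discipline, specialty, bedding).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(.stage_seeds(config$seed)[["counts"]])
  nh <- config$n_hosts; nt <- config$n_timepoints
  nx <- config$n_taxa; nc <- config$n_core_taxa
  taxa <- sprintf("g%03d", seq_len(nx))
  hosts <- sprintf("H%03d", seq_len(nh))
  core <- taxa[seq_len(nc)]
  is_core <- seq_len(nx) <= nc

  # base composition: core taxa log-uniform in a high band, rare in a
  # low heavy-tailed band (core ~ 75% of reads at defaults)
  w <- numeric(nx)
  w[is_core] <- exp(stats::runif(nc, log(10), log(40)))
  w[!is_core] <- exp(stats::runif(nx - nc, log(0.05), log(8)))

  sig_sd <- ifelse(is_core, 0.25 * config$host_sd, config$host_sd)
  host_sig <- matrix(stats::rnorm(nh * nx, 0, rep(sig_sd, each = nh)),
                     nh, nx, dimnames = list(hosts, taxa))
  time_eff <- matrix(0, nt, nx, dimnames = list(paste0("T", seq_len(nt)), taxa))
  if (nt > 1)
    time_eff[-1, ] <- stats::rnorm((nt - 1) * nx, 0, config$time_shift_sd)

  # rare-taxon presence per host and time point
  prev <- ifelse(is_core, 1, stats::runif(nx, 0.1, 0.7))
  presence <- array(1L, c(nh, nx, nt),
                    dimnames = list(hosts, taxa, rownames(time_eff)))
  presence[, !is_core, 1] <- stats::rbinom(nh * sum(!is_core), 1,
                                           rep(prev[!is_core], each = nh))
  if (nt > 1) for (t in 2:nt) {
    flip <- matrix(stats::rbinom(nh * sum(!is_core), 1,
                                 config$rare_turnover), nh)
    presence[, !is_core, t] <-
      ifelse(flip == 1, 1L - presence[, !is_core, t - 1],
             presence[, !is_core, t - 1])
  }

  samples <- as.vector(t(outer(hosts, rownames(time_eff), paste, sep = "_")))
  counts <- matrix(0L, nh * nt, nx, dimnames = list(samples, taxa))
  logw <- log(w)
  for (h in seq_len(nh)) for (t in seq_len(nt)) {
    ew <- exp(logw + host_sig[h, ] + time_eff[t, ]) * presence[h, , t]
    p <- ew / sum(ew)
    if (is.finite(config$overdispersion)) {
      g <- stats::rgamma(nx, shape = config$overdispersion * p)
      p <- if (sum(g) > 0) g / sum(g) else p
    }
    depth <- config$depth_range[1] +
      sample.int(config$depth_range[2] - config$depth_range[1] + 1, 1) - 1
    counts[(h - 1) * nt + t, ] <- stats::rmultinom(1, depth, p)[, 1]
  }

  taxonomy <- .invent_taxonomy(taxa, is_core)
  meta <- .invent_metadata(hosts, rownames(time_eff), config)
  truth <- structure(list(core_taxa = core, host_signatures = host_sig,
                          time_effects = time_eff, base_weights = w,
                          presence = presence, metadata = meta,
                          config = config),
                     class = "cohort_truth")
  list(table = feature_table(counts, taxonomy = taxonomy), truth = truth)
}

.invent_taxonomy <- function(taxa, is_core) {
  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
             "Spirochaetes", "Fibrobacteres", "Verrucomicrobia")
  fam_pool <- list(
    Firmicutes = c("Lachnospiraceae", "Ruminococcaceae",
                   "Erysipelotrichaceae", "Streptococcaceae"),
    Bacteroidetes = c("Porphyromonadaceae", "Prevotellaceae",
                      "Rikenellaceae"),
    Proteobacteria = c("Succinivibrionaceae", "Desulfovibrionaceae"),
    Spirochaetes = "Spirochaetaceae",
    Fibrobacteres = "Fibrobacteraceae",
    Verrucomicrobia = "Verrucomicrobiaceae")
  # core skews Firmicutes/Bacteroidetes as in real equine tables
  pr_core <- c(0.55, 0.25, 0.05, 0.06, 0.06, 0.03)
  pr_rare <- c(0.30, 0.20, 0.30, 0.08, 0.04, 0.08)
  ph <- ifelse(is_core, sample(phyla, length(taxa), TRUE, pr_core),
               sample(phyla, length(taxa), TRUE, pr_rare))
  fam <- vapply(ph, function(p) sample(fam_pool[[p]], 1), "")
  data.frame(phylum = ph, class = paste0(ph, "_class"),
             order = paste0(fam, "_order"), family = fam,
             genus = taxa, row.names = taxa, stringsAsFactors = FALSE)
}

.invent_metadata <- function(hosts, timepoints, config) {
  nh <- length(hosts)
  breeds <- sample(paste0("breed", seq_len(config$n_breeds)), nh, TRUE)
  disc <- sample(paste0("discipline", seq_len(config$n_disciplines)), nh,
                 TRUE)
  spec <- sample(c("gala", "cadre_noir", "competition", "formation"), nh,
                 TRUE, prob = c(0.15, 0.15, 0.35, 0.35))
  bedding <- sample(c("straw", "shavings", "pellets"), nh, TRUE,
                    prob = c(0.71, 0.20, 0.09))
  grid <- expand.grid(timepoint = timepoints, host_id = hosts,
                      stringsAsFactors = FALSE)[, 2:1]
  i <- match(grid$host_id, hosts)
  out <- data.frame(sample_id = paste(grid$host_id, grid$timepoint,
                                      sep = "_"),
                    host_id = grid$host_id, timepoint = grid$timepoint,
                    breed = breeds[i], discipline = disc[i],
                    specialty = spec[i], bedding = bedding[i],
                    stringsAsFactors = FALSE)
  rownames(out) <- out$sample_id
  out
}

#' Simulate a rooted taxon tree
#'
#' Pure-birth (Yule) tree with strictly positive branch lengths, leaves
#' labelled by the taxon ids, for UniFrac computations.
#'
#' @param n_taxa Number of leaves (>= 2), or pass `taxon_ids`.
#' @param seed Integer seed.
#' @param taxon_ids Optional leaf labels (default `g001`, `g002`, ...).
#' @return An `ape::phylo` object.
#' @export
simulate_tree <- function(n_taxa, seed = 1, taxon_ids = NULL) {
  if (!is.null(taxon_ids)) n_taxa <- length(taxon_ids)
  if (n_taxa < 2) stop("a tree needs at least 2 taxa")
  set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tree$tip.label <- if (is.null(taxon_ids)) sprintf("g%03d", seq_len(n_taxa))
                    else taxon_ids
  tree
}

#' Simulate phenotypes under the microbiability model
#'
#' Generates continuous phenotypes `y = mu + X beta + u_m + u_g + e` where
#' `u_m ~ N(0, sigma2_m M)` uses the microbial kernel computed from the
#' generated count table (CSS-log path), `u_g ~ N(0, sigma2_H K)` uses a
#' block-by-breed host kinship, and the component variances are scaled so
#' that `sigma2_m / (sigma2_m + sigma2_H + sigma2_e)` equals each
#' requested `true_m2` exactly (total variance 1). Each phenotype also
#' gets a bounded "behaviour frequency" companion column obtained by a
#' logistic map of the standardized latent value.
#'
#' @param table The [feature_table()] from [simulate_counts()].
#' @param truth The matching `cohort_truth`.
#' @param config The [cohort_config()] used.
#' @return List: `metadata` (truth metadata + phenotype columns `pheno_i`
#'   and `freq_pheno_i`), `truth` updated with `beta_true`, `u_microbial`,
#'   `u_genetic`, `m2_true`, `h2_true`, and `kinship` (host-level matrix).
#' @export
simulate_phenotypes <- function(table, truth, config) {
  stopifnot(inherits(truth, "cohort_truth"))
  meta <- truth$metadata
  if (!identical(rownames(table$counts), meta$sample_id))
    stop("table rows do not align with truth metadata")
  set.seed(.stage_seeds(config$seed)[["phenotypes"]])
  n <- nrow(meta)

  kern <- microbial_kernel(css_log(table))
  em <- eigen(kern$M, symmetric = TRUE)
  em$values[em$values < 0] <- 0
  Lm <- em$vectors %*% diag(sqrt(em$values), n)

  K <- kinship_by_breed(meta)
  Lk <- chol(K + diag(1e-8, nrow(K)))
  hosts <- rownames(K)

  X <- stats::model.matrix(~ breed + discipline + timepoint, meta)
  fes <- config$fixed_effect_sizes
  sd_for <- function(cn) {
    if (grepl("^breed", cn)) fes[["breed"]]
    else if (grepl("^discipline", cn)) fes[["discipline"]]
    else if (grepl("^timepoint", cn)) fes[["time"]]
    else 0  # intercept
  }
  beta <- vapply(colnames(X), function(cn) stats::rnorm(1, 0, sd_for(cn)), 0)
  xb <- drop(X %*% beta)

  m2 <- config$true_m2
  h2 <- config$true_h2
  um <- matrix(0, n, length(m2))
  ug <- matrix(0, n, length(m2))
  y <- matrix(0, n, length(m2))
  for (j in seq_along(m2)) {
    s_m <- sqrt(m2[j]); s_h <- sqrt(h2); s_e <- sqrt(1 - m2[j] - h2)
    um[, j] <- if (m2[j] > 0) s_m * drop(Lm %*% stats::rnorm(n)) else 0
    g_host <- s_h * drop(crossprod(Lk, stats::rnorm(length(hosts))))
    ug[, j] <- g_host[match(meta$host_id, hosts)]
    y[, j] <- xb + um[, j] + ug[, j] + stats::rnorm(n, 0, s_e)
  }
  colnames(y) <- paste0("pheno_", seq_along(m2))
  meta[colnames(y)] <- y
  freq <- stats::plogis(scale(y))
  meta[paste0("freq_", colnames(y))] <- freq

  truth$beta_true <- beta
  truth$u_microbial <- um
  truth$u_genetic <- ug
  truth$m2_true <- m2
  truth$h2_true <- h2
  list(metadata = meta, truth = truth, kinship = K)
}

#' Block-by-breed host kinship
#'
#' Hosts of the same breed get relatedness 0.25, unrelated breeds 0,
#' diagonal 1 -- the only genetic-structure signal available when no
#' pedigree exists.
#'
#' @param metadata data.frame with `host_id` and `breed` columns (one or
#'   more rows per host).
#' @return Host x host matrix with host ids as dimnames.
#' @export
kinship_by_breed <- function(metadata) {
  per_host <- unique(metadata[, c("host_id", "breed")])
  hosts <- per_host$host_id
  K <- outer(per_host$breed, per_host$breed,
             function(a, b) ifelse(a == b, 0.25, 0))
  diag(K) <- 1
  dimnames(K) <- list(hosts, hosts)
  K
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper chaining [simulate_counts()], [simulate_tree()] and
#' [simulate_phenotypes()].
#'
#' @param config A [cohort_config()] (default config if omitted).
#' @return List of class `synthetic_cohort`: `table`, `tree`, `metadata`,
#'   `kinship`, `truth`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  cts <- simulate_counts(config)
  tree <- simulate_tree(config$n_taxa,
                        seed = .stage_seeds(config$seed)[["tree"]],
                        taxon_ids = colnames(cts$table$counts))
  ph <- simulate_phenotypes(cts$table, cts$truth, config)
  structure(list(table = cts$table, tree = tree, metadata = ph$metadata,
                 kinship = ph$kinship, truth = ph$truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", x$config$n_hosts, "hosts x",
      x$config$n_timepoints, "time points,", x$config$n_taxa, "taxa (",
      x$config$n_core_taxa, "core ), true m2 =",
      paste(x$truth$m2_true, collapse = "/"), "\n")
  invisible(x)
}

#' Write a cohort to plain-text files
#'
#' Writes counts TSV, taxonomy TSV, metadata TSV, newick tree, kinship
#' TSV and a truth JSON into `dir`. Re-running the generator with the same
#' seed and writing again produces byte-identical files.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_feature_table(cohort$table, p("counts.tsv"))
  write_taxonomy(cohort$table$taxonomy, p("taxonomy.tsv"))
  utils::write.table(cohort$metadata, p("metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(cohort$tree, p("tree.nwk"))
  utils::write.table(
    data.frame(host_id = rownames(cohort$kinship), cohort$kinship,
               check.names = FALSE),
    p("kinship.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- cohort$truth
  json <- .to_json(list(m2_true = tr$m2_true, h2_true = tr$h2_true,
                        core_taxa = tr$core_taxa,
                        beta_true = as.list(tr$beta_true),
                        seed = cohort$config$seed))
  writeLines(json, p("truth.json"))
  invisible(dir)
}

# minimal JSON writer (scalars, vectors, named lists) with full precision
.to_json <- function(x) {
  esc <- function(s) gsub('"', '\\\\"', s)
  atom <- function(v) {
    if (is.character(v)) paste0('"', esc(v), '"')
    else if (is.logical(v)) ifelse(v, "true", "false")
    else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }
  go <- function(v) {
    if (is.list(v) && !is.null(names(v)))
      paste0("{", paste0('"', esc(names(v)), '":',
                         vapply(v, go, ""), collapse = ","), "}")
    else if (length(v) == 1 && !is.list(v)) atom(v)
    else paste0("[", paste(vapply(as.list(v), go, ""), collapse = ","), "]")
  }
  go(x)
}
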