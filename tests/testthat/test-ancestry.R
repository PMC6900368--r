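make_panel <- function(freq, chrom = NULL, ref = NULL, alt = NULL,
                       counts = NULL) {
  L <- nrow(freq)
  snps <- data.frame(
    chrom = chrom %||% rep("chr1", L),
    pos = seq_len(L) * 10L,
    ref = ref %||% rep("A", L),
    alt = alt %||% rep("G", L),
    stringsAsFactors = FALSE
  )
  reference_panel(snps, freq, counts = counts)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("panel QC removes multi-allelic, sex-chromosome and rare sites", {
  set.seed(2)
  L <- 100
  freq <- matrix(runif(2 * L, 0.3, 0.7), ncol = 2,
                 dimnames = list(NULL, c("A", "B")))
  chrom <- rep("chr1", L)
  alt <- rep("G", L)
  alt[1:2] <- "G,T"                       # tri-allelic
  chrom[3:5] <- "chrX"                    # sex chromosome
  freq[6:10, ] <- 0.01                    # rare
  panel <- make_panel(freq, chrom = chrom, alt = alt)
  qc <- qc_panel(panel, maf_min = 0.05)
  expect_equal(nrow(qc$snps), 90)
  expect_equal(unname(attr(qc, "qc")["multi_allelic"]), 2L)
  expect_equal(unname(attr(qc, "qc")["sex_chrom"]), 3L)
  expect_equal(unname(attr(qc, "qc")["low_maf"]), 5L)
  # all-passing panel unchanged; exact-boundary MAF retained
  clean <- make_panel(matrix(c(0.05, 0.5, 0.05, 0.5), ncol = 2,
                             dimnames = list(NULL, c("A", "B"))))
  qc2 <- qc_panel(clean, maf_min = 0.05)
  expect_equal(nrow(qc2$snps), 2)
})

test_that("LD pruning drops one of each correlated pair and verifies by exhaustive check", {
  set.seed(8)
  # two perfectly correlated sites -> one retained (the earlier)
  g <- cbind(rbinom(50, 2, 0.5))
  g <- cbind(g, g)
  expect_equal(ld_prune(g, window_snps = 10, step_snps = 2, r2_max = 0.5), 1L)

  # independent sites survive
  G <- matrix(rbinom(200 * 20, 2, 0.5), nrow = 200)
  kept <- ld_prune(G, window_snps = 10, step_snps = 2, r2_max = 0.5)
  r2 <- cor(G)^2; diag(r2) <- 0
  if (max(r2) <= 0.5) expect_equal(kept, 1:20)

  # 200-site panel with planted LD: postcondition holds by brute force
  n <- 150; L <- 200
  base <- matrix(rbinom(n * L, 2, 0.5), nrow = n)
  for (j in seq(5, L, by = 7)) base[, j] <- base[, j - 1]  # duplicated sites
  cfg <- list(window = 25, step = 5, r2 = 0.5)
  kept <- ld_prune(base, cfg$window, cfg$step, cfg$r2)
  expect_true(length(kept) < L)
  expect_equal(kept, sort(kept))  # input order preserved
  for (s in seq(1, L, by = cfg$step)) {
    idx <- kept[kept >= s & kept <= min(L, s + cfg$window - 1)]
    if (length(idx) < 2) next
    r2 <- suppressWarnings(cor(base[, idx])^2)
    diag(r2) <- 0
    r2[!is.finite(r2)] <- 0
    expect_lte(max(r2), cfg$r2)
  }
})

test_that("PCA projection reproduces a duplicated panel individual", {
  set.seed(21)
  G <- matrix(rbinom(40 * 100, 2, runif(100, 0.1, 0.9)), nrow = 40,
              byrow = TRUE)
  proj <- pca_project(G, G[7, ], n_pcs = 2)
  expect_equal(as.numeric(proj$query), as.numeric(proj$panel[7, ]),
               tolerance = 1e-6)
  expect_error(pca_project(G[, 1:1], G[1, 1, drop = FALSE], n_pcs = 2),
               "fewer")
})

test_that("PCA separates differentiated populations and places the query", {
  cfg <- sim_config(seed = 13, n_populations = 2, n_snps = 500,
                    fst = 0.1, n_per_pop = 100)
  sim <- simulate_panel(cfg)
  set.seed(14)
  qa <- rbinom(500, 2, sim$panel$freq[, "POP1"])
  proj <- pca_project(sim$genotypes, qa, n_pcs = 2)
  pc1 <- proj$panel[, 1]
  a <- pc1[sim$pop == "POP1"]; b <- pc1[sim$pop == "POP2"]
  # PC1 separates the populations with zero overlap
  expect_true(max(a) < min(b) || max(b) < min(a))
  # the query lands within its source population's PC1 span
  expect_gte(proj$query[1, 1], min(a) - 1e-9)
  expect_lte(proj$query[1, 1], max(a) + 1e-9)
})

test_that("a panel of identical individuals has no principal variance", {
  G <- matrix(1, nrow = 20, ncol = 30)
  G[, 1] <- c(rep(0, 10), rep(2, 10))  # one informative site to avoid rank 0
  proj <- pca_project(G, G[1, ], n_pcs = 2)
  expect_lt(proj$sdev[2], 1e-8)
})

test_that("block log-likelihoods implement smoothed per-site products", {
  freq <- matrix(c(0.5, 0.2), ncol = 2,
                 dimnames = list(NULL, c("A", "B")))
  panel <- make_panel(freq)
  hap <- setNames(1L, panel$snps$id[1])
  # alpha -> 0 limit approaches log of the population frequency
  ll <- block_loglik(hap, panel, "A", alpha = 1e-9)
  expect_equal(ll, log(0.5), tolerance = 1e-6)
  # zero-count allele stays finite and equals the smoothing formula
  freq0 <- matrix(c(0, 0.5), ncol = 2, dimnames = list(NULL, c("A", "B")))
  panel0 <- make_panel(freq0)
  ll0 <- block_loglik(setNames(1L, panel0$snps$id[1]), panel0, "A",
                      alpha = 0.5, nominal_chromosomes = 100)
  expect_equal(ll0, log(0.5 / 101))
  expect_error(block_loglik(setNames(1L, "chrZ:1"), panel, "A"), "absent")

  # 20-site block equals an independent per-site product
  set.seed(4)
  L <- 20
  f <- matrix(runif(2 * L, 0.05, 0.95), ncol = 2,
              dimnames = list(NULL, c("A", "B")))
  p20 <- make_panel(f, counts = c(A = 120, B = 80))
  hap <- setNames(rbinom(L, 1, 0.5), p20$snps$id)
  oracle <- 0
  for (i in seq_len(L)) {
    c1 <- f[i, "A"] * 120
    c_obs <- if (hap[i] == 1) c1 else 120 - c1
    oracle <- oracle + log((c_obs + 0.5) / (120 + 1))
  }
  expect_equal(block_loglik(hap, p20, "A", alpha = 0.5), oracle,
               ignore_attr = TRUE)
})

test_that("posterior normalization is stable, symmetric and label-equivariant", {
  ll <- c(A = -10, B = -10, C = -10)
  post <- population_posterior(ll)
  expect_equal(unname(post$prob), rep(1 / 3, 3))
  expect_equal(sum(post$prob), 1, tolerance = 1e-9)
  # a dominating population takes essentially all mass
  post <- population_posterior(c(A = -10, B = -60, C = -70))
  expect_gte(post$prob[["A"]], 1 - 1e-20)
  # extreme magnitudes do not overflow
  post <- population_posterior(c(A = -1e5, B = -1e5 - 1))
  expect_equal(sum(post$prob), 1, tolerance = 1e-9)
  expect_error(population_posterior(c(A = -Inf, B = -Inf)), "non-finite")
  # label equivariance
  ll <- c(A = -3, B = -5, C = -4)
  p1 <- population_posterior(ll)$prob
  p2 <- population_posterior(ll[c("C", "A", "B")])$prob
  expect_equal(p2[names(p1)], p1)
})

test_that("uninformative sites leave the posterior unchanged", {
  set.seed(6)
  L <- 30
  f <- matrix(runif(3 * L, 0.1, 0.9), ncol = 3,
              dimnames = list(NULL, c("A", "B", "C")))
  f <- rbind(f, matrix(0.4, 1, 3))  # equal-frequency site
  panel <- make_panel(f)
  hap_core <- rbinom(L, 1, 0.5)
  h1 <- setNames(c(hap_core, NA)[1:L], panel$snps$id[1:L])
  h2 <- setNames(c(hap_core, 1L), panel$snps$id)
  p1 <- population_posterior(sapply(panel$populations, function(k)
    block_loglik(h1, panel, k)))$prob
  p2 <- population_posterior(sapply(panel$populations, function(k)
    block_loglik(h2, panel, k)))$prob
  expect_equal(max(abs(p1 - p2)), 0, tolerance = 1e-12)
})

test_that("population ranking orders by probability and flags ties", {
  post <- population_posterior(c(A = log(0.7), B = log(0.2), C = log(0.1)))
  r <- rank_populations(post)
  expect_equal(r$population, c("A", "B", "C"))
  tie <- population_posterior(c(B = log(0.5), A = log(0.5)))
  rt <- rank_populations(tie)
  expect_equal(rt$population, c("A", "B"))  # lexical tie-break
  expect_true(all(rt$tied))
})

test_that("recovery accuracy grows with block length and differentiation", {
  accs <- vapply(c(10, 100), function(L) {
    origin_recovery_experiment(block_sites = L, replicates = 60,
                               seed = 19)$accuracy
  }, numeric(1))
  expect_gt(accs[2], accs[1])
  fst_accs <- vapply(c(0.02, 0.15), function(f) {
    origin_recovery_experiment(fst = f, block_sites = 60, replicates = 60,
                               seed = 23)$accuracy
  }, numeric(1))
  expect_gte(fst_accs[2], fst_accs[1])
})
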