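test_that("panel simulation is deterministic and tracks its parameters", {
  cfg <- sim_config(seed = 33, n_snps = 200, n_per_pop = 50)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$panel$freq, b$panel$freq)
  expect_identical(a$genotypes, b$genotypes)
  expect_equal(ncol(a$panel$freq), 6)
  expect_equal(nrow(a$genotypes), 6 * 50)
})

test_that("weak differentiation keeps population frequencies near ancestral", {
  cfg <- sim_config(seed = 40, n_snps = 1000, fst = 1e-4, n_populations = 2)
  sim <- simulate_panel(cfg)
  set.seed(40)
  p <- runif(1000, 0.05, 0.95)  # the generator's ancestral draw
  close <- abs(sim$panel$freq[, 1] - p) < 0.05
  expect_gte(mean(close), 0.99)
})

test_that("realized sample frequencies track generating frequencies", {
  cfg <- sim_config(seed = 50, n_snps = 300, n_per_pop = 500,
                    n_populations = 2, fst = 0.05)
  sim <- simulate_panel(cfg)
  for (k in c("POP1", "POP2")) {
    obs <- colMeans(sim$genotypes[sim$pop == k, ]) / 2
    expect_lt(mean(abs(obs - sim$panel$freq[, k])), 0.03)
  }
})

test_that("the compound-het kindred plants both alleles into the proband", {
  cfg <- sim_config(seed = 60, pedigree_spec = "kindred1_like")
  sim <- simulate_pedigree(cfg)
  dos <- dosage_matrix(sim$genotype_table)
  expect_true(all(dos["1-1", ] >= 1))  # ascertained compound carrier
  # identical seed, identical kindred
  sim2 <- simulate_pedigree(cfg)
  expect_identical(sim$genotype_table$geno, sim2$genotype_table$geno)
  # Mendelian consistency: every child allele count is attainable from
  # its parents
  ped <- sim$pedigree$members
  for (i in seq_len(nrow(ped))) {
    if (is.na(ped$father_id[i])) next
    for (v in colnames(dos)) {
      d <- dos[ped$subject_id[i], v]
      df <- dos[ped$father_id[i], v]; dm <- dos[ped$mother_id[i], v]
      expect_gte(d, (df == 2) + (dm == 2))
      expect_lte(d, (df >= 1) + (dm >= 1))
    }
  }
})

test_that("a homozygous parent always transmits one allele", {
  cfg <- sim_config(seed = 61, pedigree_spec = "kindred2_like")
  sim <- simulate_pedigree(cfg)
  dos <- dosage_matrix(sim$genotype_table)
  expect_equal(unname(dos["1-1", 1]), 2L)  # ascertained homozygote
  # all children of two carriers hold at least the transmitted alleles
  expect_true(all(dos[c("1-2", "1-3"), 1] %in% 0:2))
})

test_that("heterozygous transmission is a fair coin across simulations", {
  # non-ascertained sibling 1-2 of the homozygous kindred receives the
  # paternal allele with probability 1/2
  doses <- vapply(1:400, function(s) {
    sim <- simulate_pedigree(sim_config(seed = 6000 + s,
                                        pedigree_spec = "kindred2_like"))
    dosage_matrix(sim$genotype_table)["1-2", 1]
  }, numeric(1))
  # dosage of a child of two hets: 0/1/2 with probs 1/4, 1/2, 1/4
  expect_lt(abs(mean(doses) - 1), 0.11)        # 3 SE for 400 draws
  expect_lt(abs(mean(doses == 1) - 0.5), 0.08) # 3 SE binomial bound
})

test_that("phenotypes follow the genotype-dose means", {
  cfg <- sim_config(seed = 70, pedigree_spec = "kindred2_like")
  sim <- simulate_pedigree(cfg)
  # zero noise: class means are exact
  ped0 <- simulate_phenotypes(sim, list(means = c(130, 298, 625), sd = 0),
                              seed = 70)
  dos <- rowSums(dosage_matrix(sim$genotype_table))
  m <- ped0$members
  expect_equal(m$ldl,
               c(130, 298, 625)[pmin(dos[m$subject_id], 2) + 1],
               ignore_attr = TRUE)
  # Friedewald reconstructs the drawn LDL-C from TC, HDL and TG exactly
  pedn <- simulate_phenotypes(sim, list(means = c(130, 298, 625), sd = 40),
                              seed = 71)
  m <- pedn$members
  expect_equal(as.numeric(friedewald_ldl(m$tc, m$hdl, m$tg)), m$ldl)
  expect_equal(unique(m$ldl_method), "friedewald")
  # determinism
  pedn2 <- simulate_phenotypes(sim, list(means = c(130, 298, 625), sd = 40),
                               seed = 71)
  expect_identical(pedn$members$ldl, pedn2$members$ldl)
})

test_that("homozygote phenotype draws center on their class mean", {
  draws <- vapply(1:300, function(s) {
    sim <- simulate_pedigree(sim_config(seed = 8000 + s,
                                        pedigree_spec = "kindred2_like"))
    ped <- simulate_phenotypes(sim, list(means = c(130, 298, 625), sd = 40),
                               seed = 8000 + s)
    ped$members$ldl[ped$members$subject_id == "1-1"]
  }, numeric(1))
  expect_lt(abs(mean(draws) - 625), 7)  # 3 SE at sd 40, n 300
})

test_that("simulated alleles honor the deletion geometry", {
  bp <- breakpoints("chr19", 11198406, 11201384, "hg19", "TTCG")
  seqs <- simulate_sequences(bp, seed = 80)
  expect_equal(nchar(seqs$wt) - nchar(seqs$del),
               deletion_length(bp) - nchar("TTCG"))
  # junction characterization recovers the configured insert
  read <- paste0(substr(seqs$left_flank, nchar(seqs$left_flank) - 39,
                        nchar(seqs$left_flank)),
                 "TTCG", substr(seqs$right_flank, 1, 40))
  res <- characterize_junction(seqs$left_flank, seqs$right_flank, read)
  expect_equal(res$insert_seq, "TTCG")
  # FASTA output round-trips through a standard reader
  fa <- withr::local_tempfile(fileext = ".fa")
  simulate_sequences(bp, seed = 80, fasta_path = fa)
  ss <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(ss[["wild_type"]]), seqs$wt)
  expect_equal(as.character(ss[["deleted"]]), seqs$del)
})
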