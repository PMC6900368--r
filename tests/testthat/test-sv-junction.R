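test_that("deletion length counts deleted reference bases", {
  bp <- breakpoints("chr19", 11198406, 11201384, "hg19", "TTCG")
  expect_equal(deletion_length(bp), 2977L)
  expect_equal(deletion_length(breakpoints("chr1", 100, 102)), 1L)
  # translation invariance
  for (shift in c(10L, 1234L, 999999L)) {
    expect_equal(deletion_length(breakpoints("chr1", 100 + shift,
                                             102 + shift)), 1L)
  }
  expect_error(breakpoints("chr1", 100, 101), "deletion")
})

test_that("deletion length equals explicit base counting on sequences", {
  set.seed(31)
  for (i in 1:1000) {
    left <- sample(1:1e6, 1)
    len <- sample(1:5000, 1)
    right <- left + len + 1
    bp <- breakpoints("chrT", left, right)
    # oracle: count positions strictly between the retained coordinates
    expect_equal(deletion_length(bp), length(seq(left + 1, right - 1)))
  }
})

test_that("junction characterization separates inserts from microhomology", {
  set.seed(5)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  left <- paste0(rand(60), "ACCTGA")  # distinct flank ends
  right <- paste0("GTTCAG", rand(60))
  # insert case
  read <- paste0(substr(left, 37, 66), "TTCG", substr(right, 1, 30))
  res <- characterize_junction(left, right, read)
  expect_equal(res$insert_seq, "TTCG")
  expect_equal(nchar(res$insert_seq), 4L)
  expect_equal(res$microhomology_len, 0L)
  # blunt join
  read <- paste0(substr(left, 37, 66), substr(right, 1, 30))
  res <- characterize_junction(left, right, read)
  expect_equal(res$insert_seq, "")
  expect_equal(res$microhomology_len, 0L)
  # constructed 3-base terminal overlap
  left_mh <- paste0(rand(60), "TAGCAT")
  right_mh <- paste0("CATGCTA", rand(60))  # shares terminal CAT
  read <- paste0(substr(left_mh, 37, 66), substr(right_mh, 4, 33))
  res <- characterize_junction(left_mh, right_mh, read)
  expect_equal(res$insert_seq, "")
  expect_equal(res$microhomology_len, 3L)
  # microhomology of every length is recovered exactly
  for (mh in 0:6) {
    core <- rand(mh)
    l2 <- paste0(rand(40), "ACGTTC", core)
    r2 <- paste0(core, "GGATCC", rand(40))
    read2 <- paste0(substr(l2, 17, 46 + mh), substr(r2, mh + 1, mh + 30))
    res2 <- characterize_junction(l2, r2, read2)
    expect_equal(res2$microhomology_len, mh)
  }
  expect_error(characterize_junction(left, right, rand(40)), "no anchor")
})

test_that("in-silico PCR amplifies each allele's diagnostic product only", {
  bp <- breakpoints("chr19", 11198406, 11201384, "hg19", "TTCG")
  seqs <- simulate_sequences(bp, seed = 9)
  primers <- default_primers()
  wt <- in_silico_pcr(seqs$wt, primers)
  expect_equal(wt$pair_name, "internal")
  expect_equal(wt$product_bp, 481L)
  del <- in_silico_pcr(seqs$del, primers)
  expect_equal(del$pair_name, "breakpoint")
  expect_equal(del$product_bp, 254L)
  # product size equals position arithmetic on the fixture
  expect_equal(del$end - del$start + 1L, 254L)
  # no primer sites, no products
  expect_equal(nrow(in_silico_pcr(strrep("AC", 300), primers)), 0)
  # both strands are searched: the reverse complement template amplifies too
  rc <- kindredscope:::revcomp(seqs$del)
  expect_equal(in_silico_pcr(rc, primers)$product_bp, 254L)
  amb <- data.frame(name = "bad", forward_seq = "ACGTNACGTACGTACGT",
                    reverse_seq = "ACGTACGTACGTACGT",
                    stringsAsFactors = FALSE)
  expect_error(in_silico_pcr(seqs$wt, amb), "ambiguity")
})

test_that("band patterns map to deletion genotypes with size tolerance", {
  assay <- assay_config(wt_band = 481, del_band = 254, tolerance = 10)
  expect_equal(genotype_from_bands(c(481, 254), assay), "wt/del")
  expect_equal(genotype_from_bands(481, assay), "wt/wt")
  expect_equal(genotype_from_bands(c(259, 476), assay), "wt/del")  # within tolerance
  expect_equal(genotype_from_bands(254, assay), "del/del")
  expect_equal(genotype_from_bands(integer(0), assay), "fail")
  expect_equal(genotype_from_bands(c(100, 900), assay), "fail")
  expect_error(assay_config(300, 295, 10), "resolvable")
})

test_that("assay genotyping of simulated alleles closes the loop", {
  bp <- breakpoints("chr19", 11198406, 11201384, "hg19", "TTCG")
  seqs <- simulate_sequences(bp, seed = 77)
  assay <- assay_config()
  for (g in c("wt/wt", "wt/del", "del/del")) {
    expect_equal(genotype_from_bands(bands_from_genotype(g, seqs), assay), g)
  }
})

test_that("cohort screening tallies genotypes and lists carriers", {
  assay <- assay_config()
  # family screen: five carriers among twelve typed members
  gt <- kindred1()$genotypes
  bp <- breakpoints("chr19", 11198406, 11201384, "hg19", "TTCG")
  seqs <- simulate_sequences(bp, seed = 3)
  del_dos <- dosage_matrix(gt)[, "19:11198407:LDLR"]
  patterns <- lapply(del_dos, function(d) {
    bands_from_genotype(c("wt/wt", "wt/del", "del/del")[d + 1], seqs)
  })
  screen <- screen_cohort(patterns, assay)
  expect_equal(length(screen$carriers), 5)
  expect_setequal(screen$carriers, c("1-1", "1-2", "1-3", "2-3", "3-3"))
  expect_equal(sum(screen$counts), 12)

  # population screen of all-wild-type samples finds no carrier
  wt_band <- bands_from_genotype("wt/wt", seqs)
  cohort <- setNames(rep(list(wt_band), 641), paste0("P", 1:641))
  screen <- screen_cohort(cohort, assay)
  expect_equal(length(screen$carriers), 0)
  expect_equal(unname(screen$counts["wt/wt"]), 641L)

  # mixed cohort counts equal a brute-force tally
  set.seed(12)
  gts <- sample(c("wt/wt", "wt/del", "del/del"), 100, TRUE,
                prob = c(0.7, 0.25, 0.05))
  mixed <- setNames(lapply(gts, bands_from_genotype, seqs = seqs),
                    paste0("S", 1:100))
  screen <- screen_cohort(mixed, assay)
  expect_equal(unname(screen$counts[c("wt/wt", "wt/del", "del/del")]),
               unname(c(table(factor(gts, c("wt/wt", "wt/del", "del/del"))))))
  expect_error(screen_cohort(setNames(list(481, 481), c("a", "a")), assay),
               "duplicate")
})
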