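test_that("the Friedewald relation computes and flags its validity bound", {
  expect_equal(as.numeric(friedewald_ldl(200, 50, 100)), 130)
  expect_equal(as.numeric(friedewald_ldl(150, 50, 0)), 100)
  high_tg <- friedewald_ldl(300, 40, 450)
  expect_true(is.na(high_tg))
  expect_true(attr(high_tg, "invalid"))
  expect_error(friedewald_ldl(-1, 50, 100), "non-negative")
})

test_that("affection assignment follows the LDL-C cutoffs and missing data", {
  ped <- assign_affection(kindred1()$pedigree)
  m <- ped$members
  stat <- setNames(m$affection, m$subject_id)
  expect_equal(unname(stat["1-1"]), "affected")    # 719 mg/dl, child
  expect_equal(unname(stat["1-4"]), "unaffected")  # 102 mg/dl, child
  expect_equal(unname(stat["3-4"]), "unknown")     # no lipid panel
  expect_equal(unname(stat["2-2"]), "affected")    # 192 >= adult 190
  expect_equal(unname(stat["1-6"]), "unaffected")  # 171 < adult 190
})

test_that("a homozygous frameshift explains the consanguineous kindred", {
  k2 <- kindred2()
  ped <- assign_affection(k2$pedigree)
  model <- inheritance_model("recessive_homozygous", "19:11215918:LDLR",
                             "LDLR")
  res <- evaluate_model(ped, k2$genotypes, model)
  expect_true(res$explains_all_affected)
  expect_equal(res$n_inconsistent, 0)
  expect_setequal(res$severe_class, c("1-1", "1-3"))
  # heterozygous parents are the intermediate class, never contradictions
  expect_equal(unname(res$per_individual[c("2-1", "2-2")]),
               c("consistent", "consistent"))
  # the search agrees and prefers the recessive reading for the same gene
  best <- search_explanations(ped, k2$genotypes)$best
  expect_equal(best$model$kind, "recessive_homozygous")
  expect_equal(best$model$variant_ids, "19:11215918:LDLR")
})

test_that("the compound-heterozygous pair is phased through the parents", {
  k1 <- kindred1()
  ped <- assign_affection(k1$pedigree)
  model <- inheritance_model("compound_heterozygous",
                             c("19:11198407:LDLR", "19:11227604:LDLR"),
                             "LDLR")
  res <- evaluate_model(ped, k1$genotypes, model)
  expect_true(res$explains_all_affected)
  expect_equal(res$severe_class, "1-1")
  expect_false(res$phase_ambiguous)
  expect_error(
    evaluate_model(ped, k1$genotypes,
                   inheritance_model("dominant_single", "nope:1:GENE")),
    "nope:1:GENE")
})

test_that("search results match a brute-force enumeration on a toy kindred", {
  ped <- toy_pedigree()
  gt <- toy_genotypes(list(
    LDLR_v1 = c("AG", "AA", "AG", "AG", "AA", "AA"),
    LDLR_v2 = c("AA", "AG", "AG", "AA", "AG", "AA"),
    APOB_v3 = c("AG", "AA", "AA", "AG", "AA", "AG")
  ))
  ped$members$ldl <- c(300, 300, 650, 300, 300, 120)
  ped <- assign_affection(ped)
  search <- search_explanations(ped, gt)
  best <- search$best
  expect_equal(best$model$kind, "compound_heterozygous")
  expect_setequal(best$model$variant_ids,
                  c("1:1000:LDLR", "1:2000:LDLR"))

  # independent brute-force scoring of every enumerable model
  dos <- dosage_matrix(gt)[ped$members$subject_id, ]
  aff <- ped$members$affection == "affected"
  score_single <- function(v, recessive) {
    carrier <- dos[, v] >= 1
    if (recessive) {
      inc <- (dos[, v] == 2 & !aff) | (dos[, v] == 0 & aff)
    } else {
      inc <- carrier != aff
    }
    c(all_aff = !any(inc & aff), n = sum(inc))
  }
  score_pair <- function(v1, v2) {
    both <- dos[, v1] >= 1 & dos[, v2] >= 1
    none <- dos[, v1] == 0 & dos[, v2] == 0
    inc <- (both & !aff) | (none & aff)
    c(all_aff = !any(inc & aff), n = sum(inc))
  }
  vids <- colnames(dos)
  brute <- rbind(
    t(sapply(vids, score_single, recessive = FALSE)),
    score_pair("1:1000:LDLR", "1:2000:LDLR")
  )
  # the package's best model attains the brute-force optimum
  best_brute <- max(brute[, "all_aff"] - brute[, "n"] / 100)
  expect_equal(as.numeric(best$explains_all_affected) -
                 best$n_inconsistent / 100, best_brute)
})

test_that("adding a candidate variant never worsens the best explanation", {
  ped <- toy_pedigree()
  ped$members$ldl <- c(300, 120, 650, 300, 120, 120)
  ped <- assign_affection(ped)
  g1 <- list(LDLR_v1 = c("AG", "AA", "AG", "AG", "AA", "AA"))
  g2 <- c(g1, list(LDLR_v2 = c("AA", "AG", "AG", "AA", "AA", "AA")))
  b1 <- search_explanations(ped, toy_genotypes(g1))$best
  b2 <- search_explanations(ped, toy_genotypes(g2))$best
  key <- function(b) c(b$explains_all_affected, -b$n_inconsistent)
  expect_true(key(b2)[1] > key(b1)[1] ||
                (key(b2)[1] == key(b1)[1] && key(b2)[2] >= key(b1)[2]))
})

test_that("member order does not change model evaluation", {
  k2 <- kindred2()
  ped <- assign_affection(k2$pedigree)
  model <- inheritance_model("recessive_homozygous", "19:11215918:LDLR")
  base <- evaluate_model(ped, k2$genotypes, model)
  perm <- ped
  o <- c(3, 1, 5, 2, 4)
  perm$members <- perm$members[o, ]
  res <- evaluate_model(perm, k2$genotypes, model)
  expect_equal(res$per_individual[names(base$per_individual)],
               base$per_individual)
  expect_equal(res$n_inconsistent, base$n_inconsistent)
})

test_that("an empty candidate set cannot explain an affected kindred", {
  ped <- toy_pedigree()
  ped$members$ldl <- c(300, 120, 650, 120, 120, 120)
  ped <- assign_affection(ped)
  empty <- as_genotype_table(
    data.frame(gene = character(0), chrom = character(0),
               pos = integer(0), protein_change = character(0),
               ref_allele = character(0), alt_allele = character(0)),
    matrix(character(0), nrow = 6, ncol = 0,
           dimnames = list(ped$members$subject_id, NULL)))
  search <- search_explanations(ped, empty)
  expect_null(search$best)
  expect_length(search$results, 0)
})
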