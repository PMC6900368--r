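# Fixture builders shared across the test files. Everything is generated
# in code at test time; no binary data.

example_dialect <- function() read_dialect(ks_example("dialect"))

kindred1 <- function() load_kindred(1)
kindred2 <- function() load_kindred(2)

default_filter_config <- function() {
  filter_config(read_gene_list(ks_example("gene_list")))
}

# a small synthetic annotated-variant table exercising every filter rule
synthetic_variants <- function(n = 50, seed = 42) {
  set.seed(seed)
  csq <- sample(c("missense", "synonymous", "stopgain", "intronic",
                  "utr", "frameshift", "intergenic"), n, replace = TRUE)
  genes <- sample(c("LDLR", "APOB", "LCAT", "NOTLIPID1", "NOTLIPID2"),
                  n, replace = TRUE)
  depth <- sample(c(NA, 5:80), n, replace = TRUE)
  af <- function() ifelse(runif(n) < 0.25, NA, round(runif(n, 0, 0.2), 5))
  calls <- function() sample(c("D", "T", "B", "P", "U", NA), n, replace = TRUE)
  df <- data.frame(
    chrom = sample(as.character(1:22), n, replace = TRUE),
    pos = sample.int(5e7, n),
    variant_id = NA_character_, gene = genes, exon = NA_character_,
    cdna_change = NA_character_, protein_change = NA_character_,
    consequence = csq, ref_allele = "A", alt_allele = "G",
    clinvar = NA_character_, depth = depth,
    af.gnomad = af(), af.topmed = af(), af.exac = af(),
    pred.sift = calls(), pred.polyphen2_hdiv = calls(),
    pred.mutation_taster = calls(),
    score.metasvm = round(runif(n, -1, 1), 4),
    stringsAsFactors = FALSE
  )
  df$vid <- paste0(df$chrom, ":", df$pos, ":", df$gene, ":", seq_len(n))
  attr(df, "build") <- "hg19"
  class(df) <- c("variant_table", "data.frame")
  df
}

# independent re-implementation of the cascade rules, used as an oracle
brute_force_cascade <- function(variants, config) {
  keep <- !(variants$consequence %in%
              c("synonymous", "intronic", "intergenic", "utr"))
  keep <- keep & !is.na(variants$depth) & variants$depth >= config$min_depth
  keep <- keep & variants$gene %in% config$gene_list
  survivors <- logical(nrow(variants))
  for (i in which(keep)) {
    afs <- unlist(variants[i, paste0("af.", config$databases)])
    common <- any(!is.na(afs) & afs >= config$maf_cutoff) &&
      max(afs, na.rm = TRUE) >= config$maf_cutoff
    if (!common) { survivors[i] <- TRUE; next }
    calls <- unlist(variants[i, grep("^pred\\.", names(variants))])
    calls <- calls[!is.na(calls) & calls != "U"]
    frac <- if (length(calls) == 0) NA else mean(calls %in% c("D", "H", "M"))
    survivors[i] <- is.na(frac) ||
      frac >= config$exception_min_damaging_fraction
  }
  variants$vid[survivors]
}

# minimal VCF writer for phased-genotype tests
write_test_vcf <- function(path, records, sample = "S1") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gt, ps = NA) {
  fmt <- if (is.na(ps)) "GT" else "GT:PS"
  val <- if (is.na(ps)) gt else paste0(gt, ":", ps)
  paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", fmt, val, sep = "\t")
}

# tiny two-generation pedigree with a planted recessive genotype set,
# used by the brute-force cosegregation oracle test
toy_pedigree <- function() {
  new_pedigree("TOY", data.frame(
    subject_id = c("f", "m", "c1", "c2", "c3", "c4"),
    father_id = c(NA, NA, "f", "f", "f", "f"),
    mother_id = c(NA, NA, "m", "m", "m", "m"),
    sex = c("M", "F", "F", "M", "F", "M"),
    age = c(40, 38, 10, 12, 14, 16),
    stringsAsFactors = FALSE
  ))
}

toy_genotypes <- function(geno_by_variant) {
  vs <- data.frame(
    gene = sub("_.*", "", names(geno_by_variant)),
    chrom = "1", pos = seq_along(geno_by_variant) * 1000L,
    protein_change = names(geno_by_variant),
    ref_allele = "A", alt_allele = "G", stringsAsFactors = FALSE
  )
  g <- do.call(cbind, geno_by_variant)
  rownames(g) <- c("f", "m", "c1", "c2", "c3", "c4")
  as_genotype_table(vs, g)
}
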