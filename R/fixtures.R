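#' Bundled worked-example data
#'
#' The package ships plain-text transcriptions of the two published
#' kindred tables of a homozygous familial hypercholesterolemia study --
#' the proband candidate-variant tables and the family genotype/lipid
#' tables -- together with the matching pedigrees, the candidate-gene
#' list, the screening-assay primer panel and the variant-table dialect
#' they use. Values not printed in the source tables (per-variant read
#' depth, member ages) are plausible reconstructions and are marked as
#' such in the files.
#'
#' @param name one of `"kindred1_variants"`, `"kindred2_variants"`,
#'   `"kindred1_genotypes"`, `"kindred2_genotypes"`, `"kindred1_ped"`,
#'   `"kindred2_ped"`, `"dialect"`, `"gene_list"`, `"primers"`,
#'   `"assay"`.
#' @return the path to the bundled file.
#' @export
ks_example <- function(name) {
  files <- c(
    kindred1_variants = "kindred1_variants.tsv",
    kindred2_variants = "kindred2_variants.tsv",
    kindred1_genotypes = "kindred1_genotypes.tsv",
    kindred2_genotypes = "kindred2_genotypes.tsv",
    kindred1_ped = "kindred1.ped",
    kindred2_ped = "kindred2.ped",
    dialect = "dialect.yaml",
    gene_list = "lipid_genes.txt",
    primers = "primers.tsv",
    assay = "assay.yaml"
  )
  if (!name %in% names(files)) {
    stop("unknown example name: ", name, "; choose one of ",
         paste(names(files), collapse = ", "))
  }
  path <- system.file("extdata", files[[name]], package = "kindredscope",
                      mustWork = TRUE)
  path
}

#' Load a bundled kindred as ready-to-use objects
#'
#' @param kindred `1` (compound-heterozygous kindred) or `2`
#'   (homozygous kindred).
#' @return list with `variants` (a `variant_table`), `genotypes`
#'   (a `genotype_table`), and `pedigree`.
#' @export
load_kindred <- function(kindred = 1) {
  k <- as.character(kindred)
  stopifnot(k %in% c("1", "2"))
  dialect <- read_dialect(ks_example("dialect"))
  list(
    variants = read_variant_table(ks_example(paste0("kindred", k, "_variants")),
                                  dialect),
    genotypes = read_genotype_table(ks_example(paste0("kindred", k,
                                                      "_genotypes"))),
    pedigree = read_pedigree(ks_example(paste0("kindred", k, "_ped")))
  )
}
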