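#' Read phased biallelic genotypes grouped by phase set
#'
#' Parses a VCF with `GT` calls and `PS` (phase set) annotations into
#' per-sample phased haplotype blocks, as produced by linked-read phasing
#' pipelines. Within each phase set the two haplotypes are returned as
#' ordered allele sequences over the set's sites. A call contributes to a
#' block when it is phased (`|` separator) or homozygous (phase is then
#' vacuous). Unphased heterozygous calls are excluded and counted;
#' multi-allelic records are skipped with a count; a phased call without a
#' `PS` tag forms its own singleton set keyed by its position.
#'
#' @param path a VCF file (plain text or bgzipped).
#' @return a named list, one element per sample, each a
#'   `phased_genotypes` object: list with `blocks` (named list of blocks,
#'   each holding `sites` -- data frame `chrom`, `pos`, `ref`, `alt` --
#'   and `hap1`/`hap2` allele character vectors), `n_unphased` and
#'   `n_multiallelic`.
#' @export
read_phased_genotypes <- function(path) {
  stopifnot(file.exists(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0 || ncol(v@gt) < 2) {
    samples <- if (ncol(v@gt) >= 2) colnames(v@gt)[-1] else character(0)
    empty <- lapply(samples, function(s) {
      structure(list(blocks = list(), n_unphased = 0L, n_multiallelic = 0L),
                class = "phased_genotypes")
    })
    return(setNames(empty, samples))
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi > 0) {
    warning(n_multi, " multi-allelic record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ps <- tryCatch(vcfR::extract.gt(v, element = "PS"),
                 error = function(e) NULL)
  samples <- colnames(gt)
  out <- lapply(samples, function(s) {
    blocks <- list()
    n_unphased <- 0L
    for (i in which(!multi)) {
      g <- gt[i, s]
      if (is.na(g) || g %in% c(".", "./.", ".|.")) next
      phased <- grepl("|", g, fixed = TRUE)
      alleles <- strsplit(g, "[|/]")[[1]]
      if (length(alleles) != 2 || any(!alleles %in% c("0", "1"))) next
      hom <- alleles[1] == alleles[2]
      if (!phased && !hom) {
        n_unphased <- n_unphased + 1L
        next
      }
      key <- if (!is.null(ps) && !is.na(ps[i, s])) as.character(ps[i, s])
             else paste0("ps", fix$POS[i])
      allele_seq <- c(fix$REF[i], fix$ALT[i])[as.integer(alleles) + 1L]
      site <- data.frame(chrom = fix$CHROM[i],
                         pos = as.integer(fix$POS[i]),
                         ref = fix$REF[i], alt = fix$ALT[i],
                         stringsAsFactors = FALSE)
      if (is.null(blocks[[key]])) {
        blocks[[key]] <- list(sites = site, hap1 = allele_seq[1],
                              hap2 = allele_seq[2])
      } else {
        blocks[[key]]$sites <- rbind(blocks[[key]]$sites, site)
        blocks[[key]]$hap1 <- c(blocks[[key]]$hap1, allele_seq[1])
        blocks[[key]]$hap2 <- c(blocks[[key]]$hap2, allele_seq[2])
      }
    }
    blocks <- lapply(blocks, function(b) {
      o <- order(b$sites$chrom, b$sites$pos)
      list(sites = b$sites[o, , drop = FALSE],
           hap1 = b$hap1[o], hap2 = b$hap2[o])
    })
    structure(list(blocks = blocks, n_unphased = n_unphased,
                   n_multiallelic = n_multi),
              class = "phased_genotypes")
  })
  setNames(out, samples)
}

#' @export
print.phased_genotypes <- function(x, ...) {
  cat("Phased genotypes:", length(x$blocks), "block(s),",
      x$n_unphased, "unphased het site(s) excluded,",
      x$n_multiallelic, "multi-allelic record(s) skipped\n")
  for (k in names(x$blocks)) {
    cat("  block", k, "-", nrow(x$blocks[[k]]$sites), "site(s)\n")
  }
  invisible(x)
}
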