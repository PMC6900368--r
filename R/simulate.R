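#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generators. Defaults encode
#' the study-like conditions used throughout the package's tests: a
#' six-population panel with moderate differentiation, the two built-in
#' kindred structures, lipid means by deleterious-allele count of
#' 130 / 298 / 625 mg/dl (the latter two being the canonical mean LDL-C
#' of heterozygous and homozygous familial hypercholesterolemia), and a
#' 2,977 bp deletion with a TTCG junction insert.
#'
#' @param seed integer seed; fixed seed implies identical output.
#' @param n_populations number of panel populations.
#' @param n_snps number of panel sites.
#' @param fst Balding-Nichols differentiation parameter in (0,1).
#' @param n_per_pop diploid samples per population.
#' @param pedigree_spec `"kindred1_like"` (two deleterious alleles
#'   entering from opposite branches; compound-heterozygous proband) or
#'   `"kindred2_like"` (both parents carriers; homozygous proband).
#' @param effect_model list with `means` (LDL-C mg/dl for 0/1/2
#'   deleterious alleles) and `sd` (residual noise, mg/dl).
#' @param deletion_spec a [breakpoints()] object.
#' @param primer_spec primer-pair data frame (default
#'   [default_primers()]).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_populations = 6,
                       n_snps = 100,
                       fst = 0.05,
                       n_per_pop = 100,
                       pedigree_spec = c("kindred1_like", "kindred2_like"),
                       effect_model = list(means = c(130, 298, 625), sd = 40),
                       deletion_spec = breakpoints("chr19", 11198406,
                                                   11201384, "hg19", "TTCG"),
                       primer_spec = default_primers()) {
  pedigree_spec <- match.arg(pedigree_spec)
  stopifnot(fst > 0, fst < 1, length(effect_model$means) == 3,
            effect_model$sd >= 0)
  structure(list(seed = as.integer(seed), n_populations = n_populations,
                 n_snps = n_snps, fst = fst, n_per_pop = n_per_pop,
                 pedigree_spec = pedigree_spec, effect_model = effect_model,
                 deletion_spec = deletion_spec, primer_spec = primer_spec),
            class = "sim_config")
}

#' Default screening-assay primer panel
#'
#' The two pairs of the multiplex deletion screen: a breakpoint-flanking
#' pair that amplifies only across the deletion junction, and an internal
#' pair lying inside the deleted interval that reports the wild-type
#' allele.
#' @return data frame of two primer pairs.
#' @export
default_primers <- function() {
  rbind(
    primer_pair("breakpoint", "AGCTCCTAGAACTTGCCTATCCT",
                "TCGCCACAGAGCACAGCGGAA", 254L),
    primer_pair("internal", "CAACAAATCAAGTCGCCTGCC",
                "TGCCATTACCCCACAAGTCTC", 481L)
  )
}

#' Simulate a multi-population reference panel (Balding-Nichols)
#'
#' Ancestral frequencies are uniform on (0.05, 0.95); each population's
#' frequency is Beta-distributed around the ancestral value with
#' differentiation parameter `fst`; diploid genotypes are binomial draws
#' from the population frequency. The Balding-Nichols model is the
#' simplest frequency model with a single differentiation knob -- a
#' surrogate for a genotyped diversity panel, not a model of any real
#' dataset.
#'
#' @param config a [sim_config()].
#' @return list with `panel` (a `reference_panel` whose frequencies are
#'   the generating population frequencies and whose counts are the
#'   simulated chromosome numbers), `genotypes` (dosage matrix, samples x
#'   sites) and `pop` (population label per sample).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- config$n_populations; L <- config$n_snps; n <- config$n_per_pop
  pops <- paste0("POP", seq_len(K))
  p <- runif(L, 0.05, 0.95)
  Fst <- config$fst
  freq <- vapply(pops, function(k) {
    rbeta(L, p * (1 - Fst) / Fst, (1 - p) * (1 - Fst) / Fst)
  }, numeric(L))
  if (L == 1) freq <- matrix(freq, nrow = 1, dimnames = list(NULL, pops))
  snps <- data.frame(chrom = rep("chr19", L),
                     pos = seq(11100000L, by = 997L, length.out = L),
                     ref = rep("A", L), alt = rep("G", L),
                     stringsAsFactors = FALSE)
  G <- do.call(rbind, lapply(seq_len(K), function(k) {
    t(vapply(seq_len(n), function(i) rbinom(L, 2, freq[, k]), numeric(L)))
  }))
  rownames(G) <- paste0(rep(pops, each = n), "_", seq_len(n))
  pop <- rep(pops, each = n)
  panel <- reference_panel(snps, freq,
                           counts = setNames(rep(2 * n, K), pops))
  colnames(G) <- panel$snps$id
  list(panel = panel, genotypes = G, pop = pop)
}

# Built-in pedigree structures. Subject labels follow the
# generation-index convention; founders marked by absent parents.
pedigree_structure <- function(spec) {
  if (spec == "kindred1_like") {
    # maternal branch contributes an SNV, paternal branch a deletion;
    # the proband (1-1) is ascertained compound heterozygous
    data.frame(
      subject_id = c("3-1", "3-2", "3-3", "3-4",
                     "2-1", "2-2", "2-3", "2-5",
                     "1-1", "1-2", "1-3", "1-4", "1-6"),
      father_id = c(NA, NA, NA, NA,
                    "3-2", "3-2", "3-4", NA,
                    "2-3", "2-3", "2-3", "2-5", "2-5"),
      mother_id = c(NA, NA, NA, NA,
                    "3-1", "3-1", "3-3", NA,
                    "2-2", "2-2", "2-2", "2-1", "2-1"),
      sex = c("F", "M", "F", "M", "F", "F", "M", "M",
              "F", "F", "M", "M", "F"),
      age = c(62, 65, 60, 66, 38, 36, 43, 40, 5, 10, 8, 12, 19),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      subject_id = c("2-1", "2-2", "1-1", "1-2", "1-3"),
      father_id = c(NA, NA, "2-1", "2-1", "2-1"),
      mother_id = c(NA, NA, "2-2", "2-2", "2-2"),
      sex = c("M", "F", "F", "F", "F"),
      age = c(35, 32, 2, 6, 1),
      stringsAsFactors = FALSE
    )
  }
}

# founder carrier states per locus for the built-in specs
founder_states <- function(spec, loci) {
  if (spec == "kindred1_like") {
    list("3-2" = c(snv = 1L, del = 0L),
         "3-3" = c(snv = 0L, del = 1L))
  } else {
    list("2-1" = c(fs = 1L),
         "2-2" = c(fs = 1L))
  }
}

sim_loci <- function(spec) {
  if (spec == "kindred1_like") {
    data.frame(
      locus = c("snv", "del"),
      gene = c("LDLR", "LDLR"),
      chrom = c("chr19", "chr19"),
      pos = c(11227604L, 11198407L),
      protein_change = c("p.G592E", "exon1_del"),
      ref_allele = c("G", "-"),
      alt_allele = c("A", "del"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      locus = "fs", gene = "LDLR", chrom = "chr19", pos = 11215918L,
      protein_change = "p.E113fs", ref_allele = "-", alt_allele = "G",
      stringsAsFactors = FALSE
    )
  }
}

#' Simulate a kindred with Mendelian transmission of planted alleles
#'
#' Founder carrier states are fixed by the built-in structure
#' (`"kindred1_like"`: an SNV entering through one grand-parental branch
#' and a deletion allele through the other; `"kindred2_like"`: both
#' parents heterozygous for one frameshift allele, mimicking a
#' consanguineous kindred). Offspring receive one allele per parent per
#' locus. The pedigree is ascertained through its proband, as clinical
#' kindreds are: transmissions are redrawn until subject `1-1` carries
#' the planted genotype (compound heterozygous, or homozygous,
#' respectively).
#'
#' @param config a [sim_config()].
#' @param max_tries ascertainment redraw limit (default 1000).
#' @return list with `pedigree` (no phenotypes yet), `genotype_table`
#'   (planted loci for all members), `causal` (locus descriptions) and
#'   `n_redraws`.
#' @export
simulate_pedigree <- function(config, max_tries = 1000) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  spec <- config$pedigree_spec
  struct <- pedigree_structure(spec)
  loci <- sim_loci(spec)
  founders <- founder_states(spec, loci)
  nloc <- nrow(loci)

  draw <- function() {
    # per-member, per-locus pair of allele indicators (0 ref, 1 alt)
    al <- list()
    for (id in struct$subject_id) {
      row <- struct[struct$subject_id == id, ]
      if (is.na(row$father_id)) {
        st <- founders[[id]]
        g <- vapply(loci$locus, function(l) {
          c0 <- if (!is.null(st) && l %in% names(st)) st[[l]] else 0L
          # founder carrier states are heterozygous unless stated twice
          c(as.integer(c0 >= 1), as.integer(c0 >= 2))
        }, integer(2))
      } else {
        fa <- al[[row$father_id]]; mo <- al[[row$mother_id]]
        g <- vapply(seq_len(nloc), function(j) {
          c(fa[sample(1:2, 1), j], mo[sample(1:2, 1), j])
        }, integer(2))
      }
      colnames(g) <- loci$locus
      al[[id]] <- g
    }
    al
  }

  ascertained <- function(al) {
    pro <- al[["1-1"]]
    if (spec == "kindred1_like") {
      sum(pro[, "snv"]) >= 1 && sum(pro[, "del"]) >= 1
    } else {
      sum(pro[, "fs"]) == 2
    }
  }

  n_redraws <- 0L
  repeat {
    al <- draw()
    if (ascertained(al)) break
    n_redraws <- n_redraws + 1L
    if (n_redraws >= max_tries) {
      stop("ascertainment condition not met in ", max_tries, " redraws")
    }
  }

  geno <- t(vapply(struct$subject_id, function(id) {
    vapply(seq_len(nloc), function(j) {
      d <- sum(al[[id]][, j])
      ref <- loci$ref_allele[j]; alt <- loci$alt_allele[j]
      sep <- if (grepl("^[ACGT]$", ref) && grepl("^[ACGT]$", alt)) "" else "/"
      paste(c(rep(ref, 2 - d), rep(alt, d)), collapse = sep)
    }, character(1))
  }, character(nloc)))
  if (nloc == 1) geno <- matrix(geno, ncol = 1,
                                dimnames = list(struct$subject_id, NULL))
  ped <- new_pedigree(spec, struct)
  gt <- as_genotype_table(loci[, -1], geno)
  list(pedigree = ped, genotype_table = gt, causal = loci,
       n_redraws = n_redraws)
}

#' Simulate lipid panels from planted genotypes
#'
#' Each member's deleterious-allele count (total alternate dosage over
#' the causal loci, capped at 2) selects an LDL-C mean; LDL-C is drawn
#' normally around it (truncated at 0). HDL-C and triglycerides are drawn
#' from unremarkable ranges and total cholesterol is set so that the
#' Friedewald relation reproduces the drawn LDL-C exactly.
#'
#' @param pedsim output of [simulate_pedigree()].
#' @param effect_model list with `means` (length 3) and `sd`.
#' @param seed integer seed.
#' @return the pedigree with lipid columns filled
#'   (`ldl_method = "friedewald"`).
#' @export
simulate_phenotypes <- function(pedsim,
                                effect_model = list(means = c(130, 298, 625),
                                                    sd = 40),
                                seed = 1L) {
  set.seed(seed + 2L)
  ped <- pedsim$pedigree
  dos <- dosage_matrix(pedsim$genotype_table)
  count <- pmin(rowSums(dos), 2)
  m <- ped$members
  idx <- match(m$subject_id, names(count))
  mu <- effect_model$means[count[idx] + 1]
  ldl <- pmax(0, round(rnorm(length(mu), mu, effect_model$sd)))
  hdl <- pmax(5, round(rnorm(length(mu), 50, 10)))
  tg <- pmin(395, pmax(40, round(rnorm(length(mu), 120, 30) / 5) * 5))
  m$ldl <- ldl; m$hdl <- hdl; m$tg <- tg
  m$tc <- ldl + hdl + tg / 5
  m$ldl_method <- "friedewald"
  ped$members <- m
  ped
}

#' Simulate wild-type and deleted alleles with embedded primer sites
#'
#' Builds a wild-type allele containing the internal primer pair inside
#' the deleted interval and the breakpoint-flanking pair outside it, and
#' the corresponding deleted allele (flanks joined around the junction
#' insert). Primer placement reproduces the assay's diagnostic product
#' sizes: the internal pair amplifies only from the wild-type allele and
#' the flanking pair yields a short breakpoint-spanning product only from
#' the deleted allele (on the wild-type allele the flanking product spans
#' the whole deletion and exceeds any practical amplicon size).
#'
#' @param deletion_spec a [breakpoints()] object (sets the deleted
#'   length and junction insert).
#' @param primer_spec primer panel with rows named `breakpoint` and
#'   `internal` and their `expected_product_bp`.
#' @param seed integer seed for the random sequence background.
#' @param flank_len retained sequence length on each side (default 400).
#' @param fasta_path optional path; when given, both alleles are written
#'   as FASTA.
#' @return list with `wt` and `del` allele sequences (character),
#'   `truth` (deletion length, insert, expected band sizes per allele)
#'   and the flank sequences used.
#' @export
simulate_sequences <- function(deletion_spec, primer_spec = default_primers(),
                               seed = 1L, flank_len = 400,
                               fasta_path = NULL) {
  stopifnot(inherits(deletion_spec, "breakpoints"))
  set.seed(seed + 3L)
  del_len <- deletion_length(deletion_spec)
  insert <- deletion_spec$insert_seq
  bp_pair <- primer_spec[primer_spec$name == "breakpoint", ]
  in_pair <- primer_spec[primer_spec$name == "internal", ]
  stopifnot(nrow(bp_pair) == 1, nrow(in_pair) == 1)
  bp_size <- bp_pair$expected_product_bp
  in_size <- in_pair$expected_product_bp
  fwd <- bp_pair$forward_seq; rev_rc <- revcomp(bp_pair$reverse_seq)
  ifwd <- in_pair$forward_seq; irev_rc <- revcomp(in_pair$reverse_seq)

  # geometry: on the deleted allele the breakpoint product runs from the
  # forward primer start (a bases before the junction) across the insert
  # to the reverse primer end (b bases after it): a + |insert| + b = size
  a <- ceiling((bp_size - nchar(insert)) / 2)
  b <- bp_size - nchar(insert) - a
  if (a > flank_len || b > flank_len) stop("flank_len too short for primers")
  if (in_size + 20 > del_len) stop("deleted interval too short for the internal product")
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  embed <- function(seq, sub, start) {
    stopifnot(start >= 1, start + nchar(sub) - 1 <= nchar(seq))
    paste0(substr(seq, 1, start - 1), sub,
           substr(seq, start + nchar(sub), nchar(seq)))
  }
  left <- embed(rand(flank_len), fwd, flank_len - a + 1)
  right <- embed(rand(flank_len), rev_rc, b - nchar(rev_rc) + 1)
  mid <- rand(del_len)
  in_start <- 10
  mid <- embed(mid, ifwd, in_start)
  mid <- embed(mid, irev_rc, in_start + in_size - nchar(irev_rc))
  wt <- paste0(left, mid, right)
  del <- paste0(left, insert, right)
  out <- list(
    wt = wt, del = del, left_flank = left, right_flank = right,
    truth = list(deletion_length = del_len, insert_seq = insert,
                 wt_bands = in_size, del_bands = bp_size)
  )
  if (!is.null(fasta_path)) {
    ss <- Biostrings::DNAStringSet(c(wild_type = wt, deleted = del))
    Biostrings::writeXStringSet(ss, fasta_path)
  }
  out
}

#' Band patterns implied by a structural-variant genotype
#'
#' Runs the in-silico screen on each allele of a diploid genotype and
#' pools the product sizes, as a multiplex gel lane would.
#'
#' @param sv_genotype `"wt/wt"`, `"wt/del"` or `"del/del"`.
#' @param seqs output of [simulate_sequences()].
#' @param primer_spec primer panel.
#' @param max_product_bp passed to [in_silico_pcr()].
#' @return integer vector of product sizes.
#' @export
bands_from_genotype <- function(sv_genotype, seqs,
                                primer_spec = default_primers(),
                                max_product_bp = 1000) {
  alleles <- switch(sv_genotype,
                    "wt/wt" = c("wt", "wt"),
                    "wt/del" = c("wt", "del"),
                    "del/del" = c("del", "del"),
                    stop("unknown SV genotype: ", sv_genotype))
  sizes <- unlist(lapply(unique(alleles), function(a) {
    in_silico_pcr(seqs[[a]], primer_spec, max_product_bp)$product_bp
  }))
  sort(unique(as.integer(sizes)))
}
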