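#' Build a run configuration
#'
#' @param seed integer seed applied to every stochastic component.
#' @param output_dir directory for per-stage artifacts and the combined
#'   report (created if needed).
#' @param stages named logical vector enabling `prioritize`, `segregate`,
#'   `svscreen`, `ancestry`.
#' @param inputs either `"synthetic"` (every input is generated by the
#'   synthetic module under `seed`) or a named list of file paths:
#'   `variants`, `dialect`, `gene_list`, `genotypes`, `pedigree`
#'   (and optionally `primers`, `assay`).
#' @param prioritize_config a [filter_config()] or `NULL` (built from
#'   `gene_list` at run time).
#' @param affection a [affection_rule()].
#' @param sim a [sim_config()] used when `inputs == "synthetic"`.
#' @return a `run_config`.
#' @export
run_config <- function(seed = 1L,
                       output_dir = tempfile("ksrun"),
                       stages = c(prioritize = TRUE, segregate = TRUE,
                                  svscreen = TRUE, ancestry = TRUE),
                       inputs = "synthetic",
                       prioritize_config = NULL,
                       affection = affection_rule(),
                       sim = NULL) {
  default_stages <- c(prioritize = TRUE, segregate = TRUE,
                      svscreen = TRUE, ancestry = TRUE)
  default_stages[names(stages)] <- stages
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(list(seed = as.integer(seed), output_dir = output_dir,
                 stages = default_stages, inputs = inputs,
                 prioritize_config = prioritize_config,
                 affection = affection, sim = sim),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys: `seed`, `output_dir`, `stages` (map of stage ->
#' true/false), `inputs` (`synthetic` or a map of paths), and `sim`
#' (`n_populations`, `n_snps`, `fst`, `n_per_pop`, `pedigree_spec`).
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- as.integer(y$seed %||% 1L)
  sim_args <- y$sim %||% list()
  sim_args$seed <- seed
  stages <- unlist(y$stages %||% list())
  if (is.null(stages)) stages <- logical(0)
  run_config(seed = seed,
             output_dir = y$output_dir %||% tempfile("ksrun"),
             stages = stages,
             inputs = y$inputs %||% "synthetic",
             sim = do.call(sim_config, sim_args))
}

validate_inputs <- function(config) {
  if (identical(config$inputs, "synthetic")) return(invisible())
  needed <- character(0)
  if (config$stages[["prioritize"]]) {
    needed <- c(needed, "variants", "dialect", "gene_list")
  }
  if (config$stages[["segregate"]]) needed <- c(needed, "genotypes", "pedigree")
  missing_keys <- setdiff(needed, names(config$inputs))
  if (length(missing_keys) > 0) {
    stop("run config lacks input path(s): ",
         paste(missing_keys, collapse = ", "))
  }
  for (k in needed) {
    if (!file.exists(config$inputs[[k]])) {
      stop("input file for '", k, "' does not exist: ", config$inputs[[k]])
    }
  }
  invisible()
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in study order -- variant prioritization,
#' cosegregation search, structural-variant screen, block-origin ancestry
#' -- on real inputs or on a fully synthetic kindred, writing per-stage
#' artifacts and a combined JSON report. The report contains no
#' timestamps, so a rerun under the same configuration and seed is
#' byte-identical.
#'
#' @param config a [run_config()] or the path to a YAML run config.
#' @return the report, invisibly (a list; also written as
#'   `report.json` under `output_dir`).
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  validate_inputs(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed,
                 stages = as.list(config$stages),
                 synthetic = identical(config$inputs, "synthetic"))
  synthetic <- identical(config$inputs, "synthetic")

  # -- materialize inputs ---------------------------------------------
  if (synthetic) {
    sim <- config$sim
    pedsim <- simulate_pedigree(sim)
    ped <- simulate_phenotypes(pedsim, sim$effect_model, seed = sim$seed)
    gt <- pedsim$genotype_table
    variants <- synthetic_variant_table(pedsim, sim)
    pcfg <- config$prioritize_config %||%
      filter_config(gene_list = unique(c(pedsim$causal$gene, "APOB")))
    report$planted <- list(
      model = if (sim$pedigree_spec == "kindred1_like")
        "compound_heterozygous" else "recessive_homozygous",
      variant_ids = pedsim$genotype_table$variants$vid
    )
  } else {
    if (config$stages[["prioritize"]]) {
      dialect <- read_dialect(config$inputs$dialect)
      variants <- read_variant_table(config$inputs$variants, dialect)
      pcfg <- config$prioritize_config %||%
        filter_config(read_gene_list(config$inputs$gene_list))
    }
    if (config$stages[["segregate"]]) {
      gt <- read_genotype_table(config$inputs$genotypes)
      ped <- read_pedigree(config$inputs$pedigree)
    }
  }

  # -- prioritize ------------------------------------------------------
  if (config$stages[["prioritize"]]) {
    cascade <- run_cascade(variants, pcfg)
    utils::write.table(as.data.frame(cascade$candidates),
                       file.path(config$output_dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      lapply(cascade$trace, function(s) s[c("stage", "n_in", "n_out")]),
      file.path(config$output_dir, "trace.json"), auto_unbox = TRUE)
    report$prioritize <- list(
      n_input = nrow(variants),
      n_candidates = nrow(cascade$candidates),
      exceptions = cascade$trace$maf$exception_flags,
      top_ranked = utils::head(cascade$ranking$vid, 3))
  }

  # -- segregate -------------------------------------------------------
  if (config$stages[["segregate"]]) {
    ped <- assign_affection(ped, config$affection)
    search <- search_explanations(ped, gt)
    best <- search$best
    report$segregate <- if (is.null(best)) list(best_model = NULL) else list(
      best_model = list(kind = best$model$kind, gene = best$model$gene,
                        variant_ids = sort(best$model$variant_ids)),
      explains_all_affected = best$explains_all_affected,
      n_inconsistent = best$n_inconsistent,
      unexplained_affected = best$unexplained_affected,
      severe_class = sort(best$severe_class))
    jsonlite::write_json(report$segregate,
                         file.path(config$output_dir, "segregation.json"),
                         auto_unbox = TRUE, null = "null")
  }

  # -- svscreen --------------------------------------------------------
  if (config$stages[["svscreen"]]) {
    sim <- config$sim
    seqs <- simulate_sequences(sim$deletion_spec, sim$primer_spec,
                               seed = sim$seed)
    assay <- assay_config(
      wt_band = sim$primer_spec$expected_product_bp[
        sim$primer_spec$name == "internal"],
      del_band = sim$primer_spec$expected_product_bp[
        sim$primer_spec$name == "breakpoint"])
    if (config$stages[["segregate"]] && synthetic) {
      # band patterns of the simulated family, driven by the deletion locus
      del_vid <- gt$variants$vid[gt$variants$alt_allele == "del"]
      patterns <- if (length(del_vid) == 1) {
        dos <- dosage_matrix(gt)[, del_vid]
        setNames(lapply(dos, function(d) {
          bands_from_genotype(c("wt/wt", "wt/del", "del/del")[d + 1], seqs,
                              sim$primer_spec)
        }), names(dos))
      } else {
        setNames(lapply(rownames(gt$geno), function(i)
          bands_from_genotype("wt/wt", seqs, sim$primer_spec)),
          rownames(gt$geno))
      }
      screen <- screen_cohort(patterns, assay)
      report$svscreen <- list(
        junction = characterize_junction(seqs$left_flank, seqs$right_flank,
          junction_read(seqs)),
        deletion_length = deletion_length(sim$deletion_spec),
        counts = as.list(screen$counts),
        carriers = sort(screen$carriers))
      utils::write.table(
        data.frame(sample = names(screen$genotypes),
                   genotype = unname(screen$genotypes)),
        file.path(config$output_dir, "sv_genotypes.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      report$svscreen <- list(
        junction = characterize_junction(seqs$left_flank, seqs$right_flank,
          junction_read(seqs)),
        deletion_length = deletion_length(sim$deletion_spec))
    }
  }

  # -- ancestry --------------------------------------------------------
  if (config$stages[["ancestry"]]) {
    sim <- config$sim
    panelsim <- simulate_panel(sim)
    set.seed(sim$seed + 4L)
    source_pop <- sample(panelsim$panel$populations, 1)
    q <- panelsim$panel$freq[, source_pop]
    haps <- rbind(rbinom(length(q), 1, q), rbinom(length(q), 1, q))
    colnames(haps) <- panelsim$panel$snps$id
    post <- block_origin(haps, panelsim$panel)
    ranked <- rank_populations(post)
    report$ancestry <- list(
      source_population = source_pop,
      top_population = ranked$population[1],
      top_prob = ranked$prob[1],
      n_sites = post$n_sites)
    jsonlite::write_json(
      list(population = ranked$population, prob = ranked$prob),
      file.path(config$output_dir, "ancestry_posterior.json"),
      auto_unbox = TRUE, digits = NA)
  }

  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(report)
}

# read spanning the junction of the simulated deleted allele
junction_read <- function(seqs, half = 60) {
  join <- nchar(seqs$left_flank)
  del <- seqs$del
  substr(del, max(1, join - half + 1),
         min(nchar(del), join + nchar(seqs$truth$insert_seq) + half))
}

# synthetic annotated-variant table: the planted causal variants plus
# benign/common decoys, in the internal variant_table layout
synthetic_variant_table <- function(pedsim, sim) {
  set.seed(sim$seed + 5L)
  loci <- pedsim$causal
  n_decoy <- 20
  preds <- c("sift", "polyphen2_hdiv", "mutation_taster")
  mk <- function(chrom, pos, gene, consequence, af, calls, depth) {
    row <- data.frame(chrom = chrom, pos = pos,
                      variant_id = NA_character_, gene = gene,
                      exon = NA_character_, cdna_change = NA_character_,
                      protein_change = NA_character_,
                      consequence = consequence,
                      ref_allele = "A", alt_allele = "G",
                      clinvar = NA_character_, depth = depth,
                      stringsAsFactors = FALSE)
    row[paste0("af.", c("gnomad", "topmed", "exac"))] <-
      rep(af, 3) * c(1, 0.9, 1.1)
    row[paste0("pred.", preds)] <- calls
    row[["score.metasvm"]] <- NA_real_
    row
  }
  causal <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
    mk(loci$chrom[i], loci$pos[i], loci$gene[i],
       if (loci$alt_allele[i] == "del") "frameshift" else "missense",
       NA_real_, list("D", "D", "D"), 60)
  }))
  causal$ref_allele <- loci$ref_allele
  causal$alt_allele <- loci$alt_allele
  causal$protein_change <- loci$protein_change
  decoys <- do.call(rbind, lapply(seq_len(n_decoy), function(i) {
    kind <- sample(c("benign_common", "synonymous", "lowdepth", "offgene"),
                   1)
    mk(chrom = "chr2", pos = 1000000L + i * 1000L,
       gene = if (kind == "offgene") paste0("GENE", i) else "APOB",
       consequence = if (kind == "synonymous") "synonymous" else "missense",
       af = if (kind == "benign_common") runif(1, 0.05, 0.4)
            else runif(1, 0, 0.005),
       calls = if (kind == "benign_common") list("T", "B", "N")
               else list(sample(c("D", "T"), 1), "B", "N"),
       depth = if (kind == "lowdepth") sample(1:19, 1) else 50)
  }))
  out <- rbind(causal, decoys)
  out$vid <- variant_key(out)
  attr(out, "build") <- "hg19"
  class(out) <- c("variant_table", "data.frame")
  out
}
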