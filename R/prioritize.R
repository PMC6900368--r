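#' Configuration for the variant-prioritization cascade
#'
#' The cascade reproduces a standard rare-variant triage for a Mendelian
#' lipid disorder: drop non-coding and synonymous calls, drop poorly
#' supported calls, intersect with a curated candidate-gene list, then
#' drop common variants unless the predictor consensus says they are
#' potentially damaging.
#'
#' @param gene_list character vector of candidate gene symbols (non-empty).
#' @param min_depth minimum supporting read depth retained (boundary
#'   inclusive; default 20).
#' @param maf_cutoff allele-frequency threshold above which a variant is
#'   "common" (default 0.01, i.e. 1 percent).
#' @param exception_min_damaging_fraction minimum fraction of damaging
#'   predictor calls for a common variant to be kept as a damaging
#'   exception (default 0.5).
#' @param databases allele-frequency sources consulted, matching the
#'   `af.<db>` columns of the variant table.
#' @return a `filter_config` list.
#' @export
filter_config <- function(gene_list,
                          min_depth = 20,
                          maf_cutoff = 0.01,
                          exception_min_damaging_fraction = 0.5,
                          databases = c("gnomad", "topmed", "exac")) {
  gene_list <- unique(as.character(gene_list))
  if (length(gene_list) == 0) stop("gene_list must be non-empty")
  if (!(maf_cutoff > 0 && maf_cutoff < 1)) stop("maf_cutoff must be in (0,1)")
  if (min_depth < 0) stop("min_depth must be >= 0")
  stopifnot(exception_min_damaging_fraction >= 0,
            exception_min_damaging_fraction <= 1)
  structure(list(gene_list = gene_list, min_depth = min_depth,
                 maf_cutoff = maf_cutoff,
                 exception_min_damaging_fraction = exception_min_damaging_fraction,
                 databases = databases),
            class = "filter_config")
}

#' Read a candidate-gene list (one symbol per line, `#` comments allowed)
#' @param path text file of gene symbols.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, encoding = "UTF-8")
  x <- trimws(sub("#.*", "", x))
  unique(x[nzchar(x)])
}

#' Multi-predictor consensus scores
#'
#' Summarizes the categorical pathogenicity calls of each variant.
#' Calls `D` (damaging/deleterious), `H` and `M` (high/medium impact)
#' count as damaging; `T`, `B`, `P`, `N`, `L` count as not damaging
#' (`P`, possibly damaging, is deliberately counted non-damaging to keep
#' the consensus strict); `U` (unknown) and missing cells are non-calls
#' and enter neither numerator nor denominator. A variant with no
#' scoreable predictor at all (e.g. an in-frame indel, which SNV
#' predictors cannot score) has `fraction_damaging = NA` and is treated as
#' potentially damaging by the exception rule -- absence of evidence is
#' not evidence of benignity.
#'
#' @param variants a `variant_table`.
#' @param meta_score name of the numeric meta-score used for rank
#'   tie-breaking (default `"metasvm"`, matching `score.metasvm`).
#' @return data frame `vid`, `n_predictors_called`, `n_damaging`,
#'   `fraction_damaging`, `meta_score`, `rank` -- ranked by
#'   `fraction_damaging` (descending, `NA` last), then meta-score
#'   (descending), then genomic position.
#' @export
consensus_scores <- function(variants, meta_score = "metasvm") {
  pred_cols <- grep("^pred\\.", names(variants), value = TRUE)
  calls <- as.matrix(as.data.frame(variants, check.names = FALSE)[pred_cols])
  known <- c(PREDICTOR_CALLS_DAMAGING, PREDICTOR_CALLS_BENIGN,
             PREDICTOR_CALLS_NOCALL)
  bad <- setdiff(stats::na.omit(unique(as.vector(calls))), known)
  if (length(bad) > 0) {
    stop("unknown predictor call(s): ", paste(bad, collapse = ", "))
  }
  scoreable <- !is.na(calls) & !(calls %in% PREDICTOR_CALLS_NOCALL)
  n_called <- rowSums(scoreable)
  n_damaging <- rowSums(scoreable & matrix(calls %in% PREDICTOR_CALLS_DAMAGING,
                                           nrow(calls)))
  frac <- ifelse(n_called > 0, n_damaging / n_called, NA_real_)
  ms_col <- paste0("score.", meta_score)
  ms <- if (ms_col %in% names(variants)) variants[[ms_col]] else
    rep(NA_real_, nrow(variants))
  out <- data.frame(vid = variants$vid,
                    n_predictors_called = as.integer(n_called),
                    n_damaging = as.integer(n_damaging),
                    fraction_damaging = frac,
                    meta_score = ms,
                    stringsAsFactors = FALSE)
  ord <- order(-ifelse(is.na(frac), -Inf, frac),
               -ifelse(is.na(ms), -Inf, ms),
               variants$chrom, variants$pos)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Remove synonymous, intronic, intergenic and UTR variants
#' @param variants a `variant_table`.
#' @return the retained subset (same class).
#' @export
filter_consequence <- function(variants) {
  bad <- setdiff(stats::na.omit(unique(variants$consequence)),
                 CONSEQUENCE_LEVELS)
  if (length(bad) > 0) {
    stop("unknown consequence label(s): ", paste(bad, collapse = ", "))
  }
  keep <- !(variants$consequence %in% NONCODING_CONSEQUENCES)
  variants[keep, , drop = FALSE]
}

#' Remove variants with low read-depth support
#'
#' Retains variants with `depth >= min_depth` (boundary inclusive).
#' Variants with missing depth are removed and reported separately via
#' `attr(, "n_missing_depth")`.
#'
#' @param variants a `variant_table`.
#' @param min_depth minimum retained depth.
#' @return the retained subset.
#' @export
filter_depth <- function(variants, min_depth = 20) {
  if (any(!is.na(variants$depth) & variants$depth < 0)) {
    stop("negative depth")
  }
  keep <- !is.na(variants$depth) & variants$depth >= min_depth
  out <- variants[keep, , drop = FALSE]
  attr(out, "n_missing_depth") <- sum(is.na(variants$depth))
  out
}

#' Intersect variants with the candidate-gene list
#' @param variants a `variant_table`.
#' @param gene_list character vector of gene symbols.
#' @return the retained subset.
#' @export
filter_genes <- function(variants, gene_list) {
  variants[variants$gene %in% gene_list, , drop = FALSE]
}

#' Classify variants under the allele-frequency rule
#'
#' A variant is aggregated across the configured databases by its maximum
#' observed frequency (the most conservative choice when deciding
#' "common"). Status is `"keep"` when the maximum is below the cutoff or
#' every frequency is missing (a novel variant cannot be called common);
#' `"exception"` when the maximum reaches the cutoff but the predictor
#' consensus is potentially damaging (`fraction_damaging >=` the
#' configured threshold, or no predictor scoreable at all); otherwise
#' `"discard"`.
#'
#' @param variants a `variant_table`.
#' @param config a `filter_config`.
#' @param consensus output of [consensus_scores()] covering `variants`
#'   (computed on the fly when `NULL`).
#' @return character vector of statuses, one per row of `variants`.
#' @export
maf_status <- function(variants, config, consensus = NULL) {
  stopifnot(inherits(config, "filter_config"))
  if (is.null(consensus)) consensus <- consensus_scores(variants)
  af_cols <- paste0("af.", config$databases)
  af_cols <- af_cols[af_cols %in% names(variants)]
  af <- as.matrix(as.data.frame(variants, check.names = FALSE)[af_cols])
  if (any(!is.na(af) & (af < 0 | af > 1))) {
    stop("allele frequency outside [0,1]")
  }
  max_af <- apply(af, 1, function(r) if (all(is.na(r))) NA_real_ else
    max(r, na.rm = TRUE))
  frac <- consensus$fraction_damaging[match(variants$vid, consensus$vid)]
  damaging <- is.na(frac) | frac >= config$exception_min_damaging_fraction
  ifelse(is.na(max_af) | max_af < config$maf_cutoff, "keep",
         ifelse(damaging, "exception", "discard"))
}

#' Run the full prioritization cascade
#'
#' Applies, in order: consequence exclusion, read-depth filter,
#' candidate-gene intersection, and the allele-frequency rule with its
#' damaging exception. Survivors are ranked by the predictor consensus
#' (fraction damaging, then meta-score, then coordinate). Every input
#' variant is accounted for in the returned trace.
#'
#' @param variants a `variant_table`.
#' @param config a `filter_config`.
#' @return a `cascade_result`: list with `candidates` (surviving
#'   `variant_table`), `trace` (per-stage `n_in`, `n_out`, `removed` ids,
#'   plus `exception_flags`), and `ranking` (consensus scores of the
#'   survivors, best first).
#' @export
run_cascade <- function(variants, config) {
  stopifnot(inherits(config, "filter_config"))
  trace <- list()
  note <- function(stage, before, after, extra = NULL) {
    trace[[stage]] <<- c(list(stage = stage,
                              n_in = nrow(before), n_out = nrow(after),
                              removed = setdiff(before$vid, after$vid)),
                         extra)
  }
  s0 <- variants
  s1 <- filter_consequence(s0);            note("consequence", s0, s1)
  s2 <- filter_depth(s1, config$min_depth)
  note("depth", s1, s2,
       list(n_missing_depth = attr(s2, "n_missing_depth")))
  s3 <- filter_genes(s2, config$gene_list); note("gene_list", s2, s3)
  status <- maf_status(s3, config)
  s4 <- s3[status != "discard", , drop = FALSE]
  note("maf", s3, s4,
       list(exception_flags = s3$vid[status == "exception"]))
  ranking <- if (nrow(s4) > 0) consensus_scores(s4) else
    consensus_scores(s4)[0, ]
  structure(list(candidates = s4, trace = trace, ranking = ranking,
                 config = config),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("Prioritization cascade:\n")
  for (st in x$trace) {
    cat(sprintf("  %-12s %4d -> %4d\n", st$stage, st$n_in, st$n_out))
  }
  ex <- x$trace$maf$exception_flags
  if (length(ex) > 0) {
    cat("  damaging exceptions kept above the AF cutoff:",
        paste(ex, collapse = ", "), "\n")
  }
  cat("Top candidates:\n")
  print(utils::head(x$ranking, 10), row.names = FALSE)
  invisible(x)
}
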