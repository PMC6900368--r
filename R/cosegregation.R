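#' Friedewald estimate of LDL cholesterol
#'
#' LDL-C = TC - HDL-C - TG/5, all in mg/dl. The estimate is invalid at
#' triglyceride levels of 400 mg/dl or above; those entries return `NA`
#' and are flagged in the `"invalid"` attribute.
#'
#' @param tc,hdl,tg total cholesterol, HDL cholesterol and triglycerides
#'   in mg/dl (vectors recycled to a common length; all values must be
#'   non-negative).
#' @return numeric vector of LDL-C estimates in mg/dl, `NA` where the
#'   formula does not apply; `attr(, "invalid")` marks those entries.
#' @export
friedewald_ldl <- function(tc, hdl, tg) {
  n <- max(length(tc), length(hdl), length(tg))
  tc <- rep_len(tc, n); hdl <- rep_len(hdl, n); tg <- rep_len(tg, n)
  if (any(stats::na.omit(c(tc, hdl, tg)) < 0)) {
    stop("lipid inputs must be non-negative (mg/dl)")
  }
  invalid <- !is.na(tg) & tg >= 400
  ldl <- tc - hdl - tg / 5
  ldl[invalid] <- NA_real_
  structure(ldl, invalid = invalid)
}

#' Affection rule for hypercholesterolemia status
#'
#' Clinically, affection is LDL-C above the age- and sex-adjusted 95th
#' percentile. Population percentile tables are not bundled; the default
#' rule is a fixed pair of cutoffs -- 190 mg/dl for adults and 160 mg/dl
#' for children -- which reproduces the usual screening thresholds. A
#' full `(age, sex) -> cutoff` table can be supplied instead via
#' `threshold_fn`.
#'
#' @param adult_cutoff,child_cutoff LDL-C cutoffs in mg/dl.
#' @param adult_age age (years) at which the adult cutoff applies.
#' @param threshold_fn optional `function(age, sex) -> cutoff` overriding
#'   the fixed cutoffs.
#' @return an `affection_rule`.
#' @export
affection_rule <- function(adult_cutoff = 190, child_cutoff = 160,
                           adult_age = 18, threshold_fn = NULL) {
  stopifnot(adult_cutoff > 0, child_cutoff > 0)
  structure(list(adult_cutoff = adult_cutoff, child_cutoff = child_cutoff,
                 adult_age = adult_age, threshold_fn = threshold_fn),
            class = "affection_rule")
}

applicable_cutoff <- function(rule, age, sex) {
  if (!is.null(rule$threshold_fn)) return(rule$threshold_fn(age, sex))
  # unknown age defaults to the (stricter) adult cutoff
  ifelse(!is.na(age) & age < rule$adult_age,
         rule$child_cutoff, rule$adult_cutoff)
}

#' Assign affection status from lipid panels
#'
#' A member is `affected` when LDL-C is at or above the applicable
#' cutoff, `unaffected` below it, and `unknown` when no LDL-C is
#' available (missing data never silently becomes unaffected).
#'
#' @param ped a `pedigree`.
#' @param rule an [affection_rule()].
#' @return the pedigree with the `affection` column filled.
#' @export
assign_affection <- function(ped, rule = affection_rule()) {
  stopifnot(inherits(ped, "pedigree"), inherits(rule, "affection_rule"))
  m <- ped$members
  cutoff <- applicable_cutoff(rule, m$age, m$sex)
  m$affection <- ifelse(is.na(m$ldl), "unknown",
                 ifelse(m$ldl >= cutoff, "affected", "unaffected"))
  ped$members <- m
  ped
}

#' Specify an inheritance model over candidate variants
#'
#' @param kind `"dominant_single"`, `"recessive_homozygous"` or
#'   `"compound_heterozygous"`.
#' @param variant_ids one variant key for the single-variant models, an
#'   unordered pair of distinct keys for the compound model.
#' @param gene gene symbol the model concerns (required for compound
#'   models, where both variants must lie in the same gene).
#' @return an `inheritance_model`.
#' @export
inheritance_model <- function(kind, variant_ids, gene = NA_character_) {
  kind <- match.arg(kind, c("dominant_single", "recessive_homozygous",
                            "compound_heterozygous"))
  variant_ids <- unique(as.character(variant_ids))
  if (kind == "compound_heterozygous") {
    if (length(variant_ids) != 2) {
      stop("a compound-heterozygous model needs two distinct variants")
    }
  } else if (length(variant_ids) != 1) {
    stop("model '", kind, "' takes exactly one variant")
  }
  structure(list(kind = kind, variant_ids = variant_ids, gene = gene),
            class = "inheritance_model")
}

# Phase a two-variant pair in a child from parental genotypes.
# Returns "trans", "cis_or_ambiguous", or "unknown" (parents untyped).
phase_pair <- function(ped, dos, subject, v1, v2) {
  m <- ped$members
  row <- m[m$subject_id == subject, ]
  pat <- row$father_id; mat <- row$mother_id
  get <- function(id, v) {
    if (is.na(id) || !(id %in% rownames(dos))) return(NA_integer_)
    dos[id, v]
  }
  f1 <- get(pat, v1); f2 <- get(pat, v2)
  m1 <- get(mat, v1); m2 <- get(mat, v2)
  if (all(is.na(c(f1, f2, m1, m2)))) return("unknown")
  # one variant demonstrably from each parent => trans
  from_father_v1 <- !is.na(f1) && f1 > 0 && !is.na(m1) && m1 == 0
  from_mother_v1 <- !is.na(m1) && m1 > 0 && !is.na(f1) && f1 == 0
  from_father_v2 <- !is.na(f2) && f2 > 0 && !is.na(m2) && m2 == 0
  from_mother_v2 <- !is.na(m2) && m2 > 0 && !is.na(f2) && f2 == 0
  if ((from_father_v1 && from_mother_v2) ||
      (from_mother_v1 && from_father_v2)) {
    return("trans")
  }
  "cis_or_ambiguous"
}

#' Evaluate one inheritance model against a pedigree
#'
#' Scores every pedigree member with known affection against the
#' genotype expectations of the model:
#'
#' * dominant: carriers (dosage >= 1) should be affected and
#'   non-carriers unaffected;
#' * recessive: homozygous-alternate members should be affected, and no
#'   affected member may carry zero alternate alleles; heterozygous
#'   carriers are an intermediate phenotype class whose status never
#'   contradicts the model (heterozygotes of a severe lipid disorder are
#'   themselves frequently hypercholesterolemic);
#' * compound heterozygous: members carrying both pair variants in trans
#'   (phase derived from parental genotypes where available) form the
#'   severe class and should be affected; single carriers are
#'   intermediate as above; an affected member carrying neither variant
#'   is inconsistent. When no parental genotypes resolve the phase the
#'   result is flagged `phase_ambiguous` and ranks below phased
#'   explanations in [search_explanations()].
#'
#' @param ped a `pedigree` with affection assigned.
#' @param gt a `genotype_table` covering the model's variants.
#' @param model an [inheritance_model()].
#' @return a `segregation_result`: list with `model`, `per_individual`
#'   (named status vector: `consistent`/`inconsistent`/`unknown`),
#'   `n_inconsistent`, `explains_all_affected`, `unexplained_affected`,
#'   `severe_class` (members genotype-predicted to be severely affected)
#'   and `phase_ambiguous`.
#' @export
evaluate_model <- function(ped, gt, model) {
  stopifnot(inherits(ped, "pedigree"), inherits(gt, "genotype_table"),
            inherits(model, "inheritance_model"))
  missing_v <- setdiff(model$variant_ids, gt$variants$vid)
  if (length(missing_v) > 0) {
    stop("model variant(s) absent from genotype table: ",
         paste(missing_v, collapse = ", "))
  }
  dos <- dosage_matrix(gt)
  members <- ped$members$subject_id
  scored <- intersect(members, rownames(dos))
  aff <- setNames(ped$members$affection, members)
  status <- setNames(rep("unknown", length(members)), members)
  severe <- character(0)
  phase_ambiguous <- FALSE

  for (s in scored) {
    a <- aff[[s]]
    if (a == "unknown") next
    d <- dos[s, model$variant_ids, drop = TRUE]
    if (any(is.na(d))) next
    ok <- switch(model$kind,
      dominant_single = {
        carrier <- d[1] >= 1
        if (carrier && a == "affected") severe <- c(severe, s)
        carrier == (a == "affected")
      },
      recessive_homozygous = {
        if (d[1] == 2) severe <- c(severe, s)
        if (d[1] == 2) a == "affected"
        else if (d[1] == 1) TRUE        # intermediate carrier class
        else a != "affected"            # affected non-carrier unexplained
      },
      compound_heterozygous = {
        v1 <- model$variant_ids[1]; v2 <- model$variant_ids[2]
        if (d[1] >= 1 && d[2] >= 1) {
          ph <- phase_pair(ped, dos, s, v1, v2)
          if (ph == "unknown") phase_ambiguous <- TRUE
          if (ph == "trans" || ph == "unknown") {
            severe <- c(severe, s)
            a == "affected"
          } else {
            TRUE  # apparently cis: still a carrier, intermediate class
          }
        } else if (sum(d) >= 1) {
          TRUE                          # single carrier, intermediate
        } else {
          a != "affected"
        }
      })
    status[[s]] <- if (ok) "consistent" else "inconsistent"
  }
  inconsistent <- names(status)[status == "inconsistent"]
  unexplained <- inconsistent[aff[inconsistent] == "affected"]
  structure(list(
    model = model,
    per_individual = status,
    n_inconsistent = length(inconsistent),
    explains_all_affected = length(unexplained) == 0 &&
      any(aff[scored] == "affected"),
    unexplained_affected = unexplained,
    severe_class = unique(severe),
    phase_ambiguous = phase_ambiguous
  ), class = "segregation_result")
}

#' Search for inheritance explanations of the kindred phenotype
#'
#' Enumerates every dominant single-variant model, every recessive model
#' with at least one homozygous-alternate member (a recessive explanation
#' without a homozygote is vacuous), and every same-gene compound pair
#' carried jointly by at least one member. Models are ranked by:
#' explains-all-affected, phased before phase-ambiguous, fewer
#' inconsistencies, fewer variants, model kind (recessive, then compound,
#' then dominant -- a model that distinguishes a severe genotype class is
#' preferred when scores tie), then gene and variant labels.
#'
#' @param ped a `pedigree` with affection assigned.
#' @param gt a `genotype_table` of candidate variants.
#' @return a `segregation_search`: list of `segregation_result`s in rank
#'   order (element `results`), with `best` pointing at the first.
#' @export
search_explanations <- function(ped, gt) {
  stopifnot(inherits(ped, "pedigree"), inherits(gt, "genotype_table"))
  aff <- ped$members$affection
  if (!any(aff == "affected")) {
    stop("pedigree has no affected member with known status")
  }
  dos <- dosage_matrix(gt)
  vids <- gt$variants$vid
  genes <- setNames(gt$variants$gene, vids)
  models <- list()
  for (v in vids) {
    models[[length(models) + 1]] <-
      inheritance_model("dominant_single", v, genes[[v]])
    if (any(!is.na(dos[, v]) & dos[, v] == 2)) {
      models[[length(models) + 1]] <-
        inheritance_model("recessive_homozygous", v, genes[[v]])
    }
  }
  for (g in unique(genes)) {
    gv <- vids[genes == g]
    if (length(gv) < 2) next
    pairs <- utils::combn(gv, 2, simplify = FALSE)
    for (p in pairs) {
      joint <- !is.na(dos[, p[1]]) & !is.na(dos[, p[2]]) &
        dos[, p[1]] >= 1 & dos[, p[2]] >= 1
      if (any(joint)) {
        models[[length(models) + 1]] <-
          inheritance_model("compound_heterozygous", p, g)
      }
    }
  }
  if (length(models) == 0) {
    return(structure(list(results = list(), best = NULL),
                     class = "segregation_search"))
  }
  results <- lapply(models, function(m) evaluate_model(ped, gt, m))
  kind_rank <- c(recessive_homozygous = 1, compound_heterozygous = 2,
                 dominant_single = 3)
  keys <- vapply(results, function(r) {
    sprintf("%d|%d|%04d|%d|%d|%s|%s",
            as.integer(!r$explains_all_affected),
            as.integer(r$phase_ambiguous),
            r$n_inconsistent,
            length(r$model$variant_ids),
            kind_rank[[r$model$kind]],
            r$model$gene,
            paste(sort(r$model$variant_ids), collapse = "+"))
  }, character(1))
  results <- results[order(keys)]
  structure(list(results = results, best = results[[1]]),
            class = "segregation_search")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("%s [%s] %s\n", x$model$kind, x$model$gene,
              paste(x$model$variant_ids, collapse = " + ")))
  cat(sprintf("  explains all affected: %s; inconsistent: %d%s\n",
              x$explains_all_affected, x$n_inconsistent,
              if (x$phase_ambiguous) " (phase ambiguous)" else ""))
  if (length(x$unexplained_affected) > 0) {
    cat("  unexplained affected:",
        paste(x$unexplained_affected, collapse = ", "), "\n")
  }
  if (length(x$severe_class) > 0) {
    cat("  genotype-predicted severe:",
        paste(x$severe_class, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.segregation_search <- function(x, ...) {
  cat("Cosegregation search over", length(x$results), "models; best:\n")
  if (is.null(x$best)) cat("  (no candidate model)\n") else print(x$best)
  invisible(x)
}
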