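#' Describe deletion breakpoints
#'
#' Coordinates are 1-based and denote *retained* reference bases: the last
#' retained base on the left of the deletion and the first retained base
#' on its right. The genome-build tag travels with the coordinates because
#' the two builds in routine use differ; no liftover is performed.
#'
#' @param chrom chromosome label.
#' @param left_last_retained,right_first_retained 1-based coordinates of
#'   the retained bases flanking the deleted interval.
#' @param build `"hg19"` or `"hg38"`.
#' @param insert_seq non-templated bases observed at the junction
#'   (empty string when the join is clean).
#' @return a `breakpoints` object.
#' @export
breakpoints <- function(chrom, left_last_retained, right_first_retained,
                        build = c("hg19", "hg38"), insert_seq = "") {
  build <- match.arg(build)
  left_last_retained <- as.numeric(left_last_retained)
  right_first_retained <- as.numeric(right_first_retained)
  if (!(right_first_retained > left_last_retained + 1)) {
    stop("not a deletion: right_first_retained must exceed ",
         "left_last_retained + 1")
  }
  if (nchar(insert_seq) > 0 &&
      !grepl("^[ACGT]+$", insert_seq)) {
    stop("insert_seq must be over {A,C,G,T}")
  }
  structure(list(chrom = chrom,
                 left_last_retained = left_last_retained,
                 right_first_retained = right_first_retained,
                 build = build, insert_seq = insert_seq),
            class = "breakpoints")
}

#' Length of the deleted reference interval
#'
#' The count of deleted reference bases,
#' `right_first_retained - left_last_retained - 1`. Any junction insert is
#' a separate observation and is not subtracted.
#'
#' @param bp a [breakpoints()] object.
#' @return integer number of deleted bases.
#' @export
deletion_length <- function(bp) {
  stopifnot(inherits(bp, "breakpoints"))
  as.integer(bp$right_first_retained - bp$left_last_retained - 1)
}

#' Characterize a deletion junction from a spanning read
#'
#' Anchors a junction-spanning read on the retained left and right flank
#' sequences and reports what lies between: either a non-templated insert
#' (bases aligning to neither flank) or a microhomology (identical
#' sequence shared by both flank ends, making the exact breakpoint
#' ambiguous). The two observations are mutually exclusive. The read must
#' match at least `min_anchor` bases of each flank.
#'
#' @param left_flank_seq reference sequence ending at the last retained
#'   base on the left of the deletion.
#' @param right_flank_seq reference sequence starting at the first
#'   retained base on the right.
#' @param junction_read a read spanning the novel adjacency.
#' @param min_anchor minimum exact anchor length on each flank
#'   (default 10).
#' @return list with `insert_seq` (possibly `""`) and `microhomology_len`.
#' @export
characterize_junction <- function(left_flank_seq, right_flank_seq,
                                  junction_read, min_anchor = 10) {
  L <- toupper(left_flank_seq); R <- toupper(right_flank_seq)
  J <- toupper(junction_read)
  nJ <- nchar(J)
  # longest prefix of the read equal to a suffix of the left flank
  a <- 0L
  for (k in seq_len(min(nJ, nchar(L)))) {
    if (substr(J, 1, k) == substr(L, nchar(L) - k + 1, nchar(L))) a <- k
  }
  # longest suffix of the read equal to a prefix of the right flank
  b <- 0L
  for (k in seq_len(min(nJ, nchar(R)))) {
    if (substr(J, nJ - k + 1, nJ) == substr(R, 1, k)) b <- k
  }
  if (a < min_anchor || b < min_anchor) {
    stop("no anchor: junction read does not match at least ", min_anchor,
         " bases of each flank")
  }
  if (a + b < nJ) {
    list(insert_seq = substr(J, a + 1, nJ - b), microhomology_len = 0L)
  } else {
    list(insert_seq = "", microhomology_len = as.integer(a + b - nJ))
  }
}

#' Define a PCR primer pair
#'
#' @param name pair label.
#' @param forward_seq,reverse_seq primer sequences written 5' to 3', over
#'   `{A,C,G,T}`, at least 15 bases.
#' @param expected_product_bp expected amplicon size, or `NA` when the
#'   pair is not expected to amplify the reference allele.
#' @return a one-row data frame; rows may be bound into a primer panel.
#' @export
primer_pair <- function(name, forward_seq, reverse_seq,
                        expected_product_bp = NA_integer_) {
  forward_seq <- toupper(forward_seq); reverse_seq <- toupper(reverse_seq)
  for (s in c(forward_seq, reverse_seq)) {
    if (!grepl("^[ACGT]+$", s)) {
      stop("primer contains characters outside {A,C,G,T}: ", s,
           " (ambiguity codes are unsupported)")
    }
    if (nchar(s) < 15) stop("primer shorter than 15 bases: ", s)
  }
  data.frame(name = name, forward_seq = forward_seq,
             reverse_seq = reverse_seq,
             expected_product_bp = as.integer(expected_product_bp),
             stringsAsFactors = FALSE)
}

#' Read a primer panel (TSV: name, forward, reverse[, product])
#' @param path tab-separated file with a header.
#' @return data frame of primer pairs.
#' @export
read_primers <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  do.call(rbind, lapply(seq_len(nrow(raw)), function(i) {
    primer_pair(raw$name[i], raw$forward[i], raw$reverse[i],
                if ("product" %in% names(raw))
                  suppressWarnings(as.integer(raw$product[i]))
                else NA_integer_)
  }))
}

revcomp <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# all exact match start positions of pattern in subject
match_starts <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits)
}

#' Predict multiplex PCR products on a template
#'
#' Exact-match amplicon prediction: a product is reported when one primer
#' matches the template and the reverse complement of its mate matches
#' downstream within `max_product_bp`. Both template strands are searched.
#' The product size is the inclusive span from the 5' start of one primer
#' to the 5' start of the other (i.e. the amplicon length). Exact matching
#' only -- the screening assay needs presence/absence of a band, not
#' amplification efficiency.
#'
#' @param template_seq template sequence (character, `{A,C,G,T}`).
#' @param pairs data frame of primer pairs (see [primer_pair()]).
#' @param max_product_bp largest product reported (default 1000, a
#'   practical limit for a screening amplicon).
#' @return data frame `pair_name`, `product_bp`, `start`, `end` (template
#'   coordinates of the amplicon), possibly empty.
#' @export
in_silico_pcr <- function(template_seq, pairs, max_product_bp = 1000) {
  template <- toupper(template_seq)
  if (!grepl("^[ACGT]*$", template)) {
    stop("template contains characters outside {A,C,G,T}")
  }
  out <- data.frame(pair_name = character(0), product_bp = integer(0),
                    start = integer(0), end = integer(0),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    fwd <- toupper(pairs$forward_seq[i]); rev <- toupper(pairs$reverse_seq[i])
    if (!grepl("^[ACGT]+$", fwd) || !grepl("^[ACGT]+$", rev)) {
      stop("primer with ambiguity codes is unsupported (pair ",
           pairs$name[i], ")")
    }
    # orientation 1: forward primer on plus strand, reverse downstream
    # orientation 2: the amplicon read off the minus strand
    combos <- list(c(fwd, rev), c(rev, fwd))
    seen <- character(0)
    for (cmb in combos) {
      left <- cmb[1]; right_rc <- revcomp(cmb[2])
      for (s in match_starts(left, template)) {
        for (t in match_starts(right_rc, template)) {
          end <- t + nchar(right_rc) - 1L
          size <- end - s + 1L
          if (end >= s + nchar(left) && size <= max_product_bp) {
            key <- paste(s, end)
            if (!(key %in% seen)) {
              seen <- c(seen, key)
              out <- rbind(out, data.frame(
                pair_name = pairs$name[i], product_bp = size,
                start = s, end = end, stringsAsFactors = FALSE))
            }
          }
        }
      }
    }
  }
  out[order(out$pair_name, out$product_bp), , drop = FALSE]
}

#' Screening-assay configuration
#'
#' @param wt_band product size (bp) diagnostic of the wild-type allele
#'   (amplified from inside the deleted interval).
#' @param del_band breakpoint-spanning product size diagnostic of the
#'   deletion allele.
#' @param tolerance band-size matching tolerance in bp (gel-resolution
#'   proxy; default 10).
#' @return an `assay_config`.
#' @export
assay_config <- function(wt_band = 481, del_band = 254, tolerance = 10) {
  stopifnot(wt_band > 0, del_band > 0, tolerance >= 0)
  if (abs(wt_band - del_band) <= 2 * tolerance) {
    stop("wild-type and deletion bands are not resolvable at this tolerance")
  }
  structure(list(wt_band = wt_band, del_band = del_band,
                 tolerance = tolerance),
            class = "assay_config")
}

#' Read an assay configuration from YAML (`wt_band`, `del_band`, `tolerance`)
#' @param path YAML file.
#' @return an `assay_config`.
#' @export
read_assay_config <- function(path) {
  y <- yaml::read_yaml(path)
  assay_config(y$wt_band, y$del_band, y$tolerance %||% 10)
}

#' Call a structural-variant genotype from a band pattern
#'
#' Both diagnostic bands present: heterozygous (`wt/del`); wild-type band
#' only: `wt/wt`; deletion band only: `del/del`; neither: assay failure.
#' Band sizes match within the configured tolerance.
#'
#' @param product_sizes_bp integer vector of observed band sizes for one
#'   sample (may be empty).
#' @param assay an [assay_config()].
#' @return one of `"wt/wt"`, `"wt/del"`, `"del/del"`, `"fail"`.
#' @export
genotype_from_bands <- function(product_sizes_bp, assay) {
  stopifnot(inherits(assay, "assay_config"))
  sizes <- as.numeric(product_sizes_bp)
  if (any(!is.na(sizes) & sizes <= 0)) stop("band sizes must be positive")
  has_wt <- any(abs(sizes - assay$wt_band) <= assay$tolerance)
  has_del <- any(abs(sizes - assay$del_band) <= assay$tolerance)
  if (has_wt && has_del) "wt/del"
  else if (has_wt) "wt/wt"
  else if (has_del) "del/del"
  else "fail"
}

#' Screen a cohort of band patterns for the deletion
#'
#' @param band_patterns named list: sample id -> integer vector of band
#'   sizes (empty vector = no amplification).
#' @param assay an [assay_config()].
#' @return list with `genotypes` (named character vector), `counts`
#'   (named table over `wt/wt`, `wt/del`, `del/del`, `fail`) and
#'   `carriers` (sample ids with at least one deletion allele).
#' @export
screen_cohort <- function(band_patterns, assay) {
  stopifnot(length(band_patterns) > 0)
  ids <- names(band_patterns)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("band patterns must be named by sample id")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  calls <- vapply(band_patterns, genotype_from_bands, character(1),
                  assay = assay)
  counts <- setNames(integer(4), c("wt/wt", "wt/del", "del/del", "fail"))
  tab <- table(calls)
  counts[names(tab)] <- as.integer(tab)
  list(genotypes = calls, counts = counts,
       carriers = ids[calls %in% c("wt/del", "del/del")])
}
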