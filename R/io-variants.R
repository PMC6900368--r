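#' Read a dialect configuration for annotated variant tables
#'
#' Annotated exome tables arrive in many tab-separated dialects (the output
#' of annotation engines reshaped by hand). A dialect config maps the
#' column names of a particular table onto the fields of the internal
#' variant representation, and declares which columns hold per-database
#' allele frequencies, categorical pathogenicity calls and numeric scores.
#'
#' The YAML file has four blocks: `columns` (field -> column name for the
#' fixed fields), `af` (database name -> column), `predictors`
#' (predictor name -> column) and `scores` (score name -> column), plus an
#' optional `missing` list of cell tokens treated as absent values
#' (default `"—"`, `"."` and the empty string).
#'
#' @param path path to a YAML dialect file.
#' @return a list with class `"variant_dialect"`.
#' @export
read_dialect <- function(path) {
  stopifnot(file.exists(path))
  d <- yaml::read_yaml(path)
  as_dialect(d)
}

#' @rdname read_dialect
#' @param x a list with `columns`, and optionally `af`, `predictors`,
#'   `scores`, `missing` entries.
#' @export
as_dialect <- function(x) {
  required <- c("chrom", "pos", "gene", "consequence")
  cols <- x$columns
  missing_fields <- setdiff(required, names(cols))
  if (length(missing_fields) > 0) {
    stop("dialect lacks required field mapping(s): ",
         paste(missing_fields, collapse = ", "))
  }
  structure(
    list(
      columns    = cols,
      af         = x$af %||% list(),
      predictors = x$predictors %||% list(),
      scores     = x$scores %||% list(),
      missing    = unlist(x$missing %||% c("—", ".", "")),
      build      = x$build %||% "hg19"
    ),
    class = "variant_dialect"
  )
}

#' Read an annotated variant table
#'
#' Parses a tab-separated annotated exome table into a `variant_table`
#' data frame: one row per variant, with fixed fields (`chrom`, `pos`,
#' `gene`, `consequence`, optionally `variant_id`, `exon`, `cdna_change`,
#' `protein_change`, `depth`, `ref_allele`, `alt_allele`, `clinvar`),
#' allele-frequency columns `af.<database>`, categorical predictor columns
#' `pred.<name>` and numeric score columns `score.<name>`. Missing cells
#' (em-dash and friends) become `NA`, never zeros, so that absent
#' frequencies are not mistaken for rarity downstream.
#'
#' @param path tab-separated UTF-8 file with a header row.
#' @param dialect a `variant_dialect` (see [read_dialect()]).
#' @return a `variant_table` data frame; positions are 1-based and carry
#'   the dialect's genome-build tag in `attr(, "build")`.
#' @export
read_variant_table <- function(path, dialect) {
  stopifnot(file.exists(path), inherits(dialect, "variant_dialect"))
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, fileEncoding = "UTF-8")
  # header validation: every mapped column must exist
  wanted <- c(unlist(dialect$columns), unlist(dialect$af),
              unlist(dialect$predictors), unlist(dialect$scores))
  absent <- setdiff(wanted, names(raw))
  required_cols <- unlist(dialect$columns[c("chrom", "pos", "gene", "consequence")])
  bad_required <- intersect(absent, required_cols)
  if (length(bad_required) > 0) {
    stop("variant table is missing required column(s): ",
         paste(bad_required, collapse = ", "))
  }
  if (length(absent) > 0) {
    stop("variant table is missing mapped column(s): ",
         paste(absent, collapse = ", "))
  }
  blank <- function(v) {
    v <- trimws(v)
    v[v %in% dialect$missing] <- NA_character_
    v
  }
  n <- nrow(raw)
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    chrom = character(n))
  grab <- function(field) {
    col <- dialect$columns[[field]]
    if (is.null(col)) rep(NA_character_, n) else blank(raw[[col]])
  }
  out$chrom <- grab("chrom")
  pos_chr <- gsub(",", "", grab("pos"))
  pos <- suppressWarnings(as.integer(pos_chr))
  if (n > 0 && any(is.na(pos) & !is.na(pos_chr))) {
    stop("non-integer position at row(s): ",
         paste(which(is.na(pos) & !is.na(pos_chr)), collapse = ", "))
  }
  if (any(!is.na(pos) & pos < 1)) stop("positions must be >= 1")
  out$pos <- pos
  for (f in c("variant_id", "gene", "exon", "cdna_change", "protein_change",
              "consequence", "ref_allele", "alt_allele", "clinvar")) {
    out[[f]] <- grab(f)
  }
  bad_csq <- setdiff(stats::na.omit(unique(out$consequence)), CONSEQUENCE_LEVELS)
  if (length(bad_csq) > 0) {
    stop("unknown consequence label(s): ", paste(bad_csq, collapse = ", "))
  }
  depth_chr <- grab("depth")
  depth <- suppressWarnings(as.numeric(depth_chr))
  if (any(is.na(depth) & !is.na(depth_chr))) {
    stop("non-numeric depth at row(s): ",
         paste(which(is.na(depth) & !is.na(depth_chr)), collapse = ", "))
  }
  if (any(!is.na(depth) & depth < 0)) {
    stop("negative depth at row(s): ",
         paste(which(!is.na(depth) & depth < 0), collapse = ", "))
  }
  out$depth <- depth
  for (db in names(dialect$af)) {
    v <- blank(raw[[dialect$af[[db]]]])
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad) > 0) {
      stop("non-numeric allele frequency (", db, ") at row(s): ",
           paste(bad, collapse = ", "))
    }
    if (any(!is.na(num) & (num < 0 | num > 1))) {
      stop("allele frequency outside [0,1] in database ", db)
    }
    out[[paste0("af.", db)]] <- num
  }
  for (p in names(dialect$predictors)) {
    out[[paste0("pred.", p)]] <- blank(raw[[dialect$predictors[[p]]]])
  }
  for (s in names(dialect$scores)) {
    v <- blank(raw[[dialect$scores[[s]]]])
    # tolerate typeset minus signs in transcriptions
    num <- suppressWarnings(as.numeric(gsub("−", "-", v)))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad) > 0) {
      stop("non-numeric score (", s, ") at row(s): ",
           paste(bad, collapse = ", "))
    }
    out[[paste0("score.", s)]] <- num
  }
  out$vid <- variant_key(out)
  attr(out, "build") <- dialect$build
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Stable identifier for each row of a variant table
#'
#' `chrom:pos:gene`; coordinates are 1-based within the table's build.
#' @param variants a `variant_table` (or any data frame with `chrom`,
#'   `pos`, `gene`).
#' @return character vector of keys.
#' @export
variant_key <- function(variants) {
  if (nrow(variants) == 0) return(character(0))
  paste0(variants$chrom, ":", variants$pos, ":", variants$gene)
}

#' Write an annotated variant table in a given dialect
#'
#' Inverse of [read_variant_table()]: emits a tab-separated file whose
#' columns follow the dialect mapping, with `NA` rendered as the dialect's
#' first missing token. `read_variant_table(write_variant_table(x))` is
#' field-identical to `x`.
#'
#' @param variants a `variant_table`.
#' @param path output path.
#' @param dialect a `variant_dialect`.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path, dialect) {
  stopifnot(inherits(dialect, "variant_dialect"))
  miss <- dialect$missing[1]
  cols <- list()
  put <- function(colname, v) {
    v <- as.character(v)
    v[is.na(v)] <- miss
    cols[[colname]] <<- v
  }
  for (f in names(dialect$columns)) put(dialect$columns[[f]], variants[[f]])
  for (db in names(dialect$af)) put(dialect$af[[db]], variants[[paste0("af.", db)]])
  for (p in names(dialect$predictors)) put(dialect$predictors[[p]], variants[[paste0("pred.", p)]])
  for (s in names(dialect$scores)) put(dialect$scores[[s]], variants[[paste0("score.", s)]])
  df <- as.data.frame(cols, check.names = FALSE, optional = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a kindred genotype table
#'
#' A kindred genotype table records, for each candidate variant, the
#' diploid genotype of every typed family member. The file is
#' tab-separated with the variant-description columns `gene`, `chrom`,
#' `pos`, `protein_change`, `ref_allele`, `alt_allele` followed by one
#' column per subject. SNV genotypes are unordered allele pairs (`"GA"`);
#' indel and structural-variant genotypes use a `/` separator
#' (`"AGA/-"`, `"-/del"`). Missing genotypes are `"."` or empty.
#'
#' @param path tab-separated file with a header row.
#' @return a `genotype_table`: list with `variants` (data frame, one row
#'   per variant, including a `vid` key) and `geno` (character matrix,
#'   subjects x variants).
#' @export
read_genotype_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, fileEncoding = "UTF-8")
  meta_cols <- c("gene", "chrom", "pos", "protein_change",
                 "ref_allele", "alt_allele")
  missing_meta <- setdiff(meta_cols, names(raw))
  if (length(missing_meta) > 0) {
    stop("genotype table is missing column(s): ",
         paste(missing_meta, collapse = ", "))
  }
  subjects <- setdiff(names(raw), meta_cols)
  if (length(subjects) == 0) stop("genotype table has no subject columns")
  variants <- raw[meta_cols]
  variants$pos <- as.integer(gsub(",", "", variants$pos))
  variants$vid <- variant_key(variants)
  if (anyDuplicated(variants$vid)) {
    stop("duplicate variant keys: ",
         paste(variants$vid[duplicated(variants$vid)], collapse = ", "))
  }
  geno <- t(as.matrix(raw[subjects]))
  geno[geno %in% c(".", "")] <- NA_character_
  colnames(geno) <- variants$vid
  rownames(geno) <- subjects
  as_genotype_table(variants, geno)
}

#' @rdname read_genotype_table
#' @param variants data frame with at least `gene`, `chrom`, `pos`,
#'   `ref_allele`, `alt_allele` (a `vid` column is derived if absent).
#' @param geno character matrix of genotype strings, subjects in rows,
#'   variants in columns (matching `variants` order).
#' @export
as_genotype_table <- function(variants, geno) {
  if (is.null(variants$vid)) variants$vid <- variant_key(variants)
  stopifnot(ncol(geno) == nrow(variants))
  colnames(geno) <- variants$vid
  structure(list(variants = variants, geno = geno),
            class = "genotype_table")
}

#' Write a kindred genotype table
#' @param gt a `genotype_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  meta <- gt$variants[c("gene", "chrom", "pos", "protein_change",
                        "ref_allele", "alt_allele")]
  g <- t(gt$geno)
  g[is.na(g)] <- "."
  df <- cbind(meta, as.data.frame(g, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Count alternate alleles in a diploid genotype string
#'
#' Parses the genotype encodings of [read_genotype_table()]: two-character
#' strings are unordered single-base allele pairs; `/`-separated strings
#' are allele pairs of arbitrary length (indels, the deletion allele).
#' The count is the number of alleles equal to `alt`; alleles equal to
#' neither `ref` nor `alt` raise an error.
#'
#' @param geno character vector of genotype strings (`NA` allowed).
#' @param ref,alt the reference and alternate allele of the variant.
#' @return integer vector of alternate-allele dosages (0, 1, 2 or `NA`).
#' @export
allele_dosage <- function(geno, ref, alt) {
  vapply(geno, function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- if (grepl("/", g, fixed = TRUE)) {
      strsplit(g, "/", fixed = TRUE)[[1]]
    } else {
      strsplit(g, "", fixed = TRUE)[[1]]
    }
    if (length(alleles) != 2) stop("genotype is not diploid: ", g)
    bad <- setdiff(alleles, c(ref, alt))
    if (length(bad) > 0) {
      stop("allele(s) ", paste(bad, collapse = ","),
           " match neither ref '", ref, "' nor alt '", alt, "'")
    }
    sum(alleles == alt)
  }, integer(1), USE.NAMES = !is.null(names(geno)))
}

#' Alternate-allele dosage matrix of a genotype table
#'
#' @param gt a `genotype_table`.
#' @return integer matrix (subjects x variants) of alternate-allele counts.
#' @export
dosage_matrix <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  out <- matrix(NA_integer_, nrow(gt$geno), ncol(gt$geno),
                dimnames = dimnames(gt$geno))
  for (j in seq_len(ncol(gt$geno))) {
    out[, j] <- allele_dosage(gt$geno[, j],
                              gt$variants$ref_allele[j],
                              gt$variants$alt_allele[j])
  }
  out
}
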