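#' Read a pedigree file with optional lipid-panel columns
#'
#' The format extends six-column PED (`FID IID FATHER MOTHER SEX AFFECTION`)
#' with optional named columns `AGE`, `BMI`, `TC`, `HDL`, `TG`, `LDL`
#' (lipids in mg/dl). A header row is required; `0` denotes a missing
#' parent; sex is `1`/`M` male, `2`/`F` female, `0` unknown; affection is
#' `2`/`affected`, `1`/`unaffected`, `0`/`-9`/`unknown`.
#'
#' Subject labels are opaque strings kept verbatim (the generation-index
#' convention `"1-1"` of clinical pedigrees is typical). Parental links
#' are validated: a parent id that does not resolve within the family is
#' an error naming the id, and a parentage cycle is an error reporting the
#' offending chain.
#'
#' @param path tab-separated pedigree file.
#' @return a `pedigree`: list with `family_id`, `members` (data frame with
#'   `subject_id`, `father_id`, `mother_id`, `sex`, `age`, `bmi`, `tc`,
#'   `hdl`, `tg`, `ldl`, `ldl_method`, `affection`) and `founders`
#'   (subject ids with both parents missing).
#' @export
read_pedigree <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ".", ""),
                           fileEncoding = "UTF-8")
  names(raw) <- sub("^#", "", toupper(names(raw)))
  needed <- c("FID", "IID", "FATHER", "MOTHER", "SEX")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("pedigree file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  num <- function(col) {
    if (col %in% names(raw)) suppressWarnings(as.numeric(raw[[col]]))
    else rep(NA_real_, nrow(raw))
  }
  sex <- toupper(raw$SEX)
  sex <- ifelse(sex %in% c("1", "M"), "M",
         ifelse(sex %in% c("2", "F"), "F", "unknown"))
  aff <- if ("AFFECTION" %in% names(raw)) tolower(raw$AFFECTION) else
    rep(NA_character_, nrow(raw))
  aff <- ifelse(is.na(aff) | aff %in% c("0", "-9", "unknown"), "unknown",
         ifelse(aff %in% c("2", "affected"), "affected",
         ifelse(aff %in% c("1", "unaffected"), "unaffected", "unknown")))
  members <- data.frame(
    subject_id = raw$IID,
    father_id  = ifelse(raw$FATHER %in% c("0", NA), NA_character_, raw$FATHER),
    mother_id  = ifelse(raw$MOTHER %in% c("0", NA), NA_character_, raw$MOTHER),
    sex        = sex,
    age        = num("AGE"),
    bmi        = num("BMI"),
    tc         = num("TC"),
    hdl        = num("HDL"),
    tg         = num("TG"),
    ldl        = num("LDL"),
    ldl_method = if ("LDL_METHOD" %in% names(raw)) raw$LDL_METHOD else
      ifelse(is.na(num("LDL")), NA_character_, "measured"),
    affection  = aff,
    stringsAsFactors = FALSE
  )
  new_pedigree(raw$FID[1] %||% "FAM", members)
}

#' Construct a validated pedigree from a member table
#'
#' @param family_id family label.
#' @param members data frame as described in [read_pedigree()]; missing
#'   optional columns are filled with `NA`.
#' @return a `pedigree`.
#' @export
new_pedigree <- function(family_id, members) {
  for (col in c("age", "bmi", "tc", "hdl", "tg", "ldl")) {
    if (is.null(members[[col]])) members[[col]] <- NA_real_
  }
  if (is.null(members$ldl_method)) members$ldl_method <- NA_character_
  if (is.null(members$affection)) members$affection <- "unknown"
  if (anyDuplicated(members$subject_id)) {
    stop("duplicate subject id(s): ",
         paste(unique(members$subject_id[duplicated(members$subject_id)]),
               collapse = ", "))
  }
  lip <- c(members$tc, members$hdl, members$tg, members$ldl)
  if (any(!is.na(lip) & lip < 0)) stop("lipid values must be >= 0")
  ids <- members$subject_id
  for (col in c("father_id", "mother_id")) {
    dangling <- setdiff(stats::na.omit(members[[col]]), ids)
    if (length(dangling) > 0) {
      stop("parent id(s) not present in pedigree: ",
           paste(dangling, collapse = ", "))
    }
  }
  # cycle detection: walk ancestors from each member
  parent_of <- function(id) {
    r <- members[members$subject_id == id, ]
    stats::na.omit(c(r$father_id, r$mother_id))
  }
  state <- setNames(rep(0L, length(ids)), ids) # 0 new, 1 active, 2 done
  visit <- function(id, chain) {
    if (state[[id]] == 1L) {
      stop("pedigree contains an ancestry cycle: ",
           paste(c(chain, id), collapse = " -> "))
    }
    if (state[[id]] == 2L) return(invisible())
    state[[id]] <<- 1L
    for (p in parent_of(id)) visit(p, c(chain, id))
    state[[id]] <<- 2L
    invisible()
  }
  for (id in ids) visit(id, character(0))
  founders <- ids[is.na(members$father_id) & is.na(members$mother_id)]
  structure(list(family_id = family_id, members = members,
                 founders = founders),
            class = "pedigree")
}

#' Write a pedigree file
#' @param ped a `pedigree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  m <- ped$members
  df <- data.frame(
    FID = ped$family_id,
    IID = m$subject_id,
    FATHER = ifelse(is.na(m$father_id), "0", m$father_id),
    MOTHER = ifelse(is.na(m$mother_id), "0", m$mother_id),
    SEX = ifelse(m$sex == "M", "1", ifelse(m$sex == "F", "2", "0")),
    AFFECTION = ifelse(m$affection == "affected", "2",
                ifelse(m$affection == "unaffected", "1", "0")),
    AGE = m$age, BMI = m$bmi, TC = m$tc, HDL = m$hdl, TG = m$tg,
    LDL = m$ldl, LDL_METHOD = m$ldl_method,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree", x$family_id, "with", nrow(x$members), "members (",
      length(x$founders), "founders )\n")
  print(x$members[c("subject_id", "father_id", "mother_id", "sex",
                    "ldl", "affection")], row.names = FALSE)
  invisible(x)
}
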