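#' Construct a pedigree
#'
#' A pedigree is a data frame of family members with parental links, sex,
#' affection status and optional risk-allele carrier status. It drives the
#' unaffected-subtraction and paternal-removal stages of the filter cascade
#' and the germline / de novo partition of daughter-carried variants.
#'
#' @param id Character member identifiers (unique).
#' @param sex `"female"` or `"male"` per member.
#' @param father_id,mother_id Parent identifiers; `NA` marks a founder
#'   (parent not in the file).
#' @param affected Logical affection status.
#' @param carrier Optional logical carrier status for the family's risk
#'   allele (e.g. a founder mutation); `NA` when untyped.
#' @param age Optional age in years (e.g. age at diagnosis).
#' @return An object of class `pedigree`: a validated data frame with one
#'   row per member.
#' @export
pedigree <- function(id, sex, father_id = NA, mother_id = NA,
                     affected = FALSE, carrier = NA, age = NA) {
  ped <- data.frame(
    id = as.character(id),
    sex = as.character(sex),
    father_id = as.character(rep_len(father_id, length(id))),
    mother_id = as.character(rep_len(mother_id, length(id))),
    affected = as.logical(rep_len(affected, length(id))),
    carrier = as.logical(rep_len(carrier, length(id))),
    age = as.numeric(rep_len(age, length(id))),
    stringsAsFactors = FALSE
  )
  validate_pedigree(ped)
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) {
    stop("duplicate member ids in pedigree: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  }
  if (!all(ped$sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'")
  }
  for (col in c("father_id", "mother_id")) {
    ref <- ped[[col]]
    dangling <- !is.na(ref) & !(ref %in% ped$id)
    if (any(dangling)) {
      stop("pedigree references missing ", sub("_id", "", col), "(s): ",
           paste(unique(ref[dangling]), collapse = ", "))
    }
  }
  # cycle check: repeatedly peel members whose parents are all peeled founders
  remaining <- ped$id
  repeat {
    peel <- vapply(remaining, function(m) {
      row <- ped[ped$id == m, ]
      ok <- function(p) is.na(p) || !(p %in% remaining)
      ok(row$father_id) && ok(row$mother_id)
    }, logical(1))
    if (!any(peel)) break
    remaining <- remaining[!peel]
  }
  if (length(remaining) > 0) {
    stop("pedigree contains an ancestry cycle involving: ",
         paste(remaining, collapse = ", "))
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Read a pedigree from a PED file
#'
#' Parses the 6+ column whitespace-delimited PED dialect: family id, member
#' id, father id, mother id, sex (1 = male, 2 = female), phenotype
#' (2 = affected, 1 = unaffected, 0/-9 = missing, read as unaffected).
#' A parent id of `0` marks a founder. Two optional extra columns are
#' recognised in order: carrier status (1/0) and age in years.
#'
#' @param path Path to the PED file.
#' @return A [pedigree()] object.
#' @export
parse_pedigree <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(raw) < 6) {
    stop("PED file must have at least 6 columns, found ", ncol(raw))
  }
  sex_code <- raw[[5]]
  if (!all(sex_code %in% c("1", "2"))) {
    stop("PED sex column must be 1 (male) or 2 (female)")
  }
  carrier <- if (ncol(raw) >= 7) raw[[7]] == "1" else NA
  age <- if (ncol(raw) >= 8) suppressWarnings(as.numeric(raw[[8]])) else NA
  age[!is.na(age) & age < 0] <- NA # -9 = missing, PED convention
  pedigree(
    id = raw[[2]],
    sex = ifelse(sex_code == "2", "female", "male"),
    father_id = ifelse(raw[[3]] == "0", NA, raw[[3]]),
    mother_id = ifelse(raw[[4]] == "0", NA, raw[[4]]),
    affected = raw[[6]] == "2",
    carrier = carrier,
    age = age
  )
}

#' Write a pedigree to a PED file
#'
#' Inverse of [parse_pedigree()]; emits the 6-column dialect plus carrier
#' and age columns when any member has them set.
#'
#' @param ped A [pedigree()] object.
#' @param path Output path.
#' @param family_id Family identifier written in column 1.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, family_id = "FAM1") {
  out <- data.frame(
    fam = family_id,
    id = ped$id,
    father = ifelse(is.na(ped$father_id), "0", ped$father_id),
    mother = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex = ifelse(ped$sex == "female", "2", "1"),
    pheno = ifelse(ped$affected, "2", "1"),
    stringsAsFactors = FALSE
  )
  if (any(!is.na(ped$carrier)) || any(!is.na(ped$age))) {
    out$carrier <- ifelse(is.na(ped$carrier), "0", as.integer(ped$carrier))
  }
  if (any(!is.na(ped$age))) {
    out$age <- ifelse(is.na(ped$age), "-9", ped$age)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

ped_member <- function(ped, id) {
  i <- match(id, ped$id)
  if (any(is.na(i))) {
    stop("unknown pedigree member(s): ", paste(id[is.na(i)], collapse = ", "))
  }
  ped[i, , drop = FALSE]
}

#' Daughters of a father within a pedigree
#'
#' @param ped A [pedigree()] object.
#' @param father_id Member id of the father.
#' @return Character vector of female offspring ids (possibly empty).
#' @export
daughters_of <- function(ped, father_id) {
  ped_member(ped, father_id)
  ped$id[!is.na(ped$father_id) & ped$father_id == father_id &
           ped$sex == "female"]
}
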