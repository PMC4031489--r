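#' Functional classes recognised by the cascade
#' @export
FUNCTIONAL_CLASSES <- c("synonymous", "nonsynonymous_SNV", "splicing",
                        "stopgain", "stoploss", "other")

#' Read a variant annotation table
#'
#' The annotation table is tab-separated text with a header, one row per
#' variant, carrying the gene symbol, the coding / protein change, the
#' functional class, optional catalog id, per-catalog minor allele
#' frequencies (columns named `maf_<catalog>`, e.g. `maf_ESP6500`,
#' `maf_1000G`), the SIFT score, the PolyPhen-2 HumVar score and an
#' optional Sanger-confirmation flag. Missing cells are parsed as absent
#' (`NA`), never as zero: in particular an absent MAF means the variant is
#' not catalogued (novel), which the rare-variant filter treats very
#' differently from a catalogued frequency of 0.
#'
#' @param path Path to the TSV file. Required columns: `gene`, `chrom`,
#'   `pos`, `ref`, `alt`, `functional_class`. Recognised optional columns:
#'   `cdna_change`, `protein_change`, `known_id`, `sift`, `polyphen_hvar`,
#'   `sanger_confirmed`, and any number of `maf_*` columns.
#' @return A data frame keyed by the canonical variant `key` column, with
#'   class `variant_annotation`.
#' @export
read_annotation_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", "", "."))
  required <- c("gene", "chrom", "pos", "ref", "alt", "functional_class")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("annotation table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  keys <- normalize_key(tab$chrom, tab$pos, tab$ref, tab$alt)
  tab$key <- keys$key
  tab$chrom <- keys$chrom
  tab$ref <- keys$ref
  tab$alt <- keys$alt
  if (anyDuplicated(tab$key)) {
    stop("duplicate variant keys in annotation table: ",
         paste(unique(tab$key[duplicated(tab$key)]), collapse = ", "))
  }
  if (!all(tab$functional_class %in% FUNCTIONAL_CLASSES)) {
    bad <- setdiff(unique(tab$functional_class), FUNCTIONAL_CLASSES)
    stop("unknown functional class(es): ", paste(bad, collapse = ", "))
  }
  for (col in maf_columns(tab)) {
    v <- tab[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop("MAF outside [0,1] in column ", col)
    }
  }
  for (col in intersect(c("sift", "polyphen_hvar"), names(tab))) {
    v <- tab[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop("score outside [0,1] in column ", col)
    }
  }
  if (is.null(tab$sift)) tab$sift <- NA_real_
  if (is.null(tab$polyphen_hvar)) tab$polyphen_hvar <- NA_real_
  if (is.null(tab$known_id)) tab$known_id <- NA_character_
  if (!is.null(tab$sanger_confirmed)) {
    tab$sanger_confirmed <- as.logical(tab$sanger_confirmed)
  } else {
    tab$sanger_confirmed <- NA
  }
  tab <- tab[, c("key", "gene", "chrom", "pos", "ref", "alt",
                 intersect(c("cdna_change", "protein_change"), names(tab)),
                 "functional_class", "known_id", maf_columns(tab),
                 "sift", "polyphen_hvar", "sanger_confirmed")]
  class(tab) <- c("variant_annotation", "data.frame")
  tab
}

#' Names of the per-catalog MAF columns of an annotation table
#' @param anns An annotation data frame.
#' @return Character vector (possibly empty) of `maf_*` column names.
#' @export
maf_columns <- function(anns) {
  grep("^maf_", names(anns), value = TRUE)
}

#' Highest catalogued minor allele frequency per variant
#'
#' @param anns An annotation data frame.
#' @return Numeric vector; `NA` where the variant is absent from every
#'   catalog (novel).
#' @export
max_catalog_maf <- function(anns) {
  cols <- maf_columns(anns)
  if (!length(cols)) return(rep(NA_real_, nrow(anns)))
  m <- as.matrix(anns[, cols, drop = FALSE])
  out <- suppressWarnings(apply(m, 1L, max, na.rm = TRUE))
  out[!is.finite(out)] <- NA_real_
  unname(out)
}

#' Filter cascade configuration
#'
#' Bundles every tunable threshold of the prioritization cascade with the
#' published defaults: variants with a catalogued MAF above 0.001 are
#' common polymorphisms; SIFT calls a substitution damaging below 0.05;
#' PolyPhen-2 HumVar calls it at least "possibly damaging" from 0.447
#' upward; synonymous and unclassified variants are discarded; caller
#' consensus is the intersection of callers; a variant is "common" within
#' the family when at least 2 affected members carry it.
#'
#' @param maf_threshold Maximum catalogued MAF for a variant to count as
#'   rare (in \[0,1\]).
#' @param sift_damaging_max SIFT scores strictly below this are damaging.
#' @param polyphen_damaging_min PolyPhen-2 HumVar scores at or above this
#'   are damaging.
#' @param kept_classes Functional classes retained by the class filter.
#' @param caller_mode `"intersection"` or `"union"` for caller consensus.
#' @param control_ids Sample ids used as unaffected controls for the
#'   subtraction stage.
#' @param recurrence_common_min Minimum number of affected carriers for a
#'   variant to be classed "common" within the family.
#' @return An object of class `filter_config` (a named list).
#' @export
filter_config <- function(maf_threshold = 0.001,
                          sift_damaging_max = 0.05,
                          polyphen_damaging_min = 0.447,
                          kept_classes = c("nonsynonymous_SNV", "splicing",
                                           "stopgain", "stoploss"),
                          caller_mode = c("intersection", "union"),
                          control_ids = character(0),
                          recurrence_common_min = 2L) {
  caller_mode <- match.arg(caller_mode)
  for (x in c(maf_threshold, sift_damaging_max, polyphen_damaging_min)) {
    if (!is.numeric(x) || x < 0 || x > 1) {
      stop("thresholds must lie in [0,1]")
    }
  }
  if (!all(kept_classes %in% FUNCTIONAL_CLASSES)) {
    stop("kept_classes contains unknown functional classes")
  }
  structure(
    list(maf_threshold = maf_threshold,
         sift_damaging_max = sift_damaging_max,
         polyphen_damaging_min = polyphen_damaging_min,
         kept_classes = kept_classes,
         caller_mode = caller_mode,
         control_ids = as.character(control_ids),
         recurrence_common_min = as.integer(recurrence_common_min)),
    class = "filter_config"
  )
}

#' Read / write a filter configuration as JSON
#'
#' @param path File path.
#' @return For the reader, a [filter_config()]; the writer returns `path`
#'   invisibly.
#' @export
read_filter_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(filter_config, raw)
}

#' @rdname read_filter_config
#' @param config A [filter_config()] object.
#' @export
write_filter_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
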