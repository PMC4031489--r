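#' Classify daughter-carried variants as germline or de novo
#'
#' After paternal subtraction, every variant a daughter carries admits
#' exactly one origin: it is a germline variant inherited from her mother
#' when the mother also carries it, and a de novo event arisen in the
#' daughter when neither parent carries it. Residual father-daughter
#' sharing violates the precondition (the paternal-removal stage must run
#' first) and raises an error rather than becoming a third label.
#'
#' @param callset A merged [cohort_callset()] containing the mother and
#'   the daughters (the father may be absent, e.g. unsequenced).
#' @param ped A [pedigree()].
#' @param mother_id,father_id Parent sample ids (`father_id` may be `NA`).
#' @param daughter_ids Daughters to classify; each must have `mother_id`
#'   as mother in the pedigree.
#' @return A data frame of inheritance records: one row per
#'   (variant, daughter) presence with columns `key`, `daughter_id`,
#'   `label` (`"germline"` or `"de_novo"`).
#' @export
classify_pair <- function(callset, ped, mother_id, father_id,
                          daughter_ids) {
  kids <- ped_member(ped, daughter_ids)
  bad <- is.na(kids$mother_id) | kids$mother_id != mother_id
  if (any(bad)) {
    stop("daughter(s) without mother link to ", mother_id, ": ",
         paste(kids$id[bad], collapse = ", "))
  }
  m <- merged_presence(callset)
  if (!mother_id %in% colnames(m)) {
    stop("mother ", mother_id, " absent from callset")
  }
  records <- list()
  for (d in daughter_ids) {
    if (!d %in% colnames(m)) next
    carried <- rownames(m)[m[, d]]
    if (!is.na(father_id) && father_id %in% colnames(m)) {
      residual <- carried[m[carried, father_id]]
      if (length(residual)) {
        stop("father-shared variant(s) still present in daughter ", d,
             " (run paternal removal first): ",
             paste(residual, collapse = ", "))
      }
    }
    if (!length(carried)) next
    records[[d]] <- data.frame(
      key = carried,
      daughter_id = d,
      label = ifelse(m[carried, mother_id], "germline", "de_novo"),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(records)) do.call(rbind, records) else
    data.frame(key = character(0), daughter_id = character(0),
               label = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarise a mother-daughter pair's inheritance records
#'
#' The pair-level germline count deduplicates across daughters: it is the
#' number of distinct variants present in the mother and in at least one
#' daughter. De novo events are counted per daughter.
#'
#' @param records Records from [classify_pair()] for one pair.
#' @param daughter_ids The pair's daughters (so daughters with zero de
#'   novo events still appear in the result).
#' @return A list with `germline_count` (scalar) and `de_novo_count`
#'   (named integer vector over `daughter_ids`).
#' @export
pair_summary <- function(records, daughter_ids) {
  germline <- unique(records$key[records$label == "germline"])
  dn <- vapply(daughter_ids, function(d) {
    sum(records$daughter_id == d & records$label == "de_novo")
  }, integer(1))
  list(germline_count = length(germline), de_novo_count = dn)
}

#' Recurrence of variants among affected members
#'
#' For every variant in the callset, counts how many affected members
#' carry it (its family frequency) and classes it as `"common"` (carried
#' by at least `recurrence_common_min` affected members) or
#' `"individual"` (a single carrier). Unaffected carriers never enter the
#' frequency.
#'
#' @param callset A merged [cohort_callset()].
#' @param affected_ids Sample ids of the affected members.
#' @param recurrence_common_min Minimum carriers for the common class.
#' @return An object of class `recurrence_summary`: a list with
#'   `per_variant` (data frame `key`, `ref`, `alt`, `frequency`, `class`),
#'   `total_frequency`, `n_common`, `n_individual`.
#' @export
recurrence_summary <- function(callset, affected_ids,
                               recurrence_common_min = 2L) {
  if (!length(affected_ids)) stop("affected_ids must be non-empty")
  m <- merged_presence(callset)
  affected_ids <- intersect(affected_ids, colnames(m))
  freq <- rowSums(m[, affected_ids, drop = FALSE])
  per_variant <- data.frame(
    key = callset$keys$key,
    ref = callset$keys$ref,
    alt = callset$keys$alt,
    frequency = as.integer(freq),
    class = ifelse(freq >= recurrence_common_min, "common", "individual"),
    stringsAsFactors = FALSE
  )
  structure(
    list(per_variant = per_variant,
         total_frequency = sum(per_variant$frequency),
         n_common = sum(per_variant$class == "common"),
         n_individual = sum(per_variant$class == "individual" &
                              per_variant$frequency == 1L)),
    class = "recurrence_summary"
  )
}

#' Sharing of variants among a set of sisters
#'
#' @param callset A merged [cohort_callset()].
#' @param sister_ids Sample ids of the sisters.
#' @return A list with `shared_ge2` (variants present in at least two
#'   sisters) and `exclusive` (named integer vector: variants present in
#'   exactly that sister and no other sister).
#' @export
sister_sharing <- function(callset, sister_ids) {
  m <- merged_presence(callset)
  missing_samples <- setdiff(sister_ids, colnames(m))
  if (length(missing_samples)) {
    stop("sister id(s) absent from callset: ",
         paste(missing_samples, collapse = ", "))
  }
  counts <- rowSums(m[, sister_ids, drop = FALSE])
  exclusive <- vapply(sister_ids, function(s) {
    sum(counts == 1L & m[, s])
  }, integer(1))
  list(shared_ge2 = sum(counts >= 2L), exclusive = exclusive)
}

#' Exact-symbol intersection of two gene sets
#'
#' Symbols are case-folded before comparison; no fuzzy matching is
#' performed, so paralogous family members (e.g. FOXP1 vs FOXA1) never
#' match each other.
#'
#' @param genes_a,genes_b Character vectors of gene symbols.
#' @return The intersection, in `genes_b`'s casing.
#' @export
gene_set_overlap <- function(genes_a, genes_b) {
  genes_b <- unique(genes_b)
  genes_b[toupper(genes_b) %in% toupper(genes_a)]
}
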