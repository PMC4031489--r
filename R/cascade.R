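#' Collapse per-caller presence into a consensus
#'
#' First prioritization stage. Under `"intersection"` a (variant, sample)
#' call survives only when every caller made it — the strict reading of
#' requiring a variant to be called by both engines; `"union"` keeps calls
#' made by any caller. A single-caller callset is returned unchanged (up
#' to merging) under either mode.
#'
#' @param callset A [cohort_callset()] with per-caller presence.
#' @param mode `"intersection"` (default) or `"union"`.
#' @return The callset with `merged` set and per-caller matrices dropped.
#' @export
consensus_callers <- function(callset, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  if (!length(callset$presence)) {
    if (!is.null(callset$merged)) return(callset)
    stop("callset has no caller presence matrices")
  }
  merged <- Reduce(if (mode == "intersection") `&` else `|`,
                   callset$presence)
  callset$merged <- merged
  callset$presence <- list()
  callset$callers <- character(0)
  callset
}

#' Remove variants shared with unaffected controls
#'
#' Second stage: any variant carried by at least one control sample is
#' dropped outright, and so is any variant carried by no affected member.
#' What remains is, by construction, present only in affected members.
#'
#' @param callset A merged [cohort_callset()].
#' @param ped A [pedigree()].
#' @param control_ids Unaffected sample ids to subtract; must be non-empty
#'   and marked unaffected in the pedigree.
#' @return The restricted callset.
#' @export
remove_shared_with_unaffected <- function(callset, ped, control_ids) {
  if (!length(control_ids)) stop("control_ids must be non-empty")
  members <- ped_member(ped, control_ids)
  if (any(members$affected)) {
    stop("control id(s) marked affected in pedigree: ",
         paste(members$id[members$affected], collapse = ", "))
  }
  m <- merged_presence(callset)
  missing_samples <- setdiff(control_ids, colnames(m))
  if (length(missing_samples)) {
    stop("control id(s) absent from callset: ",
         paste(missing_samples, collapse = ", "))
  }
  affected_ids <- intersect(ped$id[ped$affected], colnames(m))
  in_control <- rowSums(m[, control_ids, drop = FALSE]) > 0
  in_affected <- rowSums(m[, affected_ids, drop = FALSE]) > 0
  restrict_callset(callset, rownames(m)[!in_control & in_affected])
}

#' Restrict annotations to the kept functional classes
#'
#' @param anns A `variant_annotation` data frame.
#' @param kept_classes Functional classes to retain (default: everything
#'   but synonymous and unclassified variants).
#' @return The annotation subset.
#' @export
filter_functional_class <- function(anns,
                                    kept_classes = c("nonsynonymous_SNV",
                                                     "splicing", "stopgain",
                                                     "stoploss")) {
  anns[anns$functional_class %in% kept_classes, , drop = FALSE]
}

#' Restrict annotations to rare or novel variants
#'
#' A variant passes when it is absent from every population catalog
#' (novel) or its highest catalogued MAF does not exceed the threshold.
#' Common polymorphisms (MAF above the threshold in any catalog) are
#' removed.
#'
#' @param anns A `variant_annotation` data frame.
#' @param maf_threshold Maximum catalogued MAF (default 0.001).
#' @return The annotation subset.
#' @export
filter_rare <- function(anns, maf_threshold = 0.001) {
  maf <- max_catalog_maf(anns)
  anns[is.na(maf) | maf <= maf_threshold, , drop = FALSE]
}

#' Predict deleteriousness from SIFT and PolyPhen-2 bands
#'
#' Stop gain, stop loss and splicing variants are deleterious
#' unconditionally. A nonsynonymous substitution is deleterious when
#' called damaging by either program: SIFT strictly below
#' `sift_damaging_max` (published band: damaging < 0.05, tolerated >=
#' 0.05) or PolyPhen-2 HumVar at or above `polyphen_damaging_min`
#' (published bands: benign 0-0.446, possibly damaging 0.447-0.908,
#' probably damaging 0.909-1; the cut keeps "possibly damaging" and
#' worse). A nonsynonymous variant with both scores absent is conservatively
#' not deleterious, with a warning.
#'
#' @param anns A `variant_annotation` data frame (vectorized over rows).
#' @param config A [filter_config()] providing the two score cuts.
#' @return Logical vector, one element per annotation row.
#' @export
predict_deleterious <- function(anns, config = filter_config()) {
  cls <- anns$functional_class
  auto <- cls %in% c("stopgain", "stoploss", "splicing")
  sift_hit <- !is.na(anns$sift) & anns$sift < config$sift_damaging_max
  poly_hit <- !is.na(anns$polyphen_hvar) &
    anns$polyphen_hvar >= config$polyphen_damaging_min
  scoreless <- !auto & is.na(anns$sift) & is.na(anns$polyphen_hvar)
  if (any(scoreless)) {
    warning(sum(scoreless), " nonsynonymous variant(s) lack both scores; ",
            "treated as not deleterious")
  }
  auto | (!scoreless & (sift_hit | poly_hit))
}

#' Remove paternally shared variants from daughters
#'
#' For each listed daughter, any variant present in both the father and
#' that daughter is set absent in the daughter (it was transmitted from
#' the father, so it cannot be a maternal germline or daughter de novo
#' event). Presence in samples who are not the father's daughters is
#' untouched. Variants left present in no sample are dropped.
#'
#' @param callset A merged [cohort_callset()].
#' @param ped A [pedigree()].
#' @param father_id Sample id of the father.
#' @param daughter_ids Sample ids of his daughters; each must have
#'   `father_id` as father in the pedigree.
#' @return The edited callset.
#' @export
remove_paternal <- function(callset, ped, father_id, daughter_ids) {
  kids <- ped_member(ped, daughter_ids)
  bad <- is.na(kids$father_id) | kids$father_id != father_id
  if (any(bad)) {
    stop("sample(s) not fathered by ", father_id, ": ",
         paste(kids$id[bad], collapse = ", "))
  }
  m <- merged_presence(callset)
  if (!father_id %in% colnames(m)) {
    return(callset) # father unsequenced: nothing to subtract
  }
  for (d in intersect(daughter_ids, colnames(m))) {
    m[, d] <- m[, d] & !m[, father_id]
  }
  callset$merged <- m
  # a variant now confined to the father alone carries no signal for the
  # family analysis: drop it entirely
  others <- setdiff(colnames(m), father_id)
  restrict_callset(callset,
                   rownames(m)[rowSums(m[, others, drop = FALSE]) > 0])
}

new_audit <- function() {
  structure(
    data.frame(stage = character(0), variants_in = integer(0),
               variants_out = integer(0), stringsAsFactors = FALSE),
    removed = list(), class = c("cascade_audit", "data.frame")
  )
}

audit_add <- function(audit, stage, keys_in, keys_out) {
  removed <- attr(audit, "removed")
  removed[[stage]] <- setdiff(keys_in, keys_out)
  row <- data.frame(stage = stage, variants_in = length(keys_in),
                    variants_out = length(keys_out),
                    stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(audit), row)
  attr(out, "removed") <- removed
  class(out) <- c("cascade_audit", "data.frame")
  out
}

#' Run the full prioritization cascade
#'
#' Composes the stages in published order: (1) caller consensus;
#' (2) subtraction of variants shared with unaffected controls (and of
#' variants carried by no affected member); (3) functional-class filter;
#' (4) rare-MAF filter; (5) deleteriousness prediction by the SIFT /
#' PolyPhen-2 OR-rule; (6) removal of paternally transmitted variants from
#' each father's daughters; optionally (7) restriction to
#' Sanger-confirmed variants. Every stage is a restriction, so the
#' surviving set shrinks monotonically, and an audit records each stage's
#' in/out counts and removed keys.
#'
#' Stages 3-5 need annotations; a callset variant missing from `anns`
#' raises an error under `strict = TRUE` (default) and is dropped with a
#' warning otherwise.
#'
#' @param callset A [cohort_callset()] (per-caller or already merged).
#' @param anns A `variant_annotation` data frame.
#' @param ped A [pedigree()].
#' @param config A [filter_config()]; `control_ids` must be set.
#' @param confirm_sanger If `TRUE`, apply the final confirmation filter on
#'   the `sanger_confirmed` annotation flag (never computed, only consumed).
#' @param strict Error (rather than warn) on unannotated variants.
#' @return A list with `callset` (the surviving merged callset), `anns`
#'   (annotations of the survivors) and `audit` (a `cascade_audit` data
#'   frame with a `removed` attribute listing dropped keys per stage).
#' @export
run_cascade <- function(callset, anns, ped, config = filter_config(),
                        confirm_sanger = FALSE, strict = TRUE) {
  audit <- new_audit()

  keys0 <- callset$keys$key
  cs <- consensus_callers(callset, config$caller_mode)
  cs <- drop_absent_variants(cs)
  audit <- audit_add(audit, "caller_consensus", keys0, cs$keys$key)

  keys1 <- cs$keys$key
  cs <- remove_shared_with_unaffected(cs, ped, config$control_ids)
  audit <- audit_add(audit, "unaffected_subtraction", keys1, cs$keys$key)

  unannotated <- setdiff(cs$keys$key, anns$key)
  if (length(unannotated)) {
    msg <- paste0(length(unannotated), " callset variant(s) missing from ",
                  "the annotation table")
    if (strict) stop(msg) else {
      warning(msg, "; dropped")
      cs <- restrict_callset(cs, anns$key)
    }
  }
  ann_sub <- anns[anns$key %in% cs$keys$key, , drop = FALSE]

  keys2 <- cs$keys$key
  ann_sub <- filter_functional_class(ann_sub, config$kept_classes)
  cs <- restrict_callset(cs, ann_sub$key)
  audit <- audit_add(audit, "functional_class", keys2, cs$keys$key)

  keys3 <- cs$keys$key
  ann_sub <- filter_rare(ann_sub, config$maf_threshold)
  cs <- restrict_callset(cs, ann_sub$key)
  audit <- audit_add(audit, "rare_maf", keys3, cs$keys$key)

  keys4 <- cs$keys$key
  ann_sub <- ann_sub[predict_deleterious(ann_sub, config), , drop = FALSE]
  cs <- restrict_callset(cs, ann_sub$key)
  audit <- audit_add(audit, "deleterious", keys4, cs$keys$key)

  keys5 <- cs$keys$key
  fathers <- ped$id[ped$sex == "male" &
                      ped$id %in% unique(stats::na.omit(ped$father_id))]
  for (f in intersect(fathers, cs$samples)) {
    kids <- daughters_of(ped, f)
    kids <- intersect(kids, cs$samples)
    if (length(kids)) cs <- remove_paternal(cs, ped, f, kids)
  }
  audit <- audit_add(audit, "paternal_removal", keys5, cs$keys$key)

  if (confirm_sanger) {
    keys6 <- cs$keys$key
    confirmed <- ann_sub$key[!is.na(ann_sub$sanger_confirmed) &
                               ann_sub$sanger_confirmed]
    cs <- restrict_callset(cs, confirmed)
    audit <- audit_add(audit, "sanger_confirmation", keys6, cs$keys$key)
  }

  ann_sub <- ann_sub[ann_sub$key %in% cs$keys$key, , drop = FALSE]
  rownames(ann_sub) <- NULL
  list(callset = cs, anns = ann_sub, audit = audit)
}

#' Write a cascade audit as a line-oriented log
#'
#' @param audit The `audit` element of a [run_cascade()] result.
#' @param path Output path; `""` prints to the console.
#' @return The log lines, invisibly.
#' @export
write_audit_log <- function(audit, path = "") {
  lines <- sprintf("%-24s in=%-6d out=%-6d removed=%d",
                   audit$stage, audit$variants_in, audit$variants_out,
                   audit$variants_in - audit$variants_out)
  if (nzchar(path)) writeLines(lines, path) else writeLines(lines)
  invisible(lines)
}
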