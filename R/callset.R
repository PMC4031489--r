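#' Construct a cohort callset
#'
#' A cohort callset is the variant x sample x caller presence structure all
#' filters restrict. Genotypes collapse to presence/absence on entry:
#' zygosity and phasing are deliberately discarded, so a hemizygous male
#' chrX call and a heterozygous call are both simply "present". Per-caller
#' presence matrices coexist until [consensus_callers()] collapses them
#' into a single merged matrix.
#'
#' @param keys Data frame of variant keys as from [normalize_key()].
#' @param samples Ordered character vector of sample ids.
#' @param presence Named list (one element per caller) of logical matrices,
#'   rows = `keys$key`, columns = `samples`. Alternatively a single logical
#'   matrix, interpreted as the already-merged presence.
#' @param callers Caller names; defaults to `names(presence)`.
#' @return An object of class `cohort_callset` with elements `keys`,
#'   `samples`, `callers`, `presence` (list of matrices) and `merged`
#'   (matrix or `NULL` before consensus).
#' @export
cohort_callset <- function(keys, samples, presence, callers = NULL) {
  samples <- as.character(samples)
  if (is.matrix(presence)) {
    merged <- fix_dimnames(presence, keys$key, samples)
    cs <- structure(
      list(keys = keys, samples = samples, callers = character(0),
           presence = list(), merged = merged),
      class = "cohort_callset"
    )
    return(cs)
  }
  if (is.null(callers)) callers <- names(presence)
  if (is.null(callers) || any(!nzchar(callers))) {
    stop("presence list must be named by caller")
  }
  presence <- lapply(presence, fix_dimnames, keys = keys$key,
                     samples = samples)
  names(presence) <- callers
  structure(
    list(keys = keys, samples = samples, callers = callers,
         presence = presence, merged = NULL),
    class = "cohort_callset"
  )
}

fix_dimnames <- function(m, keys, samples) {
  stopifnot(is.logical(m), nrow(m) == length(keys),
            ncol(m) == length(samples))
  dimnames(m) <- list(keys, samples)
  m
}

#' @export
print.cohort_callset <- function(x, ...) {
  cat("<cohort_callset> ", nrow(x$keys), " variants x ",
      length(x$samples), " samples", sep = "")
  if (length(x$callers)) {
    cat("; callers: ", paste(x$callers, collapse = ", "), sep = "")
  }
  cat(if (is.null(x$merged)) "; not merged\n" else "; merged\n")
  invisible(x)
}

#' Merged presence matrix of a callset
#'
#' Returns the variant x sample presence matrix after caller consensus.
#' For convenience a single-caller callset that has not been through
#' [consensus_callers()] returns its only caller's matrix.
#'
#' @param callset A [cohort_callset()].
#' @return Logical matrix, rows = variant keys, columns = samples.
#' @export
merged_presence <- function(callset) {
  if (!is.null(callset$merged)) return(callset$merged)
  if (length(callset$presence) == 1L) return(callset$presence[[1L]])
  stop("callset has multiple callers and no merged presence; ",
       "run consensus_callers() first")
}

#' Restrict a callset to a subset of variant keys
#'
#' Restriction never adds entries; keys absent from the callset are ignored.
#'
#' @param callset A [cohort_callset()].
#' @param keep Character vector of variant key strings to retain.
#' @return The restricted callset.
#' @export
restrict_callset <- function(callset, keep) {
  sel <- callset$keys$key %in% keep
  callset$keys <- callset$keys[sel, , drop = FALSE]
  rownames(callset$keys) <- NULL
  callset$presence <- lapply(callset$presence,
                             function(m) m[sel, , drop = FALSE])
  if (!is.null(callset$merged)) {
    callset$merged <- callset$merged[sel, , drop = FALSE]
  }
  callset
}

#' Drop variants present in no sample
#'
#' @param callset A merged [cohort_callset()].
#' @return The pruned callset.
#' @export
drop_absent_variants <- function(callset) {
  m <- merged_presence(callset)
  restrict_callset(callset, rownames(m)[rowSums(m) > 0])
}

#' Read per-caller VCFs into a cohort callset
#'
#' Builds the presence structure from VCF v4.x files, one (possibly
#' multi-sample) file per caller, or one file per (sample, caller) pair.
#' A sample is "present" for a variant under a caller iff its genotype
#' carries at least one copy of that alternate allele; multi-allelic
#' records are split into one key per alternate allele, and a genotype
#' contributes presence only to the alternate allele(s) it actually
#' carries. Records lacking a GT entry are skipped with a warning and
#' counted in the audit log attached to the result
#' (`attr(x, "audit_log")`).
#'
#' @param files Either a named character vector of VCF paths (names are
#'   caller names; each file may be multi-sample), or a data frame with
#'   columns `file`, `caller` and optionally `sample` (for single-sample
#'   files whose VCF sample column should be renamed).
#' @param genome Genome label passed to the VCF reader (metadata only).
#' @return A [cohort_callset()] whose samples are the union of VCF samples
#'   in first-seen order.
#' @export
read_cohort_vcf <- function(files, genome = "hg19") {
  if (is.data.frame(files)) {
    manifest <- files
    if (!all(c("file", "caller") %in% names(manifest))) {
      stop("manifest must have columns 'file' and 'caller'")
    }
    if (is.null(manifest$sample)) manifest$sample <- NA_character_
  } else {
    if (is.null(names(files)) || any(!nzchar(names(files)))) {
      stop("files vector must be named by caller")
    }
    manifest <- data.frame(file = unname(files), caller = names(files),
                           sample = NA_character_,
                           stringsAsFactors = FALSE)
  }

  skipped <- 0L
  entries <- list() # per manifest row: data.frame(key, sample)
  keyrows <- list()
  for (i in seq_len(nrow(manifest))) {
    vcf <- tryCatch(
      VariantAnnotation::readVcf(manifest$file[i], genome = genome),
      error = function(e) {
        stop("failed to parse VCF '", manifest$file[i], "': ",
             conditionMessage(e))
      }
    )
    vcf_samples <- colnames(vcf)
    if (!is.na(manifest$sample[i])) {
      if (length(vcf_samples) != 1L) {
        stop("manifest assigns a sample name to multi-sample VCF '",
             manifest$file[i], "'")
      }
      vcf_samples <- manifest$sample[i]
    }
    if (nrow(vcf) == 0L) {
      entries[[i]] <- data.frame(key = character(0), sample = character(0),
                                 caller = character(0),
                                 stringsAsFactors = FALSE)
      next
    }
    if (!"GT" %in% rownames(VariantAnnotation::geno(
          VariantAnnotation::header(vcf)))) {
      warning("VCF '", manifest$file[i], "' has no GT field; ",
              nrow(vcf), " records skipped")
      skipped <- skipped + nrow(vcf)
      entries[[i]] <- data.frame(key = character(0), sample = character(0),
                                 caller = character(0),
                                 stringsAsFactors = FALSE)
      next
    }
    rr <- SummarizedExperiment::rowRanges(vcf)
    gt <- VariantAnnotation::geno(vcf)$GT
    chrom <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    ref <- as.character(rr$REF)
    alts <- VariantAnnotation::alt(vcf) # DNAStringSetList

    rec <- list()
    for (r in seq_len(nrow(vcf))) {
      gtr <- gt[r, , drop = TRUE]
      if (all(is.na(gtr) | gtr %in% c(".", "./.", ".|."))) {
        if (all(is.na(gtr) | gtr == "")) {
          skipped <- skipped + 1L
          next
        }
      }
      alt_r <- as.character(alts[[r]])
      tokens <- strsplit(gtr, "[/|]")
      for (j in seq_along(alt_r)) {
        kj <- normalize_key(chrom[r], pos[r], ref[r], alt_r[j])
        carried <- vapply(tokens, function(tk) any(tk == as.character(j)),
                          logical(1))
        carried[is.na(carried)] <- FALSE
        if (any(carried)) {
          rec[[length(rec) + 1L]] <- data.frame(
            key = kj$key, sample = vcf_samples[carried],
            caller = manifest$caller[i], stringsAsFactors = FALSE
          )
          keyrows[[kj$key]] <- kj
        }
      }
    }
    entries[[i]] <- if (length(rec)) do.call(rbind, rec) else
      data.frame(key = character(0), sample = character(0),
                 caller = character(0), stringsAsFactors = FALSE)
    if (is.na(manifest$sample[i])) {
      manifest$sample[i] <- paste(vcf_samples, collapse = ",")
    }
  }

  long <- do.call(rbind, entries)
  samples <- unique(unlist(strsplit(manifest$sample, ",")))
  samples <- samples[!is.na(samples) & nzchar(samples)]
  callers <- unique(manifest$caller)
  keys <- if (length(keyrows)) do.call(rbind, unname(keyrows)) else
    normalize_key(character(0), integer(0), character(0), character(0))
  keys <- keys[order(keys$chrom, keys$pos, keys$ref, keys$alt), ,
               drop = FALSE]
  rownames(keys) <- NULL

  presence <- lapply(callers, function(cl) {
    m <- matrix(FALSE, nrow(keys), length(samples),
                dimnames = list(keys$key, samples))
    sub <- long[long$caller == cl, , drop = FALSE]
    if (nrow(sub)) m[cbind(sub$key, sub$sample)] <- TRUE
    m
  })
  names(presence) <- callers
  out <- cohort_callset(keys, samples, presence)
  attr(out, "audit_log") <- c(
    sprintf("files read: %d", nrow(manifest)),
    sprintf("records skipped (missing GT): %d", skipped)
  )
  out
}

#' Write a cohort callset as per-caller multi-sample VCFs
#'
#' Emits one VCF v4.2 file per caller (or a single `merged.vcf` for a
#' merged callset), with presence encoded as genotype `0/1` and absence as
#' `0/0`. Together with [read_cohort_vcf()] this round-trips the presence
#' structure exactly.
#'
#' @param callset A [cohort_callset()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of written file paths (by caller).
#' @export
write_callset_vcf <- function(callset, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mats <- if (is.null(callset$merged)) callset$presence else
    list(merged = callset$merged)
  keys <- callset$keys
  ord <- order(keys$chrom, keys$pos, keys$ref, keys$alt)
  out <- vapply(names(mats), function(cl) {
    m <- mats[[cl]][ord, , drop = FALSE]
    k <- keys[ord, , drop = FALSE]
    path <- file.path(dir, paste0(prefix, "_", cl, ".vcf"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "##fileformat=VCFv4.2",
      "##source=famvar",
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", callset$samples), collapse = "\t")
    ), con)
    if (nrow(k)) {
      gts <- matrix(ifelse(m, "0/1", "0/0"), nrow = nrow(m))
      body <- paste(
        k$chrom, k$pos, ".", k$ref, k$alt, ".", "PASS", ".", "GT",
        apply(gts, 1L, paste, collapse = "\t"),
        sep = "\t"
      )
      writeLines(body, con)
    }
    path
  }, character(1))
  out
}
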