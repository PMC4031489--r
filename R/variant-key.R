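#' Normalize a variant site into the canonical key dialect
#'
#' A variant key identifies one substitution site by chromosome, 1-based
#' position, reference allele and alternate allele. Keys are the identity
#' used by every set operation in the package: annotation joins, filter
#' restrictions and inheritance records all match on the key string, never
#' on gene or transcript annotation, so that annotation-version drift can
#' never change set logic.
#'
#' Normalization applies the canonical chromosome dialect (a `chr` prefix,
#' added when missing) and upper-cases both alleles. The function is
#' vectorized and idempotent: normalizing an already-normalized key is a
#' no-op.
#'
#' @param chrom Chromosome labels, with or without a `chr` prefix.
#' @param pos 1-based positions (integer, >= 1).
#' @param ref,alt Allele strings over A/C/G/T (multi-base strings allowed
#'   for indel pass-through; no left-alignment is performed).
#' @return A data frame with columns `key` (the canonical
#'   `chrom:pos:ref:alt` string), `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' normalize_key("5", 139936828, "c", "t")
#' normalize_key("chrX", 119680410, "A", "T")
#' @export
normalize_key <- function(chrom, pos, ref, alt) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(pos, n)
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)
  if (any(is.na(pos)) || any(pos < 1) || any(pos != trunc(pos))) {
    stop("variant position must be a positive integer (1-based)")
  }
  pos <- as.integer(pos)
  if (any(!nzchar(ref)) || any(!nzchar(alt))) {
    stop("alleles must be non-empty")
  }
  bad <- grepl("[^ACGT]", ref) | grepl("[^ACGT]", alt)
  if (any(bad)) {
    stop(
      "invalid allele characters (non-ACGT) in: ",
      paste(unique(paste0(ref[bad], ">", alt[bad])), collapse = ", ")
    )
  }
  if (any(ref == alt)) {
    stop("invalid variant: ref and alt alleles are identical")
  }
  chrom <- ifelse(grepl("^chr", chrom, ignore.case = TRUE),
    sub("^chr", "chr", chrom, ignore.case = TRUE),
    paste0("chr", chrom)
  )
  data.frame(
    key = paste(chrom, pos, ref, alt, sep = ":"),
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    stringsAsFactors = FALSE
  )
}

#' Split canonical key strings back into their fields
#'
#' @param key Character vector of `chrom:pos:ref:alt` key strings as
#'   produced by [normalize_key()].
#' @return A data frame with columns `key`, `chrom`, `pos`, `ref`, `alt`.
#' @export
parse_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) {
    stop("malformed variant key: ", paste(key[bad], collapse = ", "))
  }
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  normalize_key(m[, 1L], as.integer(m[, 2L]), m[, 3L], m[, 4L])
}
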