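#' Read a presence matrix TSV into a cohort callset
#'
#' The presence TSV has columns `gene`, `chrom`, `pos`, `ref`, `alt` and
#' one 0/1 column per sample named `S<id>`. Each sample's column is
#' replicated across the given callers (the matrix encodes consensus
#' presence, so both pseudo-callers agree).
#'
#' @param path Path to the TSV.
#' @param callers Caller names to replicate the matrix under.
#' @return A [cohort_callset()]; the `gene` column is kept in its `keys`.
#' @export
read_presence_tsv <- function(path, callers = c("varscan", "gatk")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  keys <- normalize_key(tab$chrom, tab$pos, tab$ref, tab$alt)
  keys$gene <- tab$gene
  sample_cols <- grep("^S", names(tab), value = TRUE)
  samples <- sub("^S", "", sample_cols)
  m <- as.matrix(tab[, sample_cols, drop = FALSE]) == 1
  dimnames(m) <- list(keys$key, samples)
  presence <- stats::setNames(rep(list(m), length(callers)), callers)
  cohort_callset(keys, samples, presence)
}

#' Load the bundled two-generation family fixture
#'
#' The fixture encodes a published BRCA1+ breast-cancer family of ten
#' members (six affected and two unaffected sequenced members across two
#' generations, plus two fathers used for paternal subtraction) and its
#' 23 prioritized deleterious mutations, together with six synthetic
#' background variants that exercise every cascade stage and the
#' fragile-site / structural-variation / repeat interval tracks. The
#' full-family presence matrix is reconstructed from the printed sharing
#' tables and per-variant family frequencies; where those tables disagree
#' the frequency column wins (see the package vignette).
#'
#' @return A list with elements `ped` ([pedigree()]), `anns` (annotation
#'   table), `callset` (full-family [cohort_callset()], two identical
#'   pseudo-callers), `pair_callset` (mother/father/daughter matrices for
#'   the two generation pairs), `tracks` (named list of
#'   [interval_track()]: `fragile_sites`, `structural_variation`,
#'   `repeats`), and `config` (the fixture's [filter_config()], with
#'   member 3 as the unaffected control).
#' @export
family_fixture <- function() {
  path <- function(f) system.file("extdata", f, package = "famvar",
                                  mustWork = TRUE)
  list(
    ped = parse_pedigree(path("family.ped")),
    anns = read_annotation_table(path("family_annotations.tsv")),
    callset = read_presence_tsv(path("family_presence_synthetic.tsv")),
    pair_callset = read_presence_tsv(path("pair_presence_synthetic.tsv")),
    tracks = list(
      fragile_sites = read_interval_track(path("fragile_sites.bed"),
                                          "fragile_sites"),
      structural_variation = read_interval_track(
        path("structural_variation_synthetic.bed"), "structural_variation"),
      repeats = read_interval_track(path("repeats_synthetic.bed"),
                                    "repeats")
    ),
    config = read_filter_config(path("family_config.json"))
  )
}
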