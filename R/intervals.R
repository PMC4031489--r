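#' Construct a genomic interval track
#'
#' Interval tracks carry named genomic regions (chromosomal fragile sites,
#' structural-variation regions, repeat regions) used for variant-context
#' annotation. Internally intervals are 1-based and closed on both ends,
#' matching how positions are printed in the annotation tables; BED I/O
#' converts at the boundary.
#'
#' @param name Track label, e.g. `"fragile_sites"`.
#' @param chrom,start,end Interval coordinates (1-based, closed).
#' @param label Per-interval label (e.g. the fragile-site name).
#' @return An object of class `interval_track`: a list with `name` and an
#'   `intervals` data frame.
#' @export
interval_track <- function(name, chrom = character(0),
                           start = integer(0), end = integer(0),
                           label = character(0)) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start > end)) {
    stop("interval with start > end in track '", name, "'")
  }
  chrom <- ifelse(grepl("^chr", chrom, ignore.case = TRUE),
                  sub("^chr", "chr", chrom, ignore.case = TRUE),
                  paste0("chr", chrom))
  if (!length(label)) label <- rep(NA_character_, length(chrom))
  structure(
    list(name = name,
         intervals = data.frame(chrom = chrom, start = start, end = end,
                                label = as.character(label),
                                stringsAsFactors = FALSE)),
    class = "interval_track"
  )
}

#' Read an interval track from a BED file
#'
#' BED is 0-based, half-open; intervals are converted to the internal
#' 1-based closed convention (`start + 1`, `end`). The optional fourth
#' column becomes the interval label.
#'
#' @param path Path to a BED file (3+ columns).
#' @param name Track label for the result.
#' @return An [interval_track()].
#' @export
read_interval_track <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) {
      stop("failed to parse BED '", path, "': ", conditionMessage(e))
    }
  )
  # rtracklayer already converts BED to 1-based closed coordinates
  label <- if (!is.null(gr$name)) as.character(gr$name) else
    rep(NA_character_, length(gr))
  interval_track(
    name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    label = label
  )
}

#' Write an interval track to a BED file
#'
#' Inverse of [read_interval_track()]: internal 1-based closed intervals
#' are emitted as 0-based half-open BED lines.
#'
#' @param track An [interval_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interval_track <- function(track, path) {
  iv <- track$intervals
  out <- data.frame(chrom = iv$chrom, start = iv$start - 1L, end = iv$end,
                    stringsAsFactors = FALSE)
  if (any(!is.na(iv$label))) {
    out$label <- ifelse(is.na(iv$label), ".", iv$label)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

track_granges <- function(track) {
  iv <- track$intervals
  GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start, iv$end),
                         label = iv$label)
}

#' Annotate variants with genomic-context track membership
#'
#' Point-in-interval membership under the internal 1-based closed
#' convention: a position equal to either interval bound is inside. For
#' each track the result gains a column named after the track holding the
#' label of the first covering interval (`NA` when the position is covered
#' by none), plus an `in_<track>` logical column.
#'
#' @param keys Data frame of variant keys (from [normalize_key()] or a
#'   callset's `keys`).
#' @param tracks A list of [interval_track()] objects (or a single one).
#' @return A data frame with one row per variant and the per-track columns
#'   described above; the per-track hit counts are attached as
#'   `attr(x, "summary")`.
#' @export
annotate_context <- function(keys, tracks) {
  if (inherits(tracks, "interval_track")) tracks <- list(tracks)
  out <- keys[, c("key", "chrom", "pos"), drop = FALSE]
  pts <- GenomicRanges::GRanges(keys$chrom,
                                IRanges::IRanges(keys$pos, keys$pos))
  summary <- integer(0)
  for (track in tracks) {
    hits <- GenomicRanges::findOverlaps(pts, track_granges(track),
                                        select = "first")
    lab <- track$intervals$label[hits]
    out[[track$name]] <- lab
    out[[paste0("in_", track$name)]] <- !is.na(hits)
    summary[track$name] <- sum(!is.na(hits))
  }
  attr(out, "summary") <- summary
  out
}
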