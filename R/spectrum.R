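#' Classify a single-nucleotide substitution as transition or transversion
#'
#' Transitions exchange purines (A<->G) or pyrimidines (C<->T);
#' transversions cross the two classes. Of the 12 possible substitutions,
#' 4 are transitions and 8 are transversions. The classification is
#' strand-symmetric: a substitution and its reverse complement fall in the
#' same class.
#'
#' @param ref,alt Single-base allele vectors.
#' @return Character vector: `"transition"` or `"transversion"`.
#' @export
classify_titv <- function(ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  if (any(nchar(ref) != 1L | nchar(alt) != 1L)) {
    stop("Ti/Tv classification applies to single-nucleotide variants only")
  }
  if (any(!ref %in% c("A", "C", "G", "T")) ||
      any(!alt %in% c("A", "C", "G", "T"))) {
    stop("alleles must be A, C, G or T")
  }
  if (any(ref == alt)) stop("ref and alt are identical")
  purine <- c("A", "G")
  ifelse((ref %in% purine) == (alt %in% purine),
         "transition", "transversion")
}

# half-up decimal rounding (base round() is half-even)
round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Recurrence-stratified transition/transversion table
#'
#' Counts transitions and transversions over all variants (`total`
#' stratum) and within the `common` and `individual` recurrence strata,
#' with the Ti/Tv ratio rounded half-up to one decimal. The ratio is `NA`
#' when the stratum has no transversions (or is empty); the raw counts are
#' always reported alongside.
#'
#' @param recurrence A [recurrence_summary()] (its `per_variant` element
#'   carries `ref`, `alt` and the recurrence `class` per variant).
#' @return An object of class `titv_table`: a data frame with columns
#'   `stratum`, `ti`, `tv`, `ratio`.
#' @export
titv_stratified <- function(recurrence) {
  pv <- recurrence$per_variant
  cls <- classify_titv(pv$ref, pv$alt)
  strata <- list(total = rep(TRUE, nrow(pv)),
                 common = pv$class == "common",
                 individual = pv$class == "individual")
  rows <- lapply(names(strata), function(s) {
    sel <- strata[[s]]
    ti <- sum(cls[sel] == "transition")
    tv <- sum(cls[sel] == "transversion")
    data.frame(stratum = s, ti = ti, tv = tv,
               ratio = if (tv > 0) round_half_up(ti / tv, 1L) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("titv_table", "data.frame")
  out
}

#' Exact test for a 2x2 contingency table by hypergeometric enumeration
#'
#' Enumerates every 2x2 table with the observed margins, computing each
#' table's point probability from the hypergeometric distribution in log
#' space (no normal approximation). The two-sided p-value follows the
#' point-probability definition: the sum of probabilities of all tables
#' whose point probability does not exceed that of the observed table
#' (with a small relative tolerance against floating-point ties). The
#' one-sided p-value is the upper tail on cell `a`. Both are reported so
#' either convention can be inspected.
#'
#' @param a,b,c,d The four cell counts, row-wise:
#'   `rbind(c(a, b), c(c, d))`.
#' @return An object of class `fisher_result`: a list with `p_two_sided`,
#'   `p_one_sided_greater`, `point_prob` (probability of the observed
#'   table) and `table`.
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != trunc(cells))) {
    stop("cell counts must be non-negative integers")
  }
  n <- a + b + c + d
  if (n < 1) stop("table total must be at least 1")
  r1 <- a + b
  c1 <- a + c
  # support of cell a given fixed margins
  lo <- max(0L, c1 - (n - r1))
  hi <- min(r1, c1)
  support <- lo:hi
  logp <- lchoose(r1, support) + lchoose(n - r1, c1 - support) -
    lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[support == a]
  tol <- 1 + 1e-7
  list_out <- structure(
    list(
      p_two_sided = min(1, sum(p[p <= p_obs * tol])),
      p_one_sided_greater = min(1, sum(p[support >= a])),
      point_prob = p_obs,
      table = matrix(cells, 2L, 2L, byrow = TRUE,
                     dimnames = list(NULL, NULL))
    ),
    class = "fisher_result"
  )
  list_out
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("2x2 exact test (hypergeometric enumeration)\n")
  print(x$table)
  cat(sprintf("p (two-sided, point-probability) = %.6g\n", x$p_two_sided))
  cat(sprintf("p (one-sided, upper tail on [1,1]) = %.6g\n",
              x$p_one_sided_greater))
  invisible(x)
}
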