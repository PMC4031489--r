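with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default two-generation simulation pedigree
#'
#' Mirrors the structure the analysis assumes: four sisters in the founder
#' generation (three affected, one unaffected), two marry-in unaffected
#' fathers, and a second generation of three affected daughters and one
#' unaffected son.
#'
#' @return A [pedigree()] of ten members with ids `"1"`-`"10"`.
#' @export
default_sim_pedigree <- function() {
  pedigree(
    id = as.character(1:10),
    sex = c("female", "female", "female", "female", "female", "female",
            "female", "male", "male", "male"),
    father_id = c(NA, NA, NA, NA, "9", "9", "10", "10", NA, NA),
    mother_id = c(NA, NA, NA, NA, "2", "2", "4", "4", NA, NA),
    affected = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE,
                 FALSE, FALSE),
    carrier = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE,
                FALSE, FALSE)
  )
}

#' Simulation configuration
#'
#' States the world the simulator generates: a two-generation family with
#' rare deleterious variants seeded in the affected founders and
#' transmitted Mendelianly, per-child de novo mutations, and a common
#' polymorphism background drawn from Hardy-Weinberg proportions at
#' uniform catalog MAFs. Annotation scores are spiked so that
#' truth-deleterious variants satisfy the SIFT/PolyPhen OR-rule and
#' background variants fail it.
#'
#' @param ped Simulation [pedigree()]; default [default_sim_pedigree()].
#' @param n_founder_rare_deleterious Number of rare deleterious variants
#'   seeded (heterozygous) in affected-lineage founders.
#' @param founder_carrier_ids Founders eligible to carry seeded variants;
#'   default: affected members without parents in the pedigree.
#' @param denovo_mean Poisson mean of de novo variants per child (members
#'   with at least one parent in the pedigree). The default of 3 is of
#'   the order observed in a BRCA1+ family (nine de novo events across
#'   three sequenced daughters); no population-scale realism is claimed.
#' @param n_common_background Number of common background polymorphisms.
#' @param background_maf_range MAF range for the background (uniform).
#' @param transmission_prob Probability a heterozygous parent transmits a
#'   variant per meiosis (0.5 = Mendelian).
#' @param dropout_rate Per-call false-negative probability applied to
#'   every emitted call (both callers alike).
#' @param caller_fn_rates Named per-caller additional false-negative
#'   rates; the names define the pseudo-callers emitted.
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(ped = default_sim_pedigree(),
                       n_founder_rare_deleterious = 10L,
                       founder_carrier_ids = NULL,
                       denovo_mean = 3,
                       n_common_background = 50L,
                       background_maf_range = c(0.01, 0.5),
                       transmission_prob = 0.5,
                       dropout_rate = 0,
                       caller_fn_rates = c(varscan = 0, gatk = 0),
                       seed = 1L) {
  if (is.null(founder_carrier_ids)) {
    founder_carrier_ids <- ped$id[ped$affected & is.na(ped$father_id) &
                                    is.na(ped$mother_id)]
  }
  if (!length(founder_carrier_ids)) {
    stop("no eligible founder carriers in pedigree")
  }
  probs <- c(transmission_prob, dropout_rate, caller_fn_rates)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (diff(background_maf_range) < 0 ||
      any(background_maf_range < 0 | background_maf_range > 1)) {
    stop("background_maf_range must be an increasing range within [0,1]")
  }
  structure(
    list(ped = ped,
         n_founder_rare_deleterious = as.integer(n_founder_rare_deleterious),
         founder_carrier_ids = as.character(founder_carrier_ids),
         denovo_mean = denovo_mean,
         n_common_background = as.integer(n_common_background),
         background_maf_range = background_maf_range,
         transmission_prob = transmission_prob,
         dropout_rate = dropout_rate,
         caller_fn_rates = caller_fn_rates,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Transmit a variant from parents to a child
#'
#' Each parent independently transmits one allele: a heterozygous parent
#' (one copy) transmits with probability `transmission_prob`, a homozygous
#' parent (two copies) always transmits, a non-carrier never does. Draws
#' come from the ambient R random number stream.
#'
#' @param mother_count,father_count Parental allele counts (0, 1 or 2);
#'   vectorized.
#' @param transmission_prob Per-heterozygous-parent transmission
#'   probability (default Mendelian 0.5).
#' @return Integer vector of child allele counts in 0..2.
#' @export
mendelian_transmit <- function(mother_count, father_count,
                               transmission_prob = 0.5) {
  n <- max(length(mother_count), length(father_count))
  mc <- rep_len(as.integer(mother_count), n)
  fc <- rep_len(as.integer(father_count), n)
  if (any(c(mc, fc) < 0 | c(mc, fc) > 2)) {
    stop("parental allele counts must be 0, 1 or 2")
  }
  p_of <- function(cnt) c(0, transmission_prob, 1)[cnt + 1L]
  from_mother <- stats::rbinom(n, 1L, p_of(mc))
  from_father <- stats::rbinom(n, 1L, p_of(fc))
  as.integer(from_mother + from_father)
}

random_keys <- function(n, used = character(0)) {
  bases <- c("A", "C", "G", "T")
  if (n == 0L) {
    return(normalize_key(character(0), integer(0), character(0),
                         character(0)))
  }
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
    pos <- sample.int(1e8L, n, replace = TRUE)
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                  character(1))
    cand <- normalize_key(chrom, pos, ref, alt)
    cand <- cand[!duplicated(cand$key) & !(cand$key %in% used), ,
                 drop = FALSE]
    out <- if (is.null(out)) cand else rbind(out, cand)
    out <- out[!duplicated(out$key), , drop = FALSE]
  }
  out <- out[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

topo_children <- function(ped) {
  done <- ped$id[is.na(ped$father_id) & is.na(ped$mother_id)]
  order <- character(0)
  remaining <- setdiff(ped$id, done)
  while (length(remaining)) {
    ready <- vapply(remaining, function(m) {
      row <- ped[ped$id == m, ]
      ok <- function(p) is.na(p) || p %in% done
      ok(row$father_id) && ok(row$mother_id)
    }, logical(1))
    order <- c(order, remaining[ready])
    done <- c(done, remaining[ready])
    remaining <- remaining[!ready]
  }
  order
}

#' Simulate a family variant dataset with known truth
#'
#' Generates allele counts for every pedigree member at three classes of
#' variant sites — founder rare deleterious variants (heterozygous in one
#' designated affected founder, then Mendelianly transmitted), de novo
#' variants (one carrier each, drawn per child), and common background
#' polymorphisms (founder genotypes from Hardy-Weinberg at the configured
#' MAF, then transmitted) — and emits the matching annotation table and
#' per-caller presence. The same seed always produces identical output.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, per-caller
#'   multi-sample VCFs, a PED file, the annotation TSV and a truth TSV are
#'   written there.
#' @return A list with `callset` (per-caller [cohort_callset()]), `anns`
#'   (annotation data frame), `ped`, `truth` (data frame: `key`,
#'   `origin`, `origin_individual`, `deleterious`, `carriers` as a
#'   comma-joined id string), `genotypes` (allele-count matrix), and
#'   `files` (paths, when `dir` was given).
#' @export
simulate_family <- function(config = sim_config(), dir = NULL) {
  with_seed(config$seed, {
    ped <- config$ped
    members <- ped$id
    kids <- topo_children(ped)

    n_founder <- config$n_founder_rare_deleterious
    n_bg <- config$n_common_background
    n_dn <- stats::rpois(length(kids), config$denovo_mean)

    keys_f <- random_keys(n_founder)
    keys_d <- random_keys(sum(n_dn), used = keys_f$key)
    keys_b <- random_keys(n_bg, used = c(keys_f$key, keys_d$key))
    keys <- rbind(keys_f, keys_d, keys_b)
    origin <- c(rep("founder_germline", n_founder),
                rep("de_novo", sum(n_dn)),
                rep("common_background", n_bg))
    origin_individual <- rep(NA_character_, nrow(keys))

    geno <- matrix(0L, nrow(keys), length(members),
                   dimnames = list(keys$key, members))

    # founder rare deleterious: one heterozygous designated founder each
    if (n_founder > 0) {
      seeded <- sample(config$founder_carrier_ids, n_founder, replace = TRUE)
      geno[cbind(seq_len(n_founder), match(seeded, members))] <- 1L
      origin_individual[seq_len(n_founder)] <- seeded
    }

    # common background: Hardy-Weinberg founder genotypes
    maf <- stats::runif(n_bg, config$background_maf_range[1],
                        config$background_maf_range[2])
    founders <- members[is.na(ped$father_id) & is.na(ped$mother_id)]
    bg_rows <- n_founder + sum(n_dn) + seq_len(n_bg)
    for (f in founders) {
      geno[bg_rows, f] <- stats::rbinom(n_bg, 2L, maf)
    }

    # Mendelian transmission to children, in topological order
    for (child in kids) {
      row <- ped[ped$id == child, ]
      mc <- if (is.na(row$mother_id)) integer(nrow(keys)) else
        geno[, row$mother_id]
      fc <- if (is.na(row$father_id)) integer(nrow(keys)) else
        geno[, row$father_id]
      geno[, child] <- mendelian_transmit(mc, fc, config$transmission_prob)
    }

    # de novo spike-ins: unique to one child, heterozygous
    if (sum(n_dn) > 0) {
      dn_rows <- n_founder + seq_len(sum(n_dn))
      dn_owner <- rep(kids, n_dn)
      geno[cbind(dn_rows, match(dn_owner, members))] <- 1L
      origin_individual[dn_rows] <- dn_owner
    }

    deleterious <- origin != "common_background"
    anns <- sim_annotations(keys, origin, maf)
    truth <- data.frame(
      key = keys$key, origin = origin,
      origin_individual = origin_individual,
      deleterious = deleterious,
      carriers = apply(geno > 0, 1L, function(x)
        paste(members[x], collapse = ",")),
      stringsAsFactors = FALSE
    )

    callers <- names(config$caller_fn_rates)
    carrier <- geno > 0
    presence <- lapply(callers, function(cl) {
      fn <- config$dropout_rate + config$caller_fn_rates[[cl]] -
        config$dropout_rate * config$caller_fn_rates[[cl]]
      keep <- matrix(stats::runif(length(carrier)) >= fn, nrow(carrier))
      carrier & keep
    })
    names(presence) <- callers
    callset <- cohort_callset(keys, members, presence)

    out <- list(callset = callset, anns = anns, ped = ped, truth = truth,
                genotypes = geno)
    if (!is.null(dir)) {
      out$files <- write_simulation(out, presence, dir)
    }
    out
  })
}

sim_annotations <- function(keys, origin, bg_maf) {
  n <- nrow(keys)
  cls <- character(n)
  sift <- rep(NA_real_, n)
  poly <- rep(NA_real_, n)
  maf_col <- rep(NA_real_, n)

  del <- which(origin != "common_background")
  bg <- which(origin == "common_background")

  # truth-deleterious: ~10% stop gains (scoreless), rest nonsynonymous
  # with a SIFT score in the damaging band and any PolyPhen score
  stopg <- del[stats::runif(length(del)) < 0.1]
  nsyn <- setdiff(del, stopg)
  cls[stopg] <- "stopgain"
  cls[nsyn] <- "nonsynonymous_SNV"
  sift[nsyn] <- stats::runif(length(nsyn), 0, 0.049)
  poly[nsyn] <- round(stats::runif(length(nsyn)), 3)

  # background: half synonymous, half tolerated nonsynonymous; catalogued
  syn <- bg[stats::runif(length(bg)) < 0.5]
  tol <- setdiff(bg, syn)
  cls[syn] <- "synonymous"
  cls[tol] <- "nonsynonymous_SNV"
  sift[tol] <- stats::runif(length(tol), 0.05, 1)
  poly[tol] <- stats::runif(length(tol), 0, 0.446)
  maf_col[bg] <- bg_maf

  anns <- data.frame(
    key = keys$key,
    gene = sprintf("SIMGENE%04d", seq_len(n)),
    chrom = keys$chrom, pos = keys$pos, ref = keys$ref, alt = keys$alt,
    functional_class = cls,
    known_id = ifelse(is.na(maf_col), NA_character_,
                      sprintf("sim%06d", seq_len(n))),
    maf_1000G = maf_col,
    sift = round(sift, 3),
    polyphen_hvar = round(poly, 3),
    sanger_confirmed = NA,
    stringsAsFactors = FALSE
  )
  class(anns) <- c("variant_annotation", "data.frame")
  anns
}

write_simulation <- function(sim, presence, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  keys <- sim$callset$keys
  ord <- order(keys$chrom, keys$pos, keys$ref, keys$alt)
  for (cl in names(presence)) {
    path <- file.path(dir, paste0("sim_", cl, ".vcf"))
    m <- presence[[cl]][ord, , drop = FALSE]
    g <- sim$genotypes[ord, , drop = FALSE]
    gt <- matrix("0/0", nrow(m), ncol(m))
    gt[m & g == 1L] <- "0/1"
    gt[m & g >= 2L] <- "1/1"
    k <- keys[ord, , drop = FALSE]
    con <- file(path, "w")
    writeLines(c(
      "##fileformat=VCFv4.2",
      "##source=famvar-simulator",
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", sim$callset$samples), collapse = "\t")
    ), con)
    writeLines(paste(k$chrom, k$pos, ".", k$ref, k$alt, ".", "PASS", ".",
                     "GT",
                     apply(gt, 1L, paste, collapse = "\t"), sep = "\t"),
               con)
    close(con)
    files[cl] <- path
  }

  files["ped"] <- file.path(dir, "sim.ped")
  write_pedigree(sim$ped, files["ped"])
  files["anns"] <- file.path(dir, "sim_annotations.tsv")
  utils::write.table(sim$anns, files["anns"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  files["truth"] <- file.path(dir, "sim_truth.tsv")
  utils::write.table(sim$truth, files["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  files
}

#' Compare pipeline output against simulation truth
#'
#' Scores final-set membership as a confusion matrix over the simulated
#' variant universe — a truth positive is a truth-deleterious variant
#' carried by at least one affected member and by no control — and,
#' when inheritance records are supplied, checks every (variant, daughter)
#' label against the truth carrier sets (germline iff the mother carries).
#'
#' @param final_keys Character vector of variant keys surviving the
#'   cascade (e.g. `run_cascade(...)$callset$keys$key`).
#' @param truth Truth data frame from [simulate_family()].
#' @param ped The simulation [pedigree()].
#' @param control_ids Control ids used in the cascade run.
#' @param records Optional inheritance records from [classify_pair()].
#' @return A list with `set` (named counts `tp`, `fp`, `fn`, `tn`),
#'   `discordant_keys`, and when records were given `label_mismatches`
#'   (data frame) plus `n_labels_checked`.
#' @export
recovery_report <- function(final_keys, truth, ped, control_ids,
                            records = NULL) {
  if (length(setdiff(final_keys, truth$key))) {
    stop("pipeline output contains keys outside the simulated universe")
  }
  carriers <- strsplit(truth$carriers, ",", fixed = TRUE)
  affected <- ped$id[ped$affected]
  in_aff <- vapply(carriers, function(x) any(x %in% affected), logical(1))
  in_ctl <- vapply(carriers, function(x) any(x %in% control_ids),
                   logical(1))
  truth_pos <- truth$key[truth$deleterious & in_aff & !in_ctl]
  out_pos <- unique(final_keys)
  set <- c(tp = length(intersect(out_pos, truth_pos)),
           fp = length(setdiff(out_pos, truth_pos)),
           fn = length(setdiff(truth_pos, out_pos)),
           tn = length(setdiff(truth$key, union(truth_pos, out_pos))))
  res <- list(set = set,
              discordant_keys = union(setdiff(out_pos, truth_pos),
                                      setdiff(truth_pos, out_pos)))
  if (!is.null(records)) {
    expected_label <- vapply(seq_len(nrow(records)), function(i) {
      mother <- ped$mother_id[ped$id == records$daughter_id[i]]
      carr <- carriers[[match(records$key[i], truth$key)]]
      if (!is.na(mother) && mother %in% carr) "germline" else "de_novo"
    }, character(1))
    mism <- records[expected_label != records$label, , drop = FALSE]
    res$label_mismatches <- mism
    res$n_labels_checked <- nrow(records)
  }
  res
}
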