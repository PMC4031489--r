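test_that("classify_titv partitions the 12 substitutions 4/8", {
  bases <- c("A", "C", "G", "T")
  subs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  subs <- subs[subs$ref != subs$alt, ]
  cls <- classify_titv(subs$ref, subs$alt)
  expect_equal(sum(cls == "transition"), 4)
  expect_equal(sum(cls == "transversion"), 8)
  expect_equal(classify_titv("C", "T"), "transition")
  expect_equal(classify_titv("T", "G"), "transversion")
  # strand symmetry: a substitution and its reverse complement agree
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_equal(cls, classify_titv(comp[subs$ref], comp[subs$alt]))
  expect_error(classify_titv("AG", "A"), "single-nucleotide")
})

test_that("stratified Ti/Tv table matches the published ratios", {
  fx <- family_fixture()
  res <- run_cascade(fx$callset, fx$anns, fx$ped, fx$config)
  rec <- recurrence_summary(res$callset, as.character(c(1, 2, 4, 5, 6, 7)))
  tab <- titv_stratified(rec)
  expect_equal(tab$ti, c(14, 9, 5))
  expect_equal(tab$tv, c(9, 3, 6))
  expect_equal(tab$ratio, c(1.6, 3.0, 0.8))
})

test_that("Ti/Tv ratio is NA when a stratum has no transversions", {
  keys <- normalize_key("chr1", 100, "C", "T")
  cs <- consensus_callers(toy_callset(keys, list(a = 1)))
  tab <- titv_stratified(recurrence_summary(cs, "a"))
  expect_equal(tab$ti[tab$stratum == "total"], 1)
  expect_equal(tab$tv[tab$stratum == "total"], 0)
  expect_true(is.na(tab$ratio[tab$stratum == "total"]))
  # empty common stratum: zeros with NA ratio
  expect_equal(tab$ti[tab$stratum == "common"], 0)
  expect_true(is.na(tab$ratio[tab$stratum == "common"]))
})

test_that("ratio rounding is half-up to one decimal", {
  expect_equal(famvar:::round_half_up(0.25, 1), 0.3)
  expect_equal(famvar:::round_half_up(9 / 3, 1), 3.0)
  expect_equal(famvar:::round_half_up(5 / 6, 1), 0.8)
  expect_equal(famvar:::round_half_up(0.15, 1), 0.2) # base round gives 0.1
})

test_that("fisher_exact frozen examples", {
  expect_equal(fisher_exact(1, 1, 1, 1)$p_two_sided, 1)
  expect_equal(fisher_exact(5, 0, 0, 5)$p_two_sided, 2 / 252)
  # common vs individual Ti/Tv counts of the family's 23 mutations
  expect_equal(fisher_exact(9, 3, 5, 6)$p_two_sided, 0.2137569,
               tolerance = 1e-6)
  expect_error(fisher_exact(-1, 1, 1, 1), "non-negative")
  expect_error(fisher_exact(0, 0, 0, 0), "at least 1")
})

test_that("fisher_exact equals brute-force enumeration on all N <= 30", {
  worst <- 0
  for (n in 1:30) {
    for (r1 in 0:n) {
      for (c1 in 0:r1) { # (r1,c1) symmetric; test the lower triangle
        lo <- max(0, c1 - (n - r1))
        for (a in lo:min(r1, c1)) {
          b <- r1 - a; c <- c1 - a; d <- n - r1 - c
          p <- fisher_exact(a, b, c, d)$p_two_sided
          worst <- max(worst, abs(p - brute_fisher_two_sided(a, b, c, d)))
        }
      }
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("fisher_exact invariances and normalization", {
  set.seed(11)
  for (i in 1:25) {
    cells <- as.integer(sample(0:12, 4, replace = TRUE))
    if (sum(cells) == 0) cells[1] <- 1L
    f <- do.call(fisher_exact, as.list(cells))
    # simultaneous row and column swap leaves p unchanged
    g <- fisher_exact(cells[4], cells[3], cells[2], cells[1])
    expect_equal(f$p_two_sided, g$p_two_sided, tolerance = 1e-12)
    # agreement with the independent reference implementation
    expect_equal(f$p_two_sided,
                 stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
    # enumerated probabilities sum to one
    n <- sum(cells); r1 <- cells[1] + cells[2]; c1 <- cells[1] + cells[3]
    lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
    probs <- vapply(lo:hi, function(a)
      fisher_exact(a, r1 - a, c1 - a, n - r1 - c1 + a)$point_prob,
      numeric(1))
    expect_equal(sum(probs), 1, tolerance = 1e-12)
  }
})

test_that("interval context annotation matches the published fragile sites", {
  fx <- family_fixture()
  res <- run_cascade(fx$callset, fx$anns, fx$ped, fx$config)
  ctx <- annotate_context(res$callset$keys, fx$tracks)
  expect_equal(unname(attr(ctx, "summary")),
               c(5, 15, 2)) # fragile, structural variation, repeats
  gene_of <- fx$anns$gene[match(ctx$key, fx$anns$key)]
  expect_equal(ctx$fragile_sites[gene_of == "PAMR1"], "11E")
  expect_equal(ctx$fragile_sites[gene_of == "ZNF24"], "18A")
  expect_setequal(stats::na.omit(ctx$fragile_sites),
                  c("4A", "11E", "2G", "11C", "18A"))
  expect_true(all(ctx$in_repeats[gene_of %in% c("ZNF304", "ZNF674")]))
})

test_that("closed-interval boundary: positions at either end are inside", {
  tr <- interval_track("t", "chr1", 100, 200, "X")
  keys <- normalize_key("chr1", c(99, 100, 200, 201), "A", "G")
  ctx <- annotate_context(keys, tr)
  expect_equal(ctx$in_t, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("annotate_context agrees with a naive scan on random tracks", {
  set.seed(23)
  for (i in 1:5) {
    n_iv <- sample(3:10, 1)
    tr <- interval_track(
      "rand",
      chrom = paste0("chr", sample(1:3, n_iv, replace = TRUE)),
      start = (s <- sample.int(1000, n_iv)),
      end = s + sample.int(200, n_iv),
      label = paste0("iv", seq_len(n_iv))
    )
    keys <- normalize_key(paste0("chr", sample(1:3, 40, replace = TRUE)),
                          sample.int(1300, 40), "A", "G")
    ctx <- annotate_context(keys, tr)
    expect_equal(is.na(ctx$rand), is.na(naive_context(keys, tr)))
  }
})
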