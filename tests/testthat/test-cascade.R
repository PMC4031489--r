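test_that("caller consensus: intersection vs union", {
  keys <- toy_keys(2)
  samples <- c("a", "b")
  m1 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2,
               dimnames = list(keys$key, samples))
  m2 <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2,
               dimnames = list(keys$key, samples))
  cs <- cohort_callset(keys, samples, list(varscan = m1, gatk = m2))
  expect_equal(unname(consensus_callers(cs, "intersection")$merged),
               unname(m1 & m2))
  expect_equal(unname(consensus_callers(cs, "union")$merged),
               unname(m1 | m2))
  # single caller: either mode returns the matrix unchanged
  cs1 <- cohort_callset(keys, samples, list(only = m1))
  expect_equal(unname(consensus_callers(cs1, "union")$merged), unname(m1))
  expect_equal(unname(consensus_callers(cs1, "intersection")$merged),
               unname(m1))
  expect_error(consensus_callers(cs, "vote"))
})

test_that("unaffected subtraction drops control-shared and affected-absent", {
  keys <- toy_keys(4)
  ped <- trio_ped()
  cs <- toy_callset(keys, list(mom = c(1, 2), kid = 1, aunt = c(2, 3),
                               dad = 4))
  cs <- consensus_callers(cs)
  out <- remove_shared_with_unaffected(cs, ped, "aunt")
  # variant 2 shared with control, variant 3 control-only, variant 4 in
  # no affected member: only variant 1 survives
  expect_equal(out$keys$key, keys$key[1])
  expect_error(remove_shared_with_unaffected(cs, ped, "mom"),
               "marked affected")
  expect_error(remove_shared_with_unaffected(cs, ped, character(0)),
               "non-empty")
})

test_that("functional-class and rare filters restrict annotations", {
  anns <- family_fixture()$anns
  kept <- filter_functional_class(anns)
  expect_false("SYNBG3" %in% kept$gene)
  expect_true(all(c("TTN", "FOXP1") %in% kept$gene))
  rare <- filter_rare(anns, 0.001)
  expect_false(any(c("SYNBG1", "SYNBG4") %in% rare$gene))
  expect_true(all(c("UEVLD", "ITGA1") %in% rare$gene)) # catalogued, rare
  expect_true("SRA1" %in% rare$gene) # novel passes
})

test_that("deleteriousness uses the either-program OR rule", {
  anns <- family_fixture()$anns
  del <- function(g) predict_deleterious(anns[anns$gene == g, ])
  expect_true(del("FOXP1"))   # SIFT tolerated, PolyPhen damaging
  expect_true(del("ZNF24"))   # SIFT damaging, PolyPhen benign
  expect_false(del("SYNBG5")) # both in the tolerated/benign bands
  expect_true(del("TTN"))     # stop gain: unconditional
  expect_true(del("TBC1D22B"))           # SIFT 0.03 damaging despite
                                         # PolyPhen 0.39 benign
  scoreless <- anns[anns$gene == "TTN", ]
  scoreless$functional_class <- "nonsynonymous_SNV"
  expect_warning(res <- predict_deleterious(scoreless), "lack both")
  expect_false(res)
})

test_that("paternal removal edits daughters only and drops father-only rows", {
  ped <- family_fixture()$ped
  keys <- toy_keys(3)
  # v1: father 9 + daughter 5 only -> removed entirely
  # v2: father 9 + sister 1 (not his daughter) -> unchanged for 1
  # v3: mother 2 + daughters -> retained
  cs <- toy_callset(keys, list(`9` = c(1, 2), `5` = c(1, 3), `1` = 2,
                               `2` = 3, `6` = 3))
  cs <- consensus_callers(cs)
  out <- remove_paternal(cs, ped, "9", c("5", "6"))
  expect_false(keys$key[1] %in% out$keys$key)
  m <- merged_presence(out)
  expect_true(m[keys$key[2], "1"])
  expect_true(all(m[keys$key[3], c("2", "5", "6")]))
  expect_error(remove_paternal(cs, ped, "9", "7"), "not fathered")
})

test_that("the full cascade reproduces the family fixture", {
  fx <- family_fixture()
  res <- run_cascade(fx$callset, fx$anns, fx$ped, fx$config)
  expect_equal(nrow(res$anns), 23)
  expect_false(any(grepl("^SYNBG", res$anns$gene)))
  # audit: monotone, removed keys disjoint from output
  aud <- res$audit
  expect_true(all(aud$variants_out <= aud$variants_in))
  expect_true(all(diff(aud$variants_out) <= 0))
  expect_equal(aud$variants_out[nrow(aud)], 23)
  removed <- unlist(attr(aud, "removed"))
  expect_length(intersect(removed, res$callset$keys$key), 0)
  # control exclusion
  m <- merged_presence(res$callset)
  expect_false(any(m[, fx$config$control_ids]))
  # sanger confirmation stage keeps the 23 confirmed variants
  res2 <- run_cascade(fx$callset, fx$anns, fx$ped, fx$config,
                      confirm_sanger = TRUE)
  expect_equal(sort(res2$anns$key), sort(res$anns$key))
})

test_that("cascade is idempotent and empty input yields empty audit", {
  fx <- family_fixture()
  res <- run_cascade(fx$callset, fx$anns, fx$ped, fx$config)
  res2 <- run_cascade(res$callset, fx$anns, fx$ped, fx$config)
  expect_equal(sort(res2$callset$keys$key), sort(res$callset$keys$key))
  expect_equal(merged_presence(res2$callset)[res$callset$keys$key, ],
               merged_presence(res$callset))
  empty <- restrict_callset(fx$callset, character(0))
  res0 <- run_cascade(empty, fx$anns, fx$ped, fx$config)
  expect_equal(nrow(res0$callset$keys), 0)
  expect_true(all(res0$audit$variants_in == 0))
})

test_that("permuting the restriction stages leaves the final set unchanged", {
  fx <- family_fixture()
  cfg <- fx$config
  reference <- sort(run_cascade(fx$callset, fx$anns, fx$ped,
                                cfg)$callset$keys$key)

  stage_unaff <- function(cs) remove_shared_with_unaffected(cs, fx$ped,
                                                            cfg$control_ids)
  stage_class <- function(cs) restrict_callset(
    cs, filter_functional_class(fx$anns, cfg$kept_classes)$key)
  stage_rare <- function(cs) restrict_callset(
    cs, filter_rare(fx$anns, cfg$maf_threshold)$key)
  stage_del <- function(cs) restrict_callset(
    cs, fx$anns$key[suppressWarnings(predict_deleterious(fx$anns, cfg))])
  stage_pat <- function(cs) {
    for (f in c("9", "10")) {
      kids <- intersect(daughters_of(fx$ped, f), cs$samples)
      if (length(kids)) cs <- remove_paternal(cs, fx$ped, f, kids)
    }
    cs
  }
  stages <- list(stage_unaff, stage_class, stage_rare, stage_del, stage_pat)
  orders <- list(c(5, 4, 3, 2, 1), c(3, 1, 5, 2, 4), c(2, 5, 1, 4, 3))
  for (ord in orders) {
    cs <- consensus_callers(fx$callset, cfg$caller_mode)
    for (i in ord) cs <- stages[[i]](cs)
    cs <- stage_unaff(cs) # final affected-only guarantee, as in the cascade
    expect_equal(sort(cs$keys$key), reference)
  }
})

test_that("unannotated callset variants: strict errors, lenient drops", {
  fx <- family_fixture()
  anns <- fx$anns[fx$anns$gene != "FOXP1", ]
  expect_error(run_cascade(fx$callset, anns, fx$ped, fx$config),
               "missing from")
  expect_warning(
    res <- run_cascade(fx$callset, anns, fx$ped, fx$config, strict = FALSE),
    "dropped")
  expect_equal(nrow(res$anns), 22)
})
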