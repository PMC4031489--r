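test_that("mendelian_transmit edge cases and transmission frequency", {
  # neither parent carries: child never carries
  expect_equal(mendelian_transmit(rep(0, 50), rep(0, 50)), rep(0L, 50))
  # both parents homozygous: child always carries two copies
  expect_equal(mendelian_transmit(rep(2, 50), rep(2, 50)), rep(2L, 50))
  # both parents het with certain transmission: child always carries
  expect_equal(mendelian_transmit(rep(1, 50), rep(1, 50),
                                  transmission_prob = 1), rep(2L, 50))
  # heterozygous mother: carrier fraction 0.5 within binomial tolerance
  set.seed(101)
  kids <- mendelian_transmit(rep(1, 10000), rep(0, 10000))
  expect_equal(mean(kids > 0), 0.5, tolerance = 0.03) # 0.015 absolute
  expect_error(mendelian_transmit(3, 0), "0, 1 or 2")
})

test_that("simulation output is deterministic and internally consistent", {
  cfg <- sim_config(seed = 99)
  s1 <- simulate_family(cfg)
  s2 <- simulate_family(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$anns, s2$anns)
  # written files are byte-identical across runs with the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- simulate_family(cfg, dir = d1)$files
  f2 <- simulate_family(cfg, dir = d2)$files
  for (nm in names(f1)) {
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]))
  }
  # truth structure: de novo variants have a single carrier, their owner
  dn <- s1$truth[s1$truth$origin == "de_novo", ]
  expect_true(all(dn$carriers == dn$origin_individual))
  # founder variants seeded only in designated affected founders
  fo <- s1$truth[s1$truth$origin == "founder_germline", ]
  expect_true(all(fo$origin_individual %in% cfg$founder_carrier_ids))
})

test_that("background carrier frequency converges to the configured MAF", {
  n_f <- 400L
  ped <- pedigree(id = c("seed1", paste0("f", seq_len(n_f))),
                  sex = "female",
                  affected = c(TRUE, rep(FALSE, n_f)))
  cfg <- sim_config(ped = ped, founder_carrier_ids = "seed1",
                    n_founder_rare_deleterious = 1L, denovo_mean = 0,
                    n_common_background = 40L, seed = 17)
  sim <- simulate_family(cfg)
  bg <- sim$truth$origin == "common_background"
  maf <- sim$anns$maf_1000G[bg]
  carr_freq <- rowSums(sim$genotypes[bg, -1, drop = FALSE] > 0) / n_f
  hw <- 1 - (1 - maf)^2 # Hardy-Weinberg carrier probability
  se <- sqrt(hw * (1 - hw) / n_f)
  expect_true(all(abs(carr_freq - hw) < 5 * se + 1e-9))
})

test_that("simulated VCF/PED/TSV files feed the pipeline unchanged", {
  dir <- withr::local_tempdir()
  sim <- simulate_family(sim_config(seed = 5), dir = dir)
  cs <- read_cohort_vcf(c(varscan = sim$files[["varscan"]],
                          gatk = sim$files[["gatk"]]))
  ped <- parse_pedigree(sim$files[["ped"]])
  anns <- read_annotation_table(sim$files[["anns"]])
  controls <- c("3", "8")
  res <- run_cascade(cs, anns, ped, filter_config(control_ids = controls))
  rep <- recovery_report(res$callset$keys$key, sim$truth, ped, controls)
  expect_equal(unname(rep$set[c("fp", "fn")]), c(0L, 0L))
})

test_that("noiseless recovery: cascade and labels equal truth exactly", {
  # the full 20-seed sweep lives in the acceptance suite; spot-check two
  # seeds here, including the truth-set comparison with no background
  for (seed in c(3L, 8L)) {
    cfg <- sim_config(seed = seed, n_founder_rare_deleterious = 10L,
                      n_common_background = 0L, denovo_mean = 0)
    sim <- simulate_family(cfg)
    res <- run_cascade(sim$callset, sim$anns, sim$ped,
                       filter_config(control_ids = c("3", "8")))
    rep <- recovery_report(res$callset$keys$key, sim$truth, sim$ped,
                           c("3", "8"))
    expect_equal(sum(rep$set[c("fp", "fn")]), 0L)
    # output is the subset of the 10 seeded variants reaching an affected
    # member and no control
    expect_true(all(res$callset$keys$key %in%
                      sim$truth$key[sim$truth$origin == "founder_germline"]))
  }
})

test_that("dropout and discordance are reported, not silently absorbed", {
  cfg <- sim_config(seed = 21, dropout_rate = 0.4)
  sim <- simulate_family(cfg)
  # with heavy dropout the two pseudo-callers disagree; intersection mode
  # can only shrink presence relative to truth
  merged <- consensus_callers(sim$callset, "intersection")
  expect_true(all(merged$merged <= (sim$genotypes > 0)))
  # recovery_report rejects foreign keys
  expect_error(recovery_report("chr9:1:A:T", sim$truth, sim$ped, "3"),
               "outside the simulated universe")
})
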