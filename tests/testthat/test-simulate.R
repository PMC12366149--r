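small_cfg <- function(seed = 1L, ...) {
  simulation_config(seed = seed, contigs = c(`1` = 1e7),
                    n_truth = c(DEL = 500L, INS = 300L), ...)
}

test_that("truth sets are deterministic, disjoint for deletions and >= 50 bp", {
  cfg <- small_cfg(seed = 31)
  t1 <- simulate_truth_set(cfg)
  t2 <- simulate_truth_set(cfg)
  expect_identical(t1, t2)
  expect_equal(sum(t1$svtype == "DEL"), 500)
  expect_equal(sum(t1$svtype == "INS"), 300)
  expect_true(all(t1$svlen >= 50))
  dels <- t1[svtype == "DEL"][order(pos)]
  expect_true(all(dels$pos[-1] > dels$end[-nrow(dels)]))  # non-overlapping
  empty <- simulate_truth_set(simulation_config(seed = 1,
                                                n_truth = c(DEL = 0L, INS = 0L)))
  expect_equal(nrow(empty), 0)
  expect_error(simulate_truth_set(
    simulation_config(contigs = c(`1` = 1e5), n_truth = c(DEL = 500L, INS = 0L))),
    "too small")
})

test_that("the noiseless limit reproduces the truth set exactly", {
  profiles <- list(manta = list(sens = c(DEL = 1, INS = 1), jitter_sd = 0,
                                fp_per_mb = c(DEL = 0, INS = 0)))
  cfg <- simulation_config(seed = 32, contigs = c(`1` = 1e8),
                           n_truth = c(DEL = 150L, INS = 100L),
                           caller_profiles = profiles)
  truth <- simulate_truth_set(cfg)
  # precondition for the all-TP claim: no two same-type truth records lie
  # within merge distance of each other (each cluster is one truth record)
  expect_equal(length(bf_clusters(truth, 1000, TRUE)), nrow(truth))
  sim <- simulate_caller_outputs(truth, cfg)
  calls <- sim$calls_by_caller$manta
  expect_equal(nrow(calls), nrow(truth))
  expect_equal(calls[order(chrom, pos, svtype)]$pos,
               truth[order(chrom, pos, svtype)]$pos)
  expect_equal(calls[order(chrom, pos, svtype)]$svlen,
               truth[order(chrom, pos, svtype)]$svlen)
  expect_true(all(sim$ledger$origin != "FP"))
  # noiseless consensus labels are all TP; with sensitivity 0 all FP
  cons <- merge_calls(list(manta = calls[svtype == "DEL"]))
  expect_true(all(label_consensus(cons, truth)))
  profiles0 <- list(manta = list(sens = c(DEL = 0, INS = 0), jitter_sd = 0,
                                 fp_per_mb = c(DEL = 3, INS = 0)))
  cfg0 <- small_cfg(seed = 33, caller_profiles = profiles0)
  sim0 <- simulate_caller_outputs(truth, cfg0)
  cons0 <- merge_calls(list(manta = sim0$calls_by_caller$manta))
  expect_false(any(label_consensus(cons0, truth)))
})

test_that("detection and false-positive counts follow their sampling models", {
  profiles <- list(delly = list(sens = c(DEL = 0.6, INS = 0), jitter_sd = 10,
                                fp_per_mb = c(DEL = 5, INS = 0)))
  cfg <- simulation_config(seed = 34, contigs = c(`1` = 5e7, `2` = 5e7),
                           n_truth = c(DEL = 2000L, INS = 0L),
                           caller_profiles = profiles)
  truth <- simulate_truth_set(cfg)
  sim <- simulate_caller_outputs(truth, cfg)
  n_tp <- sum(sim$ledger$origin != "FP")
  n_fp <- sum(sim$ledger$origin == "FP")
  # binomial: 2000 * 0.6 = 1200, sd ~ 21.9; Poisson: 100 Mb * 5 = 500, sd ~ 22.4
  expect_lt(abs(n_tp - 1200), 3 * sqrt(2000 * 0.6 * 0.4))
  expect_lt(abs(n_fp - 500), 3 * sqrt(500))
  # every TP origin exists in truth; jitter bounded at 6 SD
  tp_led <- sim$ledger[origin != "FP"]
  expect_true(all(tp_led$origin %in% truth$id))
  # jittered breakpoints stay within 6 SD of their truth origin
  calls <- sim$calls_by_caller$delly
  led <- sim$ledger[origin != "FP", .(id, origin)]
  jit <- merge(merge(calls[, .(id, pos)], led, by = "id"),
               truth[, .(origin = id, tpos = pos)], by = "origin")
  expect_true(all(abs(jit$pos - jit$tpos) <= 6 * 10))
})

test_that("written VCFs parse back to the in-memory call tables", {
  cfg <- small_cfg(seed = 35)
  truth <- simulate_truth_set(cfg)
  out <- tempfile()
  sim <- simulate_caller_outputs(truth, cfg, out_dir = out)
  d <- default_dialects()
  for (cl in c("manta", "delly", "insurveyor", "breakdancer")) {
    if (is.null(sim$files[cl]) || is.na(sim$files[cl])) next
    parsed <- parse_caller_vcf(sim$files[[cl]], d[[cl]])
    orig <- sim$calls_by_caller[[cl]]
    expect_equal(nrow(parsed), nrow(orig), info = cl)
    data.table::setkey(parsed, id); data.table::setkey(orig, id)
    expect_equal(parsed$pos, orig$pos, info = cl)
    expect_equal(parsed$end, orig$end, info = cl)
    expect_equal(parsed$svtype, orig$svtype, info = cl)   # DUP folded back
    expect_equal(parsed$svlen, orig$svlen, info = cl)     # sign removed
    expect_equal(parsed$genotype, orig$genotype, info = cl)
    for (m in d[[cl]]$metrics$metric)
      expect_equal(parsed[[m]], as.numeric(orig[[m]]), tolerance = 1e-6,
                   info = paste(cl, m))
  }
  expect_true(file.exists(file.path(out, "truth.vcf")))
  tr_back <- parse_caller_vcf(file.path(out, "truth.vcf"), d$truth)
  expect_equal(nrow(tr_back), nrow(truth))
  expect_true(file.exists(file.path(out, "ledger.tsv")))
  expect_true(file.exists(file.path(out, "stats.json")))
})

test_that("mixed-run consensus labels agree with the generating ledger", {
  cfg <- small_cfg(seed = 36)
  truth <- simulate_truth_set(cfg)
  sim <- simulate_caller_outputs(truth, cfg)
  del_calls <- lapply(sim$calls_by_caller, function(x) x[svtype == "DEL"])
  del_calls <- del_calls[vapply(del_calls, nrow, integer(1)) > 0]
  cons <- merge_calls(del_calls)
  labels <- label_consensus(cons, truth)
  # clusters containing at least one ledger-TP member should be labeled TP;
  # allow a small tolerance for jitter pushing members past match limits
  led <- sim$ledger[svtype == "DEL"]
  member_tp <- vapply(seq_len(nrow(cons)), function(i) {
    m <- cons$members[[i]]
    any(led[paste(caller, id) %in% paste(m$caller, m$id)]$origin != "FP")
  }, logical(1))
  expect_gt(mean(labels == member_tp), 0.97)
})
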