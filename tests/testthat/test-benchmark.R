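truth3 <- make_calls(c(10000, 50000, 90000), c(12000, 53000, 91000),
                     caller = "truth", id = paste0("t", 1:3))

test_that("matching applies distance and size-similarity rules", {
  calls <- rbind(
    make_calls(10000, 12000, id = "exact"),          # identical to t1
    make_calls(50000, 51000, id = "halfsize"),       # size ratio ~0.33 vs t2
    make_calls(300000, 302000, id = "nowhere"))      # far from any truth
  mr <- match_to_truth(calls, truth3)
  expect_s3_class(mr, "match_result")
  expect_equal(mr$tp, 1)
  expect_equal(mr$fp, 2)
  expect_equal(mr$fn, 2)  # t2 (failed size sim) and t3 (uncalled) are FN
  expect_equal(mr$pairs$call_id, "exact")
  expect_equal(mr$pairs$truth_id, "t1")
  # conservation identities
  expect_equal(mr$tp + mr$fn, mr$n_truth)
  expect_equal(mr$tp + mr$fp, mr$n_calls)
  expect_error(match_to_truth(calls, rbind(truth3, truth3)), "duplicated")
})

test_that("assignment is one-to-one, greedy by breakpoint distance", {
  # two calls compete for one truth record; nearer wins, other becomes FP
  calls <- rbind(make_calls(10005, 12005, id = "near"),
                 make_calls(10100, 12100, id = "far"))
  mr <- match_to_truth(calls, truth3)
  expect_equal(mr$pairs[truth_id == "t1"]$call_id, "near")
  expect_equal(mr$tp, 1)
  expect_equal(mr$fp, 1)
})

test_that("adding an unmatched call or truth record moves exactly one counter", {
  calls <- make_calls(10000, 12000, id = "exact")
  base <- match_to_truth(calls, truth3)
  more_calls <- match_to_truth(rbind(calls, make_calls(400000, 401000,
                                                       id = "junk")), truth3)
  expect_equal(more_calls$fp, base$fp + 1)
  expect_equal(more_calls$tp, base$tp)
  expect_equal(more_calls$fn, base$fn)
  more_truth <- match_to_truth(calls, rbind(truth3,
                                            make_calls(700000, 701000,
                                                       caller = "truth",
                                                       id = "t9")))
  expect_equal(more_truth$fn, base$fn + 1)
  expect_equal(more_truth$tp, base$tp)
  expect_equal(more_truth$fp, base$fp)
})

test_that("greedy assignment attains maximum-matching TP counts on sparse fixtures", {
  skip_if_not_installed("igraph")
  set.seed(21)
  for (i in 1:20) {
    truth <- make_calls(sort(sample.int(5e5, 30)) * 3,
                        caller = "truth", id = paste0("t", 1:30),
                        end = 0)  # placeholder, fix below
    truth[, end := pos + sample(100:3000, 30)]
    truth[, svlen := end - pos + 1L]
    calls <- truth[sample(30, 25)]
    calls[, `:=`(id = paste0("c", seq_len(.N)),
                 pos = pos + sample(-300:300, .N, replace = TRUE))]
    calls[, end := pos + svlen - 1L]
    mr <- match_to_truth(calls, truth)
    # maximum bipartite matching on the same candidate graph
    cand <- merge(calls[, .(cid = id, chrom, svtype, cp = pos, ce = end, clen = svlen)],
                  truth[, .(tid = id, chrom, svtype, tp_ = pos, te = end, tlen = svlen)],
                  by = c("chrom", "svtype"), allow.cartesian = TRUE)
    cand <- cand[abs(cp - tp_) <= 500 & abs(ce - te) <= 500 &
                   pmin(clen, tlen) / pmax(clen, tlen) >= 0.7]
    g <- igraph::graph_from_data_frame(cand[, .(cid, tid)], directed = FALSE,
                                       vertices = data.frame(
                                         name = c(calls$id, truth$id),
                                         type = rep(c(FALSE, TRUE),
                                                    c(nrow(calls), nrow(truth)))))
    expect_equal(mr$tp, igraph::max_bipartite_match(g)$matching_size)
  }
})

test_that("metric identities reproduce printed benchmark table cells", {
  m <- compute_metrics(list(tp = 3207, fp = 967, fn = 844))
  expect_equal(round_half_up(m$precision), 0.77)
  expect_equal(round_half_up(m$recall), 0.79)
  expect_equal(round_half_up(m$f1), 0.78)
  m2 <- compute_metrics(list(tp = 2649, fp = 97, fn = 1402))
  expect_equal(round_half_up(m2$precision), 0.96)
  expect_equal(round_half_up(m2$recall), 0.65)
  expect_equal(round_half_up(m2$f1), 0.78)
  z <- compute_metrics(list(tp = 0, fp = 0, fn = 0))
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
  expect_error(compute_metrics(list(tp = -1, fp = 0, fn = 0)), "non-negative")
})

test_that("rank-statistic AUC matches hand enumeration and an independent library", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  # 4 scores, 2 positives: positives 0.9 & 0.3 vs negatives 0.5 & 0.3
  # pairs: (0.9>0.5)=1, (0.9>0.3)=1, (0.3<0.5)=0, (0.3==0.3)=0.5 -> 2.5/4
  expect_equal(roc_auc(c(0.9, 0.3, 0.5, 0.3), c(TRUE, TRUE, FALSE, FALSE)),
               0.625)
  set.seed(22)
  p <- runif(10000); y <- sample(c(TRUE, FALSE), 10000, replace = TRUE)
  expect_equal(roc_auc(p, y), 0.5, tolerance = 0.02)
  expect_error(roc_auc(p, rep(TRUE, 10000)), "both classes")
  skip_if_not_installed("pROC")
  set.seed(23)
  p2 <- runif(500); y2 <- runif(500) < p2
  expect_equal(roc_auc(p2, y2),
               as.numeric(pROC::auc(pROC::roc(y2, p2, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("decile bins cover [0,1] with a closed top bin", {
  r <- decile_report(rep(0.05, 40))
  expect_equal(r$n[1], 40)
  expect_equal(sum(r$n), 40)
  expect_equal(sum(r$fraction), 1)
  r2 <- decile_report(c(1.0, 0.95, 0.9), c(TRUE, TRUE, FALSE))
  expect_equal(r2$n[10], 3)  # 1.0 counts in the top bin
  expect_equal(r2$tp_prop[10], 2 / 3)
  expect_error(decile_report(c(0.5, 1.2)), "\\[0, 1\\]")
})
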