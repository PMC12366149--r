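stats35 <- sequencing_stats(35, 150)

test_that("normalization divides by the declared scale", {
  expect_equal(normalize_metric(70, "coverage", stats35), 2.0)
  expect_equal(normalize_metric(15, "read_length", stats35), 0.1)
  expect_equal(normalize_metric(0.7, "none", stats35), 0.7)
  expect_true(is.na(normalize_metric(NA_real_, "coverage", stats35)))
  expect_error(sequencing_stats(0, 150), "positive")
})

test_that("default registries have the expected shape", {
  del <- default_feature_registry("DEL")
  ins <- default_feature_registry("INS")
  expect_equal(nrow(del$entries), 34)
  expect_equal(nrow(ins$entries), 35)
  expect_true(del$include_svlen && ins$include_svlen)
  expect_setequal(unique(del$entries$caller),
                  c("breakdancer", "delly", "lumpy", "manta", "pindel", "tardis"))
  expect_setequal(unique(ins$entries$caller),
                  c("delly", "insurveyor", "manta", "pindel", "tardis"))
  # registries refuse callers outside the type's eligible set
  expect_error(feature_registry("INS", data.frame(
    caller = "breakdancer", metric = "qual", kind = "none")), "may not draw")
})

make_two_caller_fixture <- function() {
  manta <- make_calls(c(1000, 8000), c(2000, 9000), caller = "manta")
  manta[, `:=`(qual = c(80, 40), gq = c(50, 30), pr_ref = c(20, 10),
               pr_alt = c(14, 7), sr_ref = c(8, 4), sr_alt = c(10, 2),
               homlen = c(3, 1))]
  delly <- make_calls(1010, 2010, caller = "delly")
  delly[, `:=`(pe = 7, sr = 10, mapq = 40, srmapq = 20, ce = 1.8,
               homlen = 6, gq = 14, rc = 140, rdratio = 0.5, rv = 3)]
  list(manta = manta, delly = delly)
}

test_that("feature matrix has one row per consensus call with hand-computed values", {
  calls <- make_two_caller_fixture()
  cons <- merge_calls(calls)
  fm <- suppressWarnings(  # only manta and delly supply calls here
    build_feature_matrix(cons, calls, default_feature_registry("DEL"), stats35))
  expect_equal(dim(fm), c(2L, 35L))  # 34 caller metrics + svlen
  shared <- which(cons$supp == 2)
  only_m <- which(cons$supp == 1)
  # normalized by coverage 35 / passthrough for scale-free metrics
  expect_equal(fm$x$manta.qual[shared], 80)
  expect_equal(fm$x$manta.pr_alt[shared], 14 / 35)
  expect_equal(fm$x$delly.pe[shared], 7 / 35)
  expect_equal(fm$x$delly.rc[shared], 140 / 35)
  expect_equal(fm$x$delly.homlen[shared], 6)
  expect_equal(fm$x$svlen, as.numeric(cons$svlen))
  # caller absent from a consensus call: all its columns missing
  expect_true(all(is.na(as.matrix(fm$x[only_m, grep("^delly\\.", names(fm$x)),
                                       with = FALSE]))))
  # a registry caller with no input at all warns and yields all-missing columns
  expect_warning(
    fm2 <- build_feature_matrix(cons, calls["manta"],
                                default_feature_registry("DEL"), stats35),
    "no input calls")
  expect_true(all(is.na(fm2$x$delly.pe)))
})

test_that("basic matrix is svlen plus one presence flag per caller", {
  calls <- make_two_caller_fixture()
  cons <- merge_calls(calls)
  callers6 <- c(calls, list(breakdancer = make_calls(1, 0)[0], lumpy = make_calls(1, 0)[0],
                            pindel = make_calls(1, 0)[0], tardis = make_calls(1, 0)[0]))
  bm <- basic_feature_matrix(cons, callers6)
  expect_equal(ncol(bm$x), 7L)  # svlen + 6 callers
  shared <- which(cons$supp == 2)
  expect_equal(bm$x$presence_manta[shared], 1)
  expect_equal(bm$x$presence_delly[shared], 1)
  expect_equal(bm$x$presence_tardis[shared], 0)
  expect_true(all(as.matrix(bm$x)[, -1] %in% c(0, 1)))
})

test_that("coverage scale invariance: doubling depth and coverage-kind metrics changes nothing", {
  calls <- make_two_caller_fixture()
  cons <- merge_calls(calls)
  reg <- default_feature_registry("DEL")
  fm1 <- suppressWarnings(build_feature_matrix(cons, calls, reg, stats35))
  doubled <- lapply(calls, function(x) data.table::copy(x))
  for (cl in names(doubled)) {
    ent <- reg$entries[reg$entries$caller == cl & reg$entries$kind == "coverage", ]
    for (m in ent$metric) doubled[[cl]][, (m) := get(m) * 2]
  }
  fm2 <- suppressWarnings(
    build_feature_matrix(cons, doubled, reg, sequencing_stats(70, 150)))
  expect_identical(as.matrix(fm1), as.matrix(fm2))
})

test_that("feature rows follow their consensus ids, not row order", {
  calls <- make_two_caller_fixture()
  cons <- merge_calls(calls)
  reg <- default_feature_registry("DEL")
  fm1 <- suppressWarnings(build_feature_matrix(cons, calls, reg, stats35))
  perm <- rev(seq_len(nrow(cons)))
  fm2 <- suppressWarnings(build_feature_matrix(cons[perm], calls, reg, stats35))
  m1 <- as.matrix(fm1); m2 <- as.matrix(fm2)
  expect_identical(m1, m2[rownames(m1), ])
})

test_that("correlation selection drops duplicates and constants deterministically", {
  set.seed(9)
  n <- 300
  x <- data.table::data.table(
    f_signal = rnorm(n), f_dup = numeric(n), f_const = 1,
    f_noise = rnorm(n))
  labels <- x$f_signal + rnorm(n, 0, 0.5) > 0
  x[, f_dup := f_signal]  # exact copy: r = 1
  fm <- structure(list(ids = as.character(1:n), x = x, labels = labels,
                       stats = NULL, registry = NULL, svtype = "DEL"),
                  class = "sv_feature_matrix")
  keep <- correlation_select(fm, r_threshold = 0.90)
  expect_false("f_const" %in% keep)
  expect_equal(sum(c("f_signal", "f_dup") %in% keep), 1)
  expect_true("f_noise" %in% keep)
  # ten independent features all survive at 0.90
  set.seed(10)
  xi <- data.table::as.data.table(matrix(rnorm(500 * 10), 500, 10))
  data.table::setnames(xi, sprintf("g%02d", 1:10))
  fmi <- structure(list(ids = as.character(1:500), x = xi,
                        labels = rnorm(500) > 0, stats = NULL,
                        registry = NULL, svtype = "DEL"),
                   class = "sv_feature_matrix")
  expect_equal(sort(correlation_select(fmi)), sort(names(xi)))
  # invariance to column order
  fmi2 <- fmi; fmi2$x <- fmi$x[, rev(names(fmi$x)), with = FALSE]
  expect_setequal(correlation_select(fmi2), correlation_select(fmi))
})

test_that("feature matrices survive a TSV round trip", {
  calls <- make_two_caller_fixture()
  cons <- merge_calls(calls)
  fm <- suppressWarnings(
    build_feature_matrix(cons, calls, default_feature_registry("DEL"), stats35))
  fm <- set_labels(fm, c(TRUE, FALSE))
  path <- tempfile(fileext = ".tsv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$ids, fm$ids)
  expect_equal(as.matrix(back), as.matrix(fm))
  expect_equal(back$labels, fm$labels)
  expect_equal(back$stats$mean_coverage, 35)
  expect_equal(back$registry$entries$name, fm$registry$entries$name)
})
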