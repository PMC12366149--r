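library(data.table)

# --- tiny VCF builders -------------------------------------------------

vcf_header <- function(with_sample = TRUE) {
  c("##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="e">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="l">',
    '##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description="i">',
    '##INFO=<ID=DP,Number=1,Type=Float,Description="d">',
    '##INFO=<ID=AF,Number=1,Type=Float,Description="a">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="q">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           if (with_sample) "\tFORMAT\tS1" else ""))
}

write_tmp_vcf <- function(records, with_sample = TRUE) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(vcf_header(with_sample), records), path)
  path
}

# canonical in-memory call table for merge/benchmark tests
make_calls <- function(pos, end, svtype = "DEL", chrom = "1",
                       caller = "c1", id = NULL, svlen = NULL) {
  n <- length(pos)
  data.table(
    id = id %||% sprintf("%s_%03d", caller, seq_len(n)),
    caller = caller, chrom = chrom, pos = as.integer(pos),
    end = as.integer(end), svtype = svtype,
    svlen = as.integer(svlen %||% ifelse(svtype == "DEL",
                                         end - pos + 1L, pmax(end - pos + 1L, 50L))),
    genotype = "het", precise = TRUE, filter_pass = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles ----------------------------------------------

# brute-force transitive-closure clustering over all O(n^2) pairs
bf_clusters <- function(calls, max_dist = 1000, type_match = TRUE) {
  n <- nrow(calls)
  if (n == 0) return(list())
  link <- outer(calls$chrom, calls$chrom, "==") &
    abs(outer(calls$pos, calls$pos, "-")) <= max_dist &
    abs(outer(calls$end, calls$end, "-")) <= max_dist
  if (type_match) link <- link & outer(calls$svtype, calls$svtype, "==")
  diag(link) <- TRUE
  comp <- seq_len(n)
  repeat {
    newcomp <- vapply(seq_len(n), function(i) min(comp[link[i, ]]), integer(1))
    if (identical(newcomp, comp)) break
    comp <- newcomp
  }
  split(paste(calls$caller, calls$id, sep = ":"), comp)
}

# partition of member keys from merge_calls output, for oracle comparison
merge_partition <- function(consensus) {
  lapply(seq_len(nrow(consensus)), function(i)
    sort(strsplit(consensus$member_ids[i], ",", fixed = TRUE)[[1]]))
}

canon_partition <- function(p) {
  p <- unname(lapply(p, sort))
  p[order(vapply(p, `[`, character(1), 1))]
}

random_call_set <- function(n, n_callers = 3, width = 5e4) {
  callers <- paste0("caller", seq_len(n_callers))
  svt <- sample(c("DEL", "INS"), n, replace = TRUE)
  pos <- sample.int(width, n, replace = TRUE)
  len <- sample(50:5000, n, replace = TRUE)
  calls <- data.table(
    caller = sample(callers, n, replace = TRUE),
    chrom = sample(c("1", "2"), n, replace = TRUE),
    pos = pos, svtype = svt,
    end = ifelse(svt == "DEL", pos + len - 1L, pos),
    svlen = len, genotype = "het", precise = TRUE, filter_pass = TRUE)
  calls[, id := sprintf("r%04d", seq_len(n))]
  calls
}

as_by_caller <- function(calls) split(calls, by = "caller")

# --- shared acceptance-scale simulation (computed once per session) ----

.sim_cache <- new.env(parent = emptyenv())

acceptance_sim <- function() {
  if (!is.null(.sim_cache$run)) return(.sim_cache$run)
  small_grid <- list(max_depth = c(3, 5), eta = 0.3, nrounds = 100,
                     min_child_weight = 1)
  run <- list()
  for (part in c("train", "eval")) {
    cfg <- simulation_config(seed = if (part == "train") 101L else 202L,
                             n_truth = c(DEL = 2000L, INS = 2000L))
    truth <- simulate_truth_set(cfg)
    sim <- simulate_caller_outputs(truth, cfg)
    run[[part]] <- list(cfg = cfg, truth = truth, sim = sim)
    for (svt in c("DEL", "INS")) {
      calls <- lapply(sim$calls_by_caller, function(x) x[svtype == svt])
      calls <- calls[vapply(calls, nrow, integer(1)) > 0]
      cons <- merge_calls(calls)
      labels <- label_consensus(cons, truth)
      reg <- default_feature_registry(svt)
      fm <- set_labels(build_feature_matrix(cons, calls, reg, cfg$stats),
                       labels)
      bm <- set_labels(basic_feature_matrix(cons, calls), labels)
      run[[part]][[svt]] <- list(calls = calls, consensus = cons,
                                 labels = labels, fm = fm, bm = bm)
    }
  }
  tc <- training_config(grid = small_grid, seed = 11L)
  for (svt in c("DEL", "INS")) {
    fm_model <- prune_zero_importance(
      grid_search_train(run$train[[svt]]$fm, tc), run$train[[svt]]$fm, tc)
    bm_model <- grid_search_train(run$train[[svt]]$bm, tc)
    run$models[[svt]] <- list(fm = fm_model, bm = bm_model)
  }
  .sim_cache$run <- run
  run
}
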