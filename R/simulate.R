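# Seeded simulator of truth sets and multi-caller SV call sets.
#
# The generator emulates the behaviour the meta-caller exploits: callers
# with heterogeneous sensitivity and false-positive rates, breakpoint
# jitter, and quality metrics whose TP- and FP-conditional distributions
# are separated, with coverage-referring metrics scaling linearly with
# mean coverage (so normalization by coverage makes them comparable
# across depths). It emulates VCF-level caller output only: no reads, no
# genome sequence, no realistic SV length spectrum beyond a log-uniform
# range.

#' Default per-caller simulation profiles
#'
#' Sensitivities mirror the heterogeneity of real short-read callers --
#' one balanced high-F1 profile (manta), high-precision/low-recall
#' profiles (tardis), an insertion-weak read-pair caller (breakdancer,
#' lumpy), an insertion specialist (insurveyor) -- and false-positive
#' rates per Mb scaled to yield comparable FP:TP proportions on the
#' default 120 Mb simulated genome. Jitter SDs (bp) are small for
#' split-read/assembly callers and large for read-pair-only callers.
#'
#' @return Named list of profiles: `sens` (per svtype), `jitter_sd`,
#'   `fp_per_mb` (per svtype).
#' @export
default_caller_profiles <- function() {
  prof <- function(sens_del, sens_ins, jitter, fp_del, fp_ins)
    list(sens = c(DEL = sens_del, INS = sens_ins), jitter_sd = jitter,
         fp_per_mb = c(DEL = fp_del, INS = fp_ins))
  list(
    breakdancer = prof(0.22, 0.005, 80, 2.4, 0.07),
    delly       = prof(0.56, 0.07,  15, 1.65, 0.14),
    lumpy       = prof(0.51, 0.004, 25, 0.54, 1.76),
    manta       = prof(0.65, 0.11,   5, 0.40, 0.18),
    pindel      = prof(0.65, 0.20,   3, 2.07, 21.4),
    tardis      = prof(0.32, 0.08,  30, 1.16, 15.1),
    insurveyor  = prof(0,    0.35,   5, 0,    0.42)
  )
}

#' Simulation configuration
#'
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of it.
#' @param contigs Named numeric vector of contig lengths in bp (names are
#'   autosome-style, no "chr").
#' @param n_truth Named count of truth SVs per type.
#' @param svlen_range Truth/FP SV lengths are log-uniform over this range.
#' @param caller_profiles See [default_caller_profiles()].
#' @param stats [sequencing_stats()] the emulated sample was "sequenced"
#'   at; coverage-kind metrics scale with `mean_coverage`.
#' @param dup_frac Fraction of emitted insertion records written with
#'   SVTYPE=DUP by callers whose dialect knows duplications (exercises
#'   DUP-to-INS folding).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              contigs = c(`1` = 6e7, `2` = 6e7),
                              n_truth = c(DEL = 2000L, INS = 2000L),
                              svlen_range = c(50L, 10000L),
                              caller_profiles = default_caller_profiles(),
                              stats = sequencing_stats(35, 150),
                              dup_frac = 0.15) {
  stopifnot(!is.null(names(contigs)), all(contigs > 0))
  if (svlen_range[1] < 50) stopf("svlen_range must start at >= 50 bp")
  for (p in caller_profiles) {
    stopifnot(all(p$sens >= 0 & p$sens <= 1), p$jitter_sd >= 0,
              all(p$fp_per_mb >= 0))
  }
  structure(list(seed = as.integer(seed), contigs = contigs,
                 n_truth = n_truth, svlen_range = svlen_range,
                 caller_profiles = caller_profiles, stats = stats,
                 dup_frac = dup_frac),
            class = "simulation_config")
}

rsvlen <- function(n, range) {
  as.integer(round(exp(stats::runif(n, log(range[1]), log(range[2])))))
}

#' Simulate a truth set
#'
#' Places `n_truth[svtype]` records per type uniformly over the contigs
#' (probability proportional to contig length); deletion intervals are
#' non-overlapping (rejection sampling). Deterministic given the seed.
#'
#' @param config A [simulation_config()].
#' @return data.table with `id`, `chrom`, `pos`, `end`, `svtype`,
#'   `svlen`, `genotype`.
#' @export
simulate_truth_set <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  out <- list()
  for (svt in c("DEL", "INS")) {
    n <- config$n_truth[[svt]] %||% 0L
    if (is.na(n) || n == 0L) next
    svlen <- rsvlen(n, config$svlen_range)
    if (svt == "DEL" && sum(as.numeric(svlen)) * 3 > sum(config$contigs))
      stopf("contigs too small to place %d non-overlapping deletions", n)
    chrom <- sample(names(config$contigs), n, replace = TRUE,
                    prob = config$contigs / sum(config$contigs))
    pos <- integer(n)
    for (ct in unique(chrom)) {
      w <- which(chrom == ct)
      lim <- config$contigs[[ct]]
      p <- as.integer(floor(stats::runif(length(w), 1, lim - svlen[w])))
      if (svt == "DEL") {
        # resample overlapping intervals until disjoint
        for (iter in 1:1000) {
          o <- order(p)
          s <- p[o]; e <- p[o] + svlen[w][o] - 1L
          bad_sorted <- which(s[-1] <= e[-length(e)] )
          if (!length(bad_sorted)) break
          bad <- o[bad_sorted + 1L]
          p[bad] <- as.integer(floor(stats::runif(length(bad), 1,
                                                  lim - svlen[w][bad])))
          if (iter == 1000) stopf("could not place non-overlapping deletions")
        }
      }
      pos[w] <- p
    }
    end <- if (svt == "DEL") pos + svlen - 1L else pos
    out[[svt]] <- data.table::data.table(
      id = sprintf("truth_%s_%05d", svt, seq_len(n)),
      chrom = chrom, pos = pos, end = end, svtype = svt, svlen = svlen,
      genotype = sample(c("het", "hom_alt"), n, replace = TRUE,
                        prob = c(2 / 3, 1 / 3)))
  }
  res <- data.table::rbindlist(out)
  if (nrow(res)) data.table::setorder(res, chrom, pos)
  res[]
}

# TP/FP-conditional metric draws; coverage-kind metrics scale with mean
# coverage, read-length-kind with read length. homlen and ce carry no
# class signal on purpose (not every registered metric is informative).
sim_metric_values <- function(metric, kind, is_tp, stats) {
  n <- length(is_tp)
  cov <- stats$mean_coverage; rl <- stats$read_length
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  if (metric == "precise_flag") return(rep(NA_real_, n))  # set from `precise`
  if (kind == "coverage")
    return(stats::rpois(n, ifelse(is_tp, 0.45, 0.15) * cov))
  if (kind == "read_length")
    return(pmax(0, stats::rnorm(n, ifelse(is_tp, 0.02, 0.08) * rl,
                                ifelse(is_tp, 0.01, 0.02) * rl)))
  if (metric %in% c("vaf", "ab", "allele_frac", "alt_ratio", "rdratio"))
    return(clip01(stats::rnorm(n, ifelse(is_tp, 0.5, 0.15), 0.1)))
  if (metric == "homlen") return(stats::rpois(n, 3))
  if (metric == "ce") return(pmax(0, stats::rnorm(n, 1.5, 0.4)))
  # quality-like scores (qual, gq, mapq, cnvl, anchor_score, ...)
  pmin(pmax(stats::rnorm(n, ifelse(is_tp, 55, 25), 10), 0), 99)
}

#' Simulate per-caller call sets from a truth set
#'
#' Each caller detects each truth record independently with its
#' type-specific sensitivity; detected calls get zero-mean rounded
#' Gaussian breakpoint jitter and TP-conditional metric draws. False
#' positives arrive as a Poisson process at `fp_per_mb` per Mb with
#' FP-conditional metrics and truth-like lengths (so SV length alone
#' cannot separate the classes). Optionally writes one VCF per caller in
#' its dialect.
#'
#' @param truth Output of [simulate_truth_set()].
#' @param config The same [simulation_config()].
#' @param out_dir Optional directory; when given, per-caller VCFs, a
#'   `truth.vcf`, a `ledger.tsv` and a `stats.json` are written there.
#' @param dialects Dialect registry used for VCF emission.
#' @return List: `calls_by_caller` (named list of call tables with metric
#'   columns), `ledger` (data.table caller/id/svtype/origin/pos jitter
#'   bookkeeping), `files` (named VCF paths or NULL).
#' @export
simulate_caller_outputs <- function(truth, config, out_dir = NULL,
                                    dialects = default_dialects()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  genome_mb <- sum(config$contigs) / 1e6
  calls_by_caller <- list()
  ledger <- list()

  for (cl in sort(names(config$caller_profiles))) {
    profile <- config$caller_profiles[[cl]]
    dialect <- dialects[[cl]]
    if (is.null(dialect)) stopf("no dialect registered for caller '%s'", cl)
    pieces <- list()
    for (svt in c("DEL", "INS")) {
      if (!svt %in% dialect$svtype_map) next
      sens <- profile$sens[[svt]] %||% 0
      tr <- truth[svtype == svt]
      # true detections
      det <- tr[stats::runif(.N) < sens]
      if (nrow(det)) {
        dp <- as.integer(round(stats::rnorm(nrow(det), 0, profile$jitter_sd)))
        de <- as.integer(round(stats::rnorm(nrow(det), 0, profile$jitter_sd)))
        npos <- pmax(det$pos + dp, 1L)
        if (svt == "DEL") {
          nend <- pmax(det$end + de, npos + 49L)
          nlen <- nend - npos + 1L
        } else {
          nend <- npos
          nlen <- pmax(det$svlen + de, 50L)
        }
        flip <- stats::runif(nrow(det)) < 0.05
        gt <- ifelse(flip, ifelse(det$genotype == "het", "hom_alt", "het"),
                     det$genotype)
        pieces[[paste0(svt, "_tp")]] <- data.table::data.table(
          chrom = det$chrom, pos = npos, end = nend, svtype = svt,
          svlen = nlen, genotype = gt, is_tp = TRUE, origin = det$id)
      }
      # false positives
      nfp <- stats::rpois(1, profile$fp_per_mb[[svt]] * genome_mb)
      if (nfp > 0) {
        flen <- rsvlen(nfp, config$svlen_range)
        fchrom <- sample(names(config$contigs), nfp, replace = TRUE,
                         prob = config$contigs / sum(config$contigs))
        fpos <- as.integer(floor(stats::runif(
          nfp, 1, config$contigs[fchrom] - flen)))
        pieces[[paste0(svt, "_fp")]] <- data.table::data.table(
          chrom = fchrom, pos = fpos,
          end = if (svt == "DEL") fpos + flen - 1L else fpos,
          svtype = svt, svlen = flen,
          genotype = sample(c("het", "hom_alt"), nfp, replace = TRUE,
                            prob = c(0.85, 0.15)),
          is_tp = FALSE, origin = "FP")
      }
    }
    calls <- data.table::rbindlist(pieces)
    if (is.null(calls) || nrow(calls) == 0L) {
      calls_by_caller[[cl]] <- NULL
      next
    }
    data.table::setorder(calls, chrom, pos, end)
    calls[, id := sprintf("%s_%06d", cl, seq_len(.N))]
    calls[, caller := cl]
    calls[, precise := stats::runif(.N) < ifelse(is_tp, 0.9, 0.6)]
    calls[, filter_pass := TRUE]
    for (k in seq_len(nrow(dialect$metrics))) {
      sp <- dialect$metrics[k, ]
      calls[, (sp$metric) := sim_metric_values(sp$metric, sp$kind, is_tp,
                                               config$stats)]
    }
    if ("precise_flag" %in% names(calls))
      calls[, precise_flag := as.numeric(precise)]

    ledger[[cl]] <- calls[, .(caller, id, svtype, origin, is_tp)]
    calls[, `:=`(is_tp = NULL, origin = NULL)]
    data.table::setcolorder(calls, sv_call_columns)
    calls_by_caller[[cl]] <- calls[]
  }

  ledger <- data.table::rbindlist(ledger)
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (cl in names(calls_by_caller)) {
      path <- file.path(out_dir, paste0(cl, ".vcf"))
      write_caller_vcf(calls_by_caller[[cl]], dialects[[cl]], path,
                       contigs = config$contigs, dup_frac = config$dup_frac,
                       dup_seed = config$seed + 2L)
      files[cl] <- path
    }
    tpath <- file.path(out_dir, "truth.vcf")
    write_caller_vcf(truth, dialects$truth, tpath, contigs = config$contigs)
    files["truth"] <- tpath
    data.table::fwrite(ledger, file.path(out_dir, "ledger.tsv"), sep = "\t")
    jsonlite::write_json(
      list(seed = config$seed, contigs = as.list(config$contigs),
           mean_coverage = config$stats$mean_coverage,
           read_length = config$stats$read_length),
      file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA)
  }
  list(calls_by_caller = calls_by_caller, ledger = ledger, files = files)
}

#' Emit a call table as a VCF in a caller's dialect
#'
#' Serializes canonical calls back into the caller's VCF conventions:
#' signed SVLEN for deletions where the caller signs them, "chr" contig
#' prefixes where the caller uses them, IMPRECISE flags, metric values in
#' INFO/FORMAT/QUAL as registered, and (for callers whose dialect maps
#' DUP) a fraction of insertions written as SVTYPE=DUP.
#'
#' @param calls Canonical call table (metric columns optional).
#' @param dialect The [caller_dialect()] to write in.
#' @param path Output path.
#' @param contigs Optional named contig lengths for `##contig` headers.
#' @param dup_frac Fraction of INS records written as DUP (only if the
#'   dialect maps DUP).
#' @param dup_seed Seed for the DUP subsample (kept separate so emission
#'   does not perturb the main simulation stream).
#' @return `path`, invisibly.
#' @export
write_caller_vcf <- function(calls, dialect, path, contigs = NULL,
                             dup_frac = 0, dup_seed = 1L) {
  stopifnot(inherits(dialect, "caller_dialect"))
  calls <- data.table::as.data.table(calls)
  if (!"precise" %in% names(calls)) calls[, precise := TRUE]
  if (!"filter_pass" %in% names(calls)) calls[, filter_pass := TRUE]
  if (!"genotype" %in% names(calls)) calls[, genotype := "missing"]
  fmt_num <- function(x) {
    s <- vapply(x, function(v) {
      if (is.na(v)) "." else format(v, scientific = FALSE, trim = TRUE,
                                    digits = 10)
    }, character(1))
    s
  }
  info_specs <- dialect$metrics[dialect$metrics$source == "INFO", ]
  fmt_specs <- dialect$metrics[dialect$metrics$source == "FORMAT", ]
  flag_specs <- dialect$metrics[dialect$metrics$source == "FLAG", ]
  qual_specs <- dialect$metrics[dialect$metrics$source == "QUAL", ]

  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=%s (simulated)", dialect$caller))
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s%s,length=%d>",
                          if (dialect$chr_prefix) "chr" else "",
                          names(contigs), as.integer(contigs)))
  hdr <- c(hdr,
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
    '##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description="Imprecise breakpoints">',
    sprintf('##INFO=<ID=%s,Number=0,Type=Flag,Description="%s">',
            flag_specs$field, flag_specs$metric),
    sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="%s">',
            info_specs$field, info_specs$metric),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    sprintf('##FORMAT=<ID=%s,Number=1,Type=Float,Description="%s">',
            fmt_specs$field, fmt_specs$metric),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE")

  if (nrow(calls) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  data.table::setorder(calls, chrom, pos, end)

  vcf_svtype <- calls$svtype
  if ("DUP" %in% names(dialect$svtype_map) && dup_frac > 0) {
    ins_idx <- which(calls$svtype == "INS")
    if (length(ins_idx)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(dup_seed)
      as_dup <- sample(ins_idx, floor(length(ins_idx) * dup_frac))
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      vcf_svtype[as_dup] <- "DUP"
    }
  }

  chrom_out <- paste0(if (dialect$chr_prefix) "chr" else "", calls$chrom)
  svlen_out <- if (dialect$signed_svlen)
    ifelse(calls$svtype == "DEL", -calls$svlen, calls$svlen) else calls$svlen
  qual_out <- if (nrow(qual_specs) && qual_specs$metric[1] %in% names(calls))
    fmt_num(calls[[qual_specs$metric[1]]]) else rep(".", nrow(calls))

  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               missing = "./.")[calls$genotype]
  gt_code[is.na(gt_code)] <- "./."

  recs <- vapply(seq_len(nrow(calls)), function(i) {
    info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d", vcf_svtype[i],
                    calls$end[i], svlen_out[i])
    if (!calls$precise[i]) info <- paste0(info, ";IMPRECISE")
    for (k in seq_len(nrow(flag_specs)))
      if (isTRUE(calls[[flag_specs$metric[k]]][i] >= 0.5))
        info <- paste0(info, ";", flag_specs$field[k])
    for (k in seq_len(nrow(info_specs))) {
      v <- calls[[info_specs$metric[k]]][i]
      if (!is.null(v) && !is.na(v))
        info <- paste0(info, ";", info_specs$field[k], "=", fmt_num(v))
    }
    fmt_keys <- c("GT", fmt_specs$field)
    fmt_vals <- c(gt_code[i], vapply(fmt_specs$metric, function(m)
      fmt_num(calls[[m]][i]), character(1)))
    paste(chrom_out[i], calls$pos[i], calls$id[i], "N",
          sprintf("<%s>", vcf_svtype[i]), qual_out[i],
          if (calls$filter_pass[i]) "PASS" else "LowQual", info,
          paste(fmt_keys, collapse = ":"), paste(fmt_vals, collapse = ":"),
          sep = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Label consensus calls against the simulated truth
#'
#' Applies the same matching protocol used for benchmarking
#' ([match_to_truth()]) to derive TP/FP training labels for consensus
#' calls.
#'
#' @param consensus Output of [merge_calls()] on simulated call sets.
#' @param truth The simulated truth set.
#' @param params A [match_params()].
#' @return Logical vector, one label per consensus row.
#' @export
label_consensus <- function(consensus, truth, params = match_params()) {
  if (nrow(consensus) == 0L) return(logical(0))
  mr <- match_to_truth(consensus, truth, params)
  consensus$id %in% mr$pairs$call_id
}
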