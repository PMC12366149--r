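# Caller dialect registry: which VCF fields each supported caller writes,
# how its SV type codes map onto {DEL, INS}, and which quality metrics are
# harvested from which field (INFO key, FORMAT key, QUAL column, or INFO
# flag) together with the normalization each metric needs downstream.
#
# The exact per-caller field sets are configuration, not hard-coded truth:
# callers change their VCF output between versions, and deployments may
# want to register additional metrics. `caller_dialect()` builds a dialect
# from scratch; `default_dialects()` ships a registry for the seven
# supported callers plus the consensus format this package writes.

#' Construct a caller dialect
#'
#' A dialect describes one caller's VCF output: the mapping of its SV type
#' codes to the two supported classes (duplications fold into `INS`), and a
#' metric table declaring which VCF fields are harvested as quality metrics
#' and how each is normalized before entering the feature matrix.
#'
#' @param caller Caller identifier (lower case by convention).
#' @param svtype_map Named character vector mapping the caller's SVTYPE
#'   codes to `"DEL"` or `"INS"` (e.g. `c(DEL = "DEL", DUP = "INS")`).
#' @param metrics `data.frame` with columns `field` (VCF key), `source`
#'   (one of `"INFO"`, `"FORMAT"`, `"QUAL"`, `"FLAG"`), `metric` (unique
#'   metric name) and `kind` (normalization: `"coverage"`, `"read_length"`
#'   or `"none"`). `FLAG` metrics read presence of an INFO flag as 1/0.
#' @param pass_only If `TRUE` only `FILTER == PASS` (or `.`) records are
#'   treated as high-confidence calls and survive parsing with
#'   `drop_fail = TRUE`.
#' @param signed_svlen If `TRUE` the caller writes negative SVLEN for
#'   deletions; absolute values are taken either way.
#' @param chr_prefix If `TRUE` the caller writes "chr"-prefixed contig
#'   names; parsing strips the prefix in all cases, the flag only matters
#'   when emitting VCFs in this dialect (e.g. from the simulator).
#' @return An object of class `caller_dialect`.
#' @export
caller_dialect <- function(caller, svtype_map, metrics,
                           pass_only = FALSE, signed_svlen = FALSE,
                           chr_prefix = FALSE) {
  stopifnot(is.character(caller), length(caller) == 1L)
  metrics <- as.data.frame(metrics, stringsAsFactors = FALSE)
  needed <- c("field", "source", "metric", "kind")
  if (!all(needed %in% names(metrics)))
    stopf("dialect metrics table needs columns: %s", paste(needed, collapse = ", "))
  if (anyDuplicated(metrics$metric))
    stopf("duplicate metric names in dialect for caller '%s'", caller)
  if (!all(metrics$source %in% c("INFO", "FORMAT", "QUAL", "FLAG")))
    stopf("metric source must be INFO, FORMAT, QUAL or FLAG")
  if (!all(metrics$kind %in% c("coverage", "read_length", "none")))
    stopf("metric kind must be coverage, read_length or none")
  if (!all(svtype_map %in% c("DEL", "INS")))
    stopf("svtype_map values must be DEL or INS")
  structure(
    list(caller = caller, svtype_map = svtype_map, metrics = metrics,
         pass_only = pass_only, signed_svlen = signed_svlen,
         chr_prefix = chr_prefix),
    class = "caller_dialect"
  )
}

mspec <- function(...) {
  # rows of (field, source, metric, kind)
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(field = r[[1]], source = r[[2]], metric = r[[3]], kind = r[[4]],
               stringsAsFactors = FALSE)))
}

#' Default dialect registry
#'
#' Dialects for the seven supported short-read SV callers (BreakDancer,
#' Delly, LUMPY, Manta, Pindel, TARDIS, INSurVeyor) plus `"consensus"`
#' (this package's own output format, QUAL = prediction probability) and
#' `"truth"` (a minimal dialect for truth-set VCFs carrying no metrics).
#'
#' Metric sets are per-caller configuration covering the usual evidence
#' classes: supporting read-pair and split-read counts and local depth
#' (normalized by mean coverage), per-read length scales such as average
#' edit distance of insertion-supporting stable reads (normalized by read
#' length), and scale-free qualities (QUAL, genotype quality, mapping
#' quality, microhomology length, allele fraction, PRECISE flags).
#' Delly and INSurVeyor are registered with `pass_only = TRUE`
#' (high-confidence calls only); toggle per caller by rebuilding the
#' dialect.
#'
#' @return Named list of [caller_dialect()] objects.
#' @export
default_dialects <- function() {
  d <- list()

  d$breakdancer <- caller_dialect(
    "breakdancer", c(DEL = "DEL", INS = "INS"),
    mspec(list("DP", "INFO", "supp_pairs", "coverage"),
          list(".", "QUAL", "qual", "none"),
          list("AF", "INFO", "allele_frac", "none")))

  d$delly <- caller_dialect(
    "delly", c(DEL = "DEL", INS = "INS", DUP = "INS"),
    mspec(list("PE", "INFO", "pe", "coverage"),
          list("SR", "INFO", "sr", "coverage"),
          list("MAPQ", "INFO", "mapq", "none"),
          list("SRMAPQ", "INFO", "srmapq", "none"),
          list("CE", "INFO", "ce", "none"),
          list("HOMLEN", "INFO", "homlen", "none"),
          list("GQ", "FORMAT", "gq", "none"),
          list("RC", "INFO", "rc", "coverage"),
          list("RDRATIO", "INFO", "rdratio", "none"),
          list("RV", "INFO", "rv", "coverage")),
    pass_only = TRUE, signed_svlen = TRUE, chr_prefix = TRUE)

  d$lumpy <- caller_dialect(
    "lumpy", c(DEL = "DEL", INS = "INS", DUP = "INS"),
    mspec(list("SU", "INFO", "su", "coverage"),
          list("PE", "INFO", "pe", "coverage"),
          list("SR", "INFO", "sr", "coverage"),
          list("GQ", "FORMAT", "gq", "none"),
          list("AB", "FORMAT", "ab", "none"),
          list("DP", "FORMAT", "dp", "coverage"),
          list(".", "QUAL", "qual", "none")))

  d$manta <- caller_dialect(
    "manta", c(DEL = "DEL", INS = "INS", DUP = "INS"),
    mspec(list(".", "QUAL", "qual", "none"),
          list("GQ", "FORMAT", "gq", "none"),
          list("PR_REF", "FORMAT", "pr_ref", "coverage"),
          list("PR_ALT", "FORMAT", "pr_alt", "coverage"),
          list("SR_REF", "FORMAT", "sr_ref", "coverage"),
          list("SR_ALT", "FORMAT", "sr_alt", "coverage"),
          list("HOMLEN", "INFO", "homlen", "none")),
    signed_svlen = TRUE, chr_prefix = TRUE)

  d$pindel <- caller_dialect(
    "pindel", c(DEL = "DEL", INS = "INS", DUP = "INS"),
    mspec(list("AD_ALT", "FORMAT", "ad_alt", "coverage"),
          list("VAF", "FORMAT", "vaf", "none"),
          list("HOMLEN", "INFO", "homlen", "none")))

  d$tardis <- caller_dialect(
    "tardis", c(DEL = "DEL", INS = "INS", DUP = "INS"),
    mspec(list("CNVL", "INFO", "cnvl", "none"),
          list("RP", "INFO", "rp", "coverage"),
          list("HOMLEN", "INFO", "homlen", "none"),
          list("PRECISE", "FLAG", "precise_flag", "none")))

  d$insurveyor <- caller_dialect(
    "insurveyor", c(INS = "INS", DUP = "INS"),
    mspec(list("SUPPORT", "INFO", "support", "coverage"),
          list("SUPPORT_FWD", "INFO", "support_fwd", "coverage"),
          list("SUPPORT_REV", "INFO", "support_rev", "coverage"),
          list("SPLIT_READS", "INFO", "split_reads", "coverage"),
          list("SPANNING_READS", "INFO", "spanning_reads", "coverage"),
          list("STABLE_DEPTH_LEFT", "INFO", "stable_depth_left", "coverage"),
          list("STABLE_DEPTH_RIGHT", "INFO", "stable_depth_right", "coverage"),
          list("STABLE_READS", "INFO", "stable_reads", "coverage"),
          list("AVG_STABLE_NM", "INFO", "avg_stable_nm", "read_length"),
          list("AVG_CLIP_LEN", "INFO", "avg_clip_len", "read_length"),
          list("MAX_MAPQ", "INFO", "max_mapq", "none"),
          list("AVG_MAPQ", "INFO", "avg_mapq", "none"),
          list("HOMLEN", "INFO", "homlen", "none"),
          list("ANCHOR_SCORE", "INFO", "anchor_score", "none"),
          list("ALT_RATIO", "INFO", "alt_ratio", "none"),
          list("GQ", "FORMAT", "gq", "none"),
          list("PRECISE", "FLAG", "precise_flag", "none"),
          list(".", "QUAL", "qual", "none")),
    pass_only = TRUE, chr_prefix = TRUE)

  # this package's own ranked-consensus output: QUAL is a TP probability
  d$consensus <- caller_dialect(
    "consensus", c(DEL = "DEL", INS = "INS"),
    mspec(list(".", "QUAL", "probability", "none"),
          list("SUPP", "INFO", "supp", "none")))

  d$truth <- caller_dialect(
    "truth", c(DEL = "DEL", INS = "INS", DUP = "INS"),
    mspec(list(".", "QUAL", "qual", "none")))

  d
}

#' Hash of a dialect registry
#'
#' Deterministic hexadecimal digest over the serialized dialect
#' definitions. Stored in model artifacts and consensus VCF headers so that
#' a model trained under one metric configuration refuses to score features
#' built under another.
#'
#' @param dialects Named list of [caller_dialect()] objects (or any
#'   serializable configuration object, e.g. a feature registry).
#' @return Character scalar, 8 hex digits.
#' @export
dialect_registry_hash <- function(dialects) {
  txt <- paste(utils::capture.output(utils::str(dialects, digits.d = 12)),
               collapse = "\n")
  # 31-polynomial rolling hash mod 2^31-1; no external digest dependency
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
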