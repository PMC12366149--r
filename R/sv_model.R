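# VCF parsing, SV-call filtering and consensus VCF output.
#
# Internally one caller's call set is a data.table with the canonical
# columns (id, caller, chrom, pos, end, svtype, svlen, genotype, precise,
# filter_pass) followed by one numeric column per registered metric.
# Coordinates follow VCF convention: 1-based POS, inclusive END. Contig
# names are stored without "chr" prefix. Missing metric values are NA,
# never 0: a caller that does not report a value stays distinguishable
# from one reporting zero.

#' Sequencing statistics required for metric normalization
#'
#' @param mean_coverage Genome-wide mean sequencing depth (reads per base),
#'   e.g. 35.
#' @param read_length Read length in bp, e.g. 150.
#' @return Object of class `sequencing_stats`.
#' @export
sequencing_stats <- function(mean_coverage, read_length) {
  if (!is.numeric(mean_coverage) || length(mean_coverage) != 1L ||
      !is.finite(mean_coverage) || mean_coverage <= 0)
    stopf("mean_coverage must be a single positive number")
  if (!is.numeric(read_length) || length(read_length) != 1L ||
      !is.finite(read_length) || read_length <= 0)
    stopf("read_length must be a single positive number")
  structure(list(mean_coverage = as.numeric(mean_coverage),
                 read_length = as.numeric(read_length)),
            class = "sequencing_stats")
}

#' Parse one caller's SV VCF under its dialect
#'
#' Reads a VCF 4.x file (plain or bgzipped) and returns the caller's
#' deletion and insertion records in the package's canonical call table.
#' Duplications are folded into `INS` at parse time, permanently. SVLEN is
#' taken as `abs(SVLEN)` when present, otherwise `END - POS + 1` for
#' deletions; insertion records without END get `end = pos`. Metric values
#' that cannot be parsed as numbers become `NA` (missing), never 0.
#'
#' @param path VCF file path.
#' @param dialect A [caller_dialect()]; names the caller and its metrics.
#' @param drop_fail Drop records failing the caller's high-confidence rule
#'   (`FILTER != PASS/.`) when the dialect has `pass_only = TRUE`.
#'   The `filter_pass` column is recorded either way.
#' @return data.table of calls (possibly zero rows) with one column per
#'   registered metric.
#' @export
parse_caller_vcf <- function(path, dialect, drop_fail = TRUE) {
  if (!inherits(dialect, "caller_dialect"))
    stopf("unknown caller: 'dialect' must be a caller_dialect object")
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stopf("malformed VCF '%s': %s",
                                          path, conditionMessage(e)))
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  empty <- empty_sv_calls()
  for (m in dialect$metrics$metric) empty[, (m) := numeric(0)]
  if (is.null(fix) || nrow(fix) == 0L) return(empty[])

  info <- fix[, "INFO"]
  info_get <- function(key) {
    # scalar INFO values as character; NA when absent
    vcfR::extract.info(v, element = key)
  }
  num <- function(x) suppressWarnings(as.numeric(x))

  svtype_raw <- info_get("SVTYPE")
  svtype <- unname(dialect$svtype_map[svtype_raw])
  keep <- !is.na(svtype)

  pos <- as.integer(fix[, "POS"])
  endv <- num(info_get("END"))
  svlen_raw <- num(info_get("SVLEN"))
  svlen <- abs(svlen_raw)

  # fill in the member of the (END, SVLEN) pair the caller omitted
  is_del <- !is.na(svtype) & svtype == "DEL"
  svlen[is.na(svlen) & is_del] <-
    endv[is.na(svlen) & is_del] - pos[is.na(svlen) & is_del] + 1
  endv[is.na(endv)] <- ifelse(is_del[is.na(endv)],
                              pos[is.na(endv)] + svlen[is.na(endv)] - 1,
                              pos[is.na(endv)])
  is_ins <- !is.na(svtype) & svtype == "INS"
  endv[is_ins & (is.na(endv) | endv < pos)] <- pos[is_ins & (is.na(endv) | endv < pos)]

  filt <- fix[, "FILTER"]
  filter_pass <- is.na(filt) | filt %in% c("PASS", ".")
  precise <- !grepl("(^|;)IMPRECISE($|;|=)", info)

  gt_raw <- if (ncol(v@gt) >= 2L) vcfR::extract.gt(v, element = "GT")[, 1L] else
    rep(NA_character_, nrow(fix))
  gt_core <- gsub("\\|", "/", gt_raw)
  genotype <- rep("missing", length(gt_core))
  genotype[gt_core %in% c("0/0")] <- "hom_ref"
  genotype[gt_core %in% c("0/1", "1/0")] <- "het"
  genotype[gt_core %in% c("1/1")] <- "hom_alt"

  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- sprintf("%s_rec%d", dialect$caller, which(no_id))

  calls <- data.table::data.table(
    id = ids, caller = dialect$caller,
    chrom = normalize_chrom(fix[, "CHROM"]),
    pos = pos, end = as.integer(round(endv)), svtype = svtype,
    svlen = as.integer(round(svlen)), genotype = genotype,
    precise = precise, filter_pass = filter_pass
  )

  for (i in seq_len(nrow(dialect$metrics))) {
    sp <- dialect$metrics[i, ]
    val <- switch(sp$source,
      INFO   = num(info_get(sp$field)),
      QUAL   = num(fix[, "QUAL"]),
      FLAG   = as.numeric(grepl(paste0("(^|;)", sp$field, "($|;)"), info)),
      FORMAT = if (ncol(v@gt) >= 2L)
                 num(vcfR::extract.gt(v, element = sp$field)[, 1L])
               else rep(NA_real_, nrow(fix))
    )
    calls[, (sp$metric) := val]
  }

  calls <- calls[keep & !is.na(svlen) & svlen >= 1]
  if (dialect$pass_only && drop_fail) calls <- calls[filter_pass == TRUE]
  data.table::setorder(calls, chrom, pos, end)
  calls[]
}

#' Filtering configuration for SV call sets
#'
#' @param min_svlen Minimum SV length in bp (default 50, inclusive).
#' @param allowed_types Subset of `c("DEL", "INS")` to keep.
#' @param autosomes_only Keep only contigs 1..22 (after "chr" stripping).
#' @param include_regions Optional region table (`chrom`, `start`, `end`,
#'   1-based inclusive, as returned by [read_bed_regions()]); a call is
#'   kept if its start position falls in a region.
#' @param require_nonref_genotype Keep only heterozygous or homozygous-alt
#'   calls (drops `hom_ref` and `missing`).
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(min_svlen = 50L,
                          allowed_types = c("DEL", "INS"),
                          autosomes_only = TRUE,
                          include_regions = NULL,
                          require_nonref_genotype = FALSE) {
  if (min_svlen < 1) stopf("min_svlen must be >= 1")
  stopifnot(all(allowed_types %in% c("DEL", "INS")))
  structure(list(min_svlen = as.integer(min_svlen),
                 allowed_types = allowed_types,
                 autosomes_only = isTRUE(autosomes_only),
                 include_regions = include_regions,
                 require_nonref_genotype = isTRUE(require_nonref_genotype)),
            class = "filter_config")
}

#' Filter an SV call table
#'
#' Applies the configured predicates (length, type, autosomes, regions,
#' genotype). Output is a subset of the input with order preserved;
#' filtering is idempotent.
#'
#' @param calls Call table from [parse_caller_vcf()].
#' @param config A [filter_config()].
#' @return Filtered call table.
#' @export
filter_sv_calls <- function(calls, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (nrow(calls) == 0L) return(calls)
  keep <- calls$svlen >= config$min_svlen &
    calls$svtype %in% config$allowed_types
  if (config$autosomes_only) keep <- keep & calls$chrom %in% AUTOSOMES
  if (config$require_nonref_genotype)
    keep <- keep & calls$genotype %in% c("het", "hom_alt")
  if (!is.null(config$include_regions)) {
    reg <- data.table::as.data.table(config$include_regions)
    inreg <- logical(nrow(calls))
    for (k in seq_len(nrow(reg)))
      inreg <- inreg | (calls$chrom == reg$chrom[k] &
                          calls$pos >= reg$start[k] & calls$pos <= reg$end[k])
    keep <- keep & inreg
  }
  calls[keep]
}

#' Read a BED file of regions
#'
#' Standard BED: 0-based half-open intervals, first three columns
#' chrom/start/end. Returned as 1-based inclusive intervals with "chr"
#' prefixes stripped, the coordinate convention used everywhere in this
#' package.
#'
#' @param path BED file path.
#' @return data.table with columns `chrom`, `start`, `end`.
#' @export
read_bed_regions <- function(path) {
  if (!file.exists(path)) stopf("BED not found: %s", path)
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end"),
                           colClasses = c("character", "integer", "integer"))
  data.table::data.table(chrom = normalize_chrom(bed$chrom),
                         start = bed$start + 1L, end = bed$end)
}

#' Write a scored consensus call set as VCF 4.2
#'
#' One record per consensus call, sorted by (chrom, pos). QUAL carries the
#' classifier's TP probability (fixed 4 decimal digits); INFO carries
#' SVTYPE, END, SVLEN, SUPP (number of distinct supporting callers),
#' CALLERS (comma-joined caller names, sorted) and MEMBER_IDS
#' (comma-joined `caller:record_id` of every contributing call), so every
#' consensus entry can be traced back to the standalone VCFs.
#'
#' @param consensus Consensus table from [merge_calls()], with a
#'   `probability` column in `[0, 1]` (absent probabilities default to 0).
#' @param path Output file path.
#' @param registry_hash Optional dialect/registry hash for the header.
#' @param merge_params Optional [merge_params()] echoed into the header.
#' @return `path`, invisibly.
#' @export
write_consensus_vcf <- function(consensus, path, registry_hash = NULL,
                                merge_params = NULL) {
  cs <- data.table::as.data.table(consensus)
  if (!"probability" %in% names(cs)) cs[, probability := 0]
  if (nrow(cs) && (any(!is.finite(cs$probability)) ||
                   any(cs$probability < 0 | cs$probability > 1)))
    stopf("consensus probabilities must lie in [0, 1]")
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=svmeld-%s", as.character(utils::packageVersion("svmeld"))),
    if (!is.null(registry_hash)) sprintf("##svmeld_registry_hash=%s", registry_hash),
    if (!is.null(merge_params))
      sprintf("##svmeld_merge_params=max_dist=%d,min_support=%d,type_match=%s",
              merge_params$max_dist, merge_params$min_support,
              merge_params$require_type_match),
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV class (DEL or INS; duplications folded into INS)">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="Inclusive end position">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length in bp">',
    '##INFO=<ID=SUPP,Number=1,Type=Integer,Description="Number of distinct supporting callers">',
    '##INFO=<ID=CALLERS,Number=.,Type=String,Description="Supporting caller names">',
    '##INFO=<ID=MEMBER_IDS,Number=.,Type=String,Description="caller:id of contributing standalone calls">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- hdr
  if (nrow(cs)) {
    data.table::setorder(cs, chrom, pos)
    recs <- vapply(seq_len(nrow(cs)), function(i) {
      r <- cs[i]
      paste(r$chrom, r$pos, r$id, "N", sprintf("<%s>", r$svtype),
            formatC(r$probability, format = "f", digits = 4), "PASS",
            sprintf("SVTYPE=%s;END=%d;SVLEN=%d;SUPP=%d;CALLERS=%s;MEMBER_IDS=%s",
                    r$svtype, r$end, r$svlen, r$supp, r$callers, r$member_ids),
            sep = "\t")
    }, character(1))
    lines <- c(lines, recs)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse a consensus VCF written by [write_consensus_vcf()]
#'
#' Round-trip reader used by benchmarking and by downstream tools: recovers
#' coordinates, type, length, probability (QUAL), SUPP, CALLERS and
#' MEMBER_IDS.
#'
#' @param path Consensus VCF path.
#' @return data.table with consensus columns and `probability`.
#' @export
read_consensus_vcf <- function(path) {
  calls <- parse_caller_vcf(path, default_dialects()$consensus)
  if (nrow(calls) == 0L) {
    calls[, `:=`(callers = character(0), member_ids = character(0))]
    return(calls[])
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  calls[, callers := vcfR::extract.info(v, "CALLERS")]
  calls[, member_ids := vcfR::extract.info(v, "MEMBER_IDS")]
  calls[, supp := as.integer(supp)]
  calls[]
}
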