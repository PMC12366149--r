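# shared small helpers

AUTOSOMES <- as.character(1:22)

#' Normalize a contig name for comparison
#'
#' Strips a leading "chr" prefix so that GRCh37-style ("1") and
#' GRCh38-style ("chr1") contig names compare equal.
#'
#' @param chrom Character vector of contig names.
#' @return Character vector without "chr" prefix.
#' @export
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed report tables use
#' conventional half-up rounding instead. Internal computations always keep
#' full precision; this is applied at report time only.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# lower median: for even n the smaller of the two central order statistics
lower_median <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1) / 2)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# canonical empty SV call table (parse/filter/merge all speak this layout;
# metric columns, when present, follow these)
sv_call_columns <- c("id", "caller", "chrom", "pos", "end", "svtype",
                     "svlen", "genotype", "precise", "filter_pass")

empty_sv_calls <- function(caller = character(0)) {
  data.table::data.table(
    id = character(0), caller = character(0), chrom = character(0),
    pos = integer(0), end = integer(0), svtype = character(0),
    svlen = integer(0), genotype = character(0), precise = logical(0),
    filter_pass = logical(0)
  )
}
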