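# Multi-caller consensus merging.
#
# Calls of the same type on the same contig are linked when BOTH
# breakpoints lie within max_dist of each other; clusters are the
# connected components (transitive closure) of that link relation, so the
# result is deterministic and independent of input order. Requiring both
# breakpoints prevents a short deletion from chaining onto a long one that
# shares a single breakpoint.

#' Merge parameters
#'
#' @param max_dist Maximum breakpoint distance in bp for linking two calls;
#'   both `|pos1 - pos2|` and `|end1 - end2|` must be `<= max_dist`.
#' @param require_type_match Only link calls of identical SV type.
#' @param min_support Minimum number of distinct supporting callers for a
#'   consensus call to be reported. The default 1 keeps single-caller
#'   calls: the classifier scores them instead of discarding them, which is
#'   the point of quality-aware meta-calling.
#' @param min_svlen Minimum SV length in bp applied before merging.
#' @return Object of class `merge_params`.
#' @export
merge_params <- function(max_dist = 1000L, require_type_match = TRUE,
                         min_support = 1L, min_svlen = 50L) {
  if (max_dist < 0) stopf("max_dist must be >= 0")
  if (min_support < 1) stopf("min_support must be >= 1")
  structure(list(max_dist = as.integer(max_dist),
                 require_type_match = isTRUE(require_type_match),
                 min_support = as.integer(min_support),
                 min_svlen = as.integer(min_svlen)),
            class = "merge_params")
}

# enumerate linked pairs within one (chrom [, svtype]) group, sorted by pos
link_pairs <- function(pos, end, max_dist) {
  n <- length(pos)
  if (n < 2L) return(NULL)
  from <- integer(0); to <- integer(0)
  j_hi <- 1L
  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    while (j <= n && pos[j] - pos[i] <= max_dist) {
      if (abs(end[j] - end[i]) <= max_dist) {
        from <- c(from, i); to <- c(to, j)
      }
      j <- j + 1L
    }
  }
  if (length(from)) cbind(from, to) else NULL
}

#' Merge same-type SV calls from multiple callers into consensus calls
#'
#' Clusters are connected components of the pairwise link relation (same
#' contig, same type when required, both breakpoints within `max_dist`).
#' Representative `pos`, `end` and `svlen` are member-wise lower medians
#' (the smaller central order statistic on even counts), which is robust
#' and deterministic. When one caller contributes several calls to a
#' cluster, the one closest to the representative (smallest
#' `|pos diff| + |end diff|`, ties by record id) becomes that caller's
#' feature source; all member ids are retained.
#'
#' @param calls_by_caller Named list of call tables (one per caller), as
#'   returned by [parse_caller_vcf()] + [filter_sv_calls()].
#' @param params A [merge_params()].
#' @return data.table of consensus calls sorted by (chrom, pos): columns
#'   `id`, `chrom`, `pos`, `end`, `svtype`, `svlen`, `supp`, `callers`
#'   (comma-joined, sorted), `member_ids` (comma-joined `caller:id`) and
#'   `members` (list column of per-member tables with `caller`, `id`,
#'   `pos`, `end`, `svlen` and logical `rep`).
#' @export
merge_calls <- function(calls_by_caller, params = merge_params()) {
  stopifnot(inherits(params, "merge_params"))
  if (is.null(names(calls_by_caller)) && length(calls_by_caller))
    stopf("calls_by_caller must be a named list (caller -> call table)")
  all_calls <- data.table::rbindlist(
    lapply(names(calls_by_caller), function(cl) {
      x <- data.table::as.data.table(calls_by_caller[[cl]])
      if (nrow(x) == 0L) return(NULL)
      x <- x[, .(id, chrom, pos, end, svtype, svlen)]
      x[, caller := cl]
      x
    }), use.names = TRUE)
  out_cols <- c("id", "chrom", "pos", "end", "svtype", "svlen", "supp",
                "callers", "member_ids")
  if (is.null(all_calls) || nrow(all_calls) == 0L) {
    empty <- data.table::data.table(
      id = character(0), chrom = character(0), pos = integer(0),
      end = integer(0), svtype = character(0), svlen = integer(0),
      supp = integer(0), callers = character(0), member_ids = character(0),
      members = list())
    return(empty[])
  }
  all_calls <- all_calls[svlen >= params$min_svlen]

  # stable canonical order: clusters and representatives are then
  # independent of the order callers or records were supplied in
  data.table::setorder(all_calls, chrom, svtype, pos, end, caller, id)
  grp_keys <- if (params$require_type_match) c("chrom", "svtype") else "chrom"
  grp <- all_calls[, .(idx = list(.I)), by = grp_keys]

  cluster_id <- integer(nrow(all_calls))
  next_cluster <- 0L
  for (g in seq_len(nrow(grp))) {
    idx <- grp$idx[[g]]
    ed <- link_pairs(all_calls$pos[idx], all_calls$end[idx], params$max_dist)
    if (is.null(ed)) {
      comp <- seq_along(idx)
    } else {
      gph <- igraph::make_graph(t(ed), n = length(idx), directed = FALSE)
      comp <- igraph::components(gph)$membership
    }
    cluster_id[idx] <- next_cluster + comp
    next_cluster <- next_cluster + max(comp)
  }
  all_calls[, cluster := cluster_id]

  # cluster ids are globally unique, so grouping by cluster alone is safe;
  # with type matching on, clusters are type-pure by construction, else the
  # modal type (ties: alphabetically first) labels the consensus
  cons <- all_calls[, {
    rp <- lower_median(pos); re <- lower_median(end); rl <- lower_median(svlen)
    tt <- table(svtype)
    svt <- names(tt)[order(-tt, names(tt))][1L]
    d <- abs(pos - rp) + abs(end - re)
    is_rep <- logical(.N)
    for (cl in unique(caller)) {
      w <- which(caller == cl)
      is_rep[w[order(d[w], id[w])[1L]]] <- TRUE
    }
    mem <- data.table::data.table(caller = caller, id = id, pos = pos,
                                  end = end, svlen = svlen, rep = is_rep)
    ucall <- sort(unique(caller))
    .(chrom = chrom[1L], svtype = svt,
      pos = as.integer(rp), end = as.integer(re), svlen = as.integer(rl),
      supp = length(ucall), callers = paste(ucall, collapse = ","),
      member_ids = paste(paste(caller, id, sep = ":"), collapse = ","),
      members = list(mem))
  }, by = .(cluster)]

  cons <- cons[supp >= params$min_support]
  data.table::setorder(cons, chrom, pos, end, svtype)
  cons[, id := sprintf("%s_%05d", svtype, seq_len(.N))]
  cons[, cluster := NULL]
  data.table::setcolorder(cons, c(out_cols, "members"))
  cons[]
}

#' Count consensus calls per SV type
#'
#' The union call set size per type (every consensus entry, including
#' single-caller calls).
#'
#' @param consensus Output of [merge_calls()].
#' @return Named integer vector `c(DEL = ..., INS = ...)`.
#' @export
union_counts <- function(consensus) {
  c(DEL = sum(consensus$svtype == "DEL"),
    INS = sum(consensus$svtype == "INS"))
}
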