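# Feature matrix construction.
#
# Each consensus call becomes one row; each registered (caller, metric)
# pair one column, named caller.metric. A caller that does not support a
# consensus call contributes NA to all of its columns -- the tree learner
# consumes NA natively, so "caller silent" stays distinct from "caller
# reports 0" with no imputation. Coverage-referring metrics are divided by
# mean coverage and read-length-scale metrics by read length, making the
# features dimensionless and portable across sequencing depths and read
# lengths.

DEL_FEATURE_CALLERS <- c("breakdancer", "delly", "lumpy", "manta", "pindel", "tardis")
INS_FEATURE_CALLERS <- c("delly", "insurveyor", "manta", "pindel", "tardis")

#' Normalize one quality metric value
#'
#' @param value Numeric vector of raw metric values (NA passes through).
#' @param kind `"coverage"` (divide by mean coverage), `"read_length"`
#'   (divide by read length) or `"none"` (identity).
#' @param stats A [sequencing_stats()].
#' @return Normalized numeric vector.
#' @export
normalize_metric <- function(value, kind, stats) {
  if (!inherits(stats, "sequencing_stats"))
    stopf("stats must be a sequencing_stats object")
  switch(kind,
         coverage = value / stats$mean_coverage,
         read_length = value / stats$read_length,
         none = value,
         stopf("unknown normalization kind '%s'", kind))
}

#' Feature registry: which caller metrics feed a type-specific model
#'
#' @param svtype `"DEL"` or `"INS"`.
#' @param entries `data.frame` with columns `caller`, `metric`, `kind`.
#'   Deletion registries may draw on BreakDancer, Delly, LUMPY, Manta,
#'   Pindel and TARDIS; insertion registries on Delly, INSurVeyor, Manta,
#'   Pindel and TARDIS (callers with adequate accuracy for the type).
#' @param include_svlen Add the consensus SV length as a feature.
#' @param include_presence Add one 0/1 per-caller presence column.
#' @return Object of class `feature_registry`.
#' @export
feature_registry <- function(svtype, entries, include_svlen = TRUE,
                             include_presence = FALSE) {
  svtype <- match.arg(svtype, c("DEL", "INS"))
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  stopifnot(all(c("caller", "metric", "kind") %in% names(entries)))
  allowed <- if (svtype == "DEL") DEL_FEATURE_CALLERS else INS_FEATURE_CALLERS
  bad <- setdiff(unique(entries$caller), allowed)
  if (length(bad))
    stopf("%s registry may not draw on caller(s): %s", svtype,
          paste(bad, collapse = ", "))
  entries$name <- paste(entries$caller, entries$metric, sep = ".")
  if (anyDuplicated(entries$name)) stopf("duplicate registry entries")
  structure(list(svtype = svtype, entries = entries,
                 include_svlen = isTRUE(include_svlen),
                 include_presence = isTRUE(include_presence)),
            class = "feature_registry")
}

#' Default type-specific feature registries
#'
#' Built from [default_dialects()]: every registered metric of each
#' eligible caller for the SV type, plus SV length. Strand-bias-like
#' metrics are deliberately not registered for insertions. With defaults
#' the deletion registry has 34 caller metrics + svlen = 35 columns and
#' the insertion registry 35 + svlen = 36.
#'
#' @param svtype `"DEL"` or `"INS"`.
#' @param dialects Dialect registry, defaults to [default_dialects()].
#' @return A [feature_registry()].
#' @export
default_feature_registry <- function(svtype, dialects = default_dialects()) {
  svtype <- match.arg(svtype, c("DEL", "INS"))
  pick <- function(caller, metrics = NULL) {
    m <- dialects[[caller]]$metrics
    if (!is.null(metrics)) m <- m[m$metric %in% metrics, ]
    data.frame(caller = caller, metric = m$metric, kind = m$kind,
               stringsAsFactors = FALSE)
  }
  entries <- if (svtype == "DEL") {
    rbind(pick("breakdancer"), pick("delly"), pick("lumpy"),
          pick("manta"), pick("pindel"), pick("tardis"))
  } else {
    rbind(pick("delly", c("pe", "sr", "mapq", "srmapq", "homlen", "gq")),
          pick("insurveyor"),
          pick("manta", c("qual", "gq", "pr_ref", "pr_alt", "sr_alt", "homlen")),
          pick("pindel"),
          pick("tardis", c("cnvl", "rp")))
  }
  feature_registry(svtype, entries, include_svlen = TRUE,
                   include_presence = FALSE)
}

# per-consensus-row representative member id for each caller
rep_id_table <- function(consensus) {
  n <- nrow(consensus)
  memdt <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    m <- consensus$members[[i]]
    if (is.null(m) || nrow(m) == 0L) return(NULL)
    data.table::data.table(row = i, caller = m$caller, mid = m$id, rep = m$rep)
  }))
  if (is.null(memdt) || nrow(memdt) == 0L)
    return(data.table::data.table(row = integer(0), caller = character(0),
                                  mid = character(0)))
  memdt[rep == TRUE, .(row, caller, mid)]
}

#' Build the full per-consensus-call feature matrix
#'
#' One row per consensus call. For each registry entry the value is the
#' normalized metric of the supporting caller's representative member, or
#' NA when that caller does not support the call. Adds `svlen` and 0/1
#' `presence_<caller>` columns as configured.
#'
#' @param consensus Output of [merge_calls()].
#' @param calls_by_caller Named list of the (filtered) per-caller call
#'   tables the consensus was merged from.
#' @param registry A [feature_registry()].
#' @param stats A [sequencing_stats()] used for normalization.
#' @return Object of class `sv_feature_matrix`: list with `ids`, `x`
#'   (data.table of numeric features), `labels` (NULL until set), `stats`,
#'   `registry`, `svtype`.
#' @export
build_feature_matrix <- function(consensus, calls_by_caller, registry, stats) {
  stopifnot(inherits(registry, "feature_registry"),
            inherits(stats, "sequencing_stats"))
  cs <- data.table::as.data.table(consensus)
  n <- nrow(cs)
  reps <- rep_id_table(cs)
  x <- data.table::data.table(.rows = seq_len(n))

  reg_callers <- unique(registry$entries$caller)
  absent <- setdiff(reg_callers, names(calls_by_caller))
  if (length(absent))
    warning(sprintf("registry caller(s) with no input calls: %s",
                    paste(absent, collapse = ", ")), call. = FALSE)

  for (cl in reg_callers) {
    rid <- rep(NA_character_, n)
    rr <- reps[caller == cl]
    rid[rr$row] <- rr$mid
    tab <- calls_by_caller[[cl]]
    ent <- registry$entries[registry$entries$caller == cl, ]
    for (k in seq_len(nrow(ent))) {
      val <- rep(NA_real_, n)
      if (!is.null(tab) && nrow(tab) && ent$metric[k] %in% names(tab)) {
        ix <- match(rid, tab$id)
        raw <- as.numeric(tab[[ent$metric[k]]])[ix]
        val <- normalize_metric(raw, ent$kind[k], stats)
      }
      x[, (ent$name[k]) := val]
    }
  }
  if (registry$include_svlen) x[, svlen := as.numeric(cs$svlen)]
  if (registry$include_presence) {
    for (cl in sort(reg_callers)) {
      rid <- rep(NA_character_, n)
      rr <- reps[caller == cl]
      rid[rr$row] <- rr$mid
      x[, (paste0("presence_", cl)) := as.numeric(!is.na(rid))]
    }
  }
  x[, .rows := NULL]
  structure(list(ids = cs$id, x = x[], labels = NULL, stats = stats,
                 registry = registry, svtype = registry$svtype),
            class = "sv_feature_matrix")
}

#' Build the basic (presence-only) feature matrix
#'
#' The baseline representation against which the full model is compared:
#' SV length plus one 0/1 column per caller encoding whether the caller
#' supports the consensus call -- nothing else.
#'
#' @param consensus Output of [merge_calls()].
#' @param calls_by_caller Named list of per-caller call tables (names
#'   define the caller set; sorted alphabetically in the output).
#' @return An `sv_feature_matrix` with `1 + n_callers` columns.
#' @export
basic_feature_matrix <- function(consensus, calls_by_caller) {
  cs <- data.table::as.data.table(consensus)
  n <- nrow(cs)
  callers <- sort(names(calls_by_caller))
  x <- data.table::data.table(svlen = as.numeric(cs$svlen))
  supp_sets <- strsplit(cs$callers, ",", fixed = TRUE)
  for (cl in callers)
    x[, (paste0("presence_", cl)) :=
          as.numeric(vapply(supp_sets, function(s) cl %in% s, logical(1)))]
  structure(list(ids = cs$id, x = x[], labels = NULL, stats = NULL,
                 registry = NULL, svtype = if (n) cs$svtype[1] else NA_character_),
            class = "sv_feature_matrix")
}

#' Attach TP/FP labels to a feature matrix
#'
#' @param fm An `sv_feature_matrix`.
#' @param labels Logical vector (TRUE = true positive), one per row.
#' @return The feature matrix with labels set.
#' @export
set_labels <- function(fm, labels) {
  stopifnot(inherits(fm, "sv_feature_matrix"))
  if (length(labels) != length(fm$ids))
    stopf("labels (%d) do not align with rows (%d)",
          length(labels), length(fm$ids))
  fm$labels <- as.logical(labels)
  fm
}

#' @export
dim.sv_feature_matrix <- function(x) c(length(x$ids), ncol(x$x))

#' @export
print.sv_feature_matrix <- function(x, ...) {
  cat(sprintf("sv_feature_matrix: %d calls x %d features (%s)%s\n",
              length(x$ids), ncol(x$x), x$svtype %||% "?",
              if (is.null(x$labels)) "" else sprintf(
                ", labeled (%d TP / %d FP)", sum(x$labels), sum(!x$labels))))
  invisible(x)
}

#' @export
as.matrix.sv_feature_matrix <- function(x, ...) {
  m <- as.matrix(x$x)
  rownames(m) <- x$ids
  m
}

#' Correlation-based feature pre-selection
#'
#' Drops constant columns, then resolves every pair of features with
#' absolute pairwise Pearson correlation above `r_threshold` (computed on
#' pairwise-complete rows) by dropping the member less correlated (in
#' absolute value) with the TP/FP label; ties drop the lexicographically
#' later name. Pairs are visited in sorted-name order, so the result does
#' not depend on row or column order.
#'
#' @param fm A labeled `sv_feature_matrix` (>= 2 rows).
#' @param r_threshold Redundancy threshold on `|r|` (default 0.90).
#' @return Character vector of retained feature names (input column order).
#' @export
correlation_select <- function(fm, r_threshold = 0.90) {
  stopifnot(inherits(fm, "sv_feature_matrix"))
  if (is.null(fm$labels)) stopf("correlation_select needs labels")
  x <- as.matrix(fm$x)
  if (nrow(x) < 2L) stopf("need >= 2 rows")
  y <- as.numeric(fm$labels)
  nonconst <- apply(x, 2, function(v) {
    v <- v[!is.na(v)]
    length(unique(v)) > 1L
  })
  if (!any(nonconst)) {
    warning("all feature columns are constant; empty selection", call. = FALSE)
    return(character(0))
  }
  x <- x[, nonconst, drop = FALSE]
  label_cor <- abs(suppressWarnings(
    apply(x, 2, function(v) stats::cor(v, y, use = "pairwise.complete.obs"))))
  label_cor[is.na(label_cor)] <- 0
  cm <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  nm <- sort(colnames(x))
  dropped <- character(0)
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (j <= i) next
      a <- nm[i]; b <- nm[j]
      if (a %in% dropped || b %in% dropped) next
      r <- cm[a, b]
      if (is.na(r) || abs(r) <= r_threshold) next
      loser <- if (label_cor[a] < label_cor[b]) a
               else if (label_cor[b] < label_cor[a]) b
               else max(a, b)  # tie: lexicographically later goes
      dropped <- c(dropped, loser)
    }
  }
  keep <- setdiff(colnames(fm$x)[nonconst[colnames(fm$x)]], dropped)
  intersect(colnames(fm$x), keep)
}

#' Serialize a feature matrix to TSV + JSON sidecar
#'
#' Writes `<path>` as tab-separated text (id column, one column per
#' feature, optional label column; NA is the missing sentinel) and
#' `<path>.meta.json` recording sequencing stats, registry entries and the
#' sentinel convention.
#'
#' @param fm An `sv_feature_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "sv_feature_matrix"))
  out <- data.table::data.table(id = fm$ids)
  out <- cbind(out, fm$x)
  if (!is.null(fm$labels)) out[, label := as.integer(fm$labels)]
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  meta <- list(
    svtype = fm$svtype, sentinel = "NA",
    stats = if (!is.null(fm$stats)) unclass(fm$stats),
    registry = if (!is.null(fm$registry)) list(
      svtype = fm$registry$svtype,
      entries = fm$registry$entries,
      include_svlen = fm$registry$include_svlen,
      include_presence = fm$registry$include_presence)
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV path (expects `<path>.meta.json` alongside).
#' @return An `sv_feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  tab <- data.table::fread(path, sep = "\t", na.strings = "NA")
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  labels <- NULL
  if ("label" %in% names(tab)) {
    labels <- as.logical(tab$label)
    tab[, label := NULL]
  }
  ids <- tab$id
  tab[, id := NULL]
  stats <- if (!is.null(meta$stats))
    sequencing_stats(meta$stats$mean_coverage, meta$stats$read_length)
  registry <- if (!is.null(meta$registry))
    feature_registry(meta$registry$svtype,
                     meta$registry$entries[, c("caller", "metric", "kind")],
                     meta$registry$include_svlen,
                     meta$registry$include_presence)
  structure(list(ids = ids, x = tab[], labels = labels, stats = stats,
                 registry = registry, svtype = meta$svtype),
            class = "sv_feature_matrix")
}
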