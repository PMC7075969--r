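# Gene signatures: paired up/down tag sets built from differential-expression
# tables (disease state) or treated/control expression matrices (drug
# perturbation), with cross-namespace probe mapping and GRP file I/O.

#' Construct a gene signature
#'
#' A gene signature is a pair of ordered, duplicate-free identifier sets:
#' `up` (identifiers up-regulated in the state of interest) and `down`
#' (down-regulated). The two sets must be disjoint and at least one must be
#' non-empty. Signatures are the query unit for [run_query()].
#'
#' @param up,down Character vectors of identifiers (genes or probes).
#' @param namespace Label for the identifier namespace (e.g. `"mouse_symbol"`,
#'   `"HG-U133A"`). Purely descriptive.
#' @param provenance Free-form list recording how the signature was built.
#' @param .allow_empty Internal: permit both sides empty (used by
#'   [map_to_probes()], whose contract is to return a degenerate signature
#'   plus a report rather than fail).
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(up = character(), down = character(),
                           namespace = NA_character_, provenance = list(),
                           .allow_empty = FALSE) {
  up <- as.character(up)
  down <- as.character(down)
  if (anyDuplicated(up))
    sc_error("validation", "duplicate identifiers in up tag set: %s",
             paste(unique(up[duplicated(up)]), collapse = ", "))
  if (anyDuplicated(down))
    sc_error("validation", "duplicate identifiers in down tag set: %s",
             paste(unique(down[duplicated(down)]), collapse = ", "))
  both <- intersect(up, down)
  if (length(both))
    sc_error("validation", "up and down tag sets must be disjoint (shared: %s)",
             paste(utils::head(both, 5L), collapse = ", "))
  if (!.allow_empty && length(up) + length(down) == 0L)
    sc_error("empty_signature", "both tag sets are empty after filtering")
  structure(list(up = up, down = down, namespace = namespace,
                 provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature: %d up / %d down tags (namespace: %s)\n",
              length(x$up), length(x$down),
              if (is.na(x$namespace)) "<unset>" else x$namespace))
  invisible(x)
}

#' Load a differential-expression table
#'
#' Reads a header-bearing TSV of per-gene differential-expression results
#' (such as a Cuffdiff or DESeq2 export) into the three fields the signature
#' builder needs: gene identifier, log2 fold change, and significance
#' q-value. Rows with a missing identifier, a non-finite fold change, or a
#' q-value outside \[0, 1\] are skipped; the skip count is attached as the
#' `n_skipped` attribute and reported.
#'
#' @param path TSV file path.
#' @param columns Named character vector mapping the required fields
#'   `gene_id`, `log2fc`, `qvalue` to the column names used in the file.
#' @return A `data.frame` with columns `gene_id`, `log2fc`, `qvalue`, in file
#'   order, with attribute `n_skipped`.
#' @export
load_de_table <- function(path,
                          columns = c(gene_id = "gene_id", log2fc = "log2fc",
                                      qvalue = "qvalue")) {
  need <- c("gene_id", "log2fc", "qvalue")
  if (!all(need %in% names(columns)))
    sc_error("config", "`columns` must name gene_id, log2fc and qvalue")
  df <- read_tsv(path)
  absent <- setdiff(unname(columns[need]), names(df))
  if (length(absent))
    sc_error("schema", "column(s) missing from %s: %s", path,
             paste(absent, collapse = ", "))
  out <- data.frame(
    gene_id = as.character(df[[columns[["gene_id"]]]]),
    log2fc  = suppressWarnings(as.numeric(df[[columns[["log2fc"]]]])),
    qvalue  = suppressWarnings(as.numeric(df[[columns[["qvalue"]]]])),
    stringsAsFactors = FALSE)
  bad <- is.na(out$gene_id) | out$gene_id == "" |
    !is.finite(out$log2fc) |
    is.na(out$qvalue) | out$qvalue < 0 | out$qvalue > 1
  n_skipped <- sum(bad)
  if (n_skipped > 0L)
    log_msg("WARN", "load_de_table", "%d malformed row(s) skipped", n_skipped)
  if (nrow(out) == 0L)
    log_msg("WARN", "load_de_table", "table %s has a header but no rows", path)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Build a disease signature from differential-expression records
#'
#' Selects significant genes (`qvalue <= q_threshold`) and splits them by
#' fold-change sign: positive log2 fold changes become up tags, negative
#' become down tags; genes with a fold change of exactly 0 are excluded.
#' Within each side, tags are ordered by decreasing `|log2fc|` (ties broken
#' by identifier) and, when `top_k` is given, truncated to the `top_k`
#' strongest genes per side.
#'
#' @param records Data frame as returned by [load_de_table()].
#' @param q_threshold Significance cutoff in (0, 1].
#' @param top_k Optional per-side cap (>= 1) on signature size.
#' @param namespace Namespace label stored in the signature.
#' @return A `gene_signature`.
#' @export
build_disease_signature <- function(records, q_threshold = 0.05, top_k = NULL,
                                    namespace = NA_character_) {
  if (!is.numeric(q_threshold) || length(q_threshold) != 1L ||
      is.na(q_threshold) || q_threshold <= 0 || q_threshold > 1)
    sc_error("config", "q_threshold must be a single value in (0, 1]")
  if (!is.null(top_k) && (!is.numeric(top_k) || top_k < 1))
    sc_error("config", "top_k, if given, must be >= 1")
  keep <- records$qvalue <= q_threshold & records$log2fc != 0
  sel <- records[keep, , drop = FALSE]
  if (anyDuplicated(sel$gene_id)) {
    log_msg("WARN", "build_disease_signature",
            "%d duplicate gene id(s); keeping first occurrence",
            sum(duplicated(sel$gene_id)))
    sel <- sel[!duplicated(sel$gene_id), , drop = FALSE]
  }
  pick <- function(side) {
    side <- side[order(-abs(side$log2fc), side$gene_id), , drop = FALSE]
    if (!is.null(top_k)) side <- utils::head(side, top_k)
    side$gene_id
  }
  up <- pick(sel[sel$log2fc > 0, , drop = FALSE])
  down <- pick(sel[sel$log2fc < 0, , drop = FALSE])
  gene_signature(up, down, namespace = namespace,
                 provenance = list(builder = "disease",
                                   q_threshold = q_threshold,
                                   top_k = top_k,
                                   n_input = nrow(records)))
}

#' Read a gene-to-probe mapping table
#'
#' Many-to-many mapping from one identifier namespace (e.g. mouse gene
#' symbols) to another (e.g. human array probes), as a two-column TSV.
#' Duplicate (gene, probe) pairs are collapsed.
#'
#' @param path TSV path with header.
#' @param columns Named character vector mapping `gene` and `probe` to the
#'   file's column names.
#' @return A `data.frame` with columns `gene` and `probe`.
#' @export
read_probe_map <- function(path, columns = c(gene = "gene", probe = "probe")) {
  df <- read_tsv(path)
  absent <- setdiff(unname(columns[c("gene", "probe")]), names(df))
  if (length(absent))
    sc_error("schema", "column(s) missing from %s: %s", path,
             paste(absent, collapse = ", "))
  out <- data.frame(gene = as.character(df[[columns[["gene"]]]]),
                    probe = as.character(df[[columns[["probe"]]]]),
                    stringsAsFactors = FALSE)
  out[!duplicated(out), , drop = FALSE]
}

#' Map a gene signature into a probe namespace
#'
#' Offline replacement for an annotation batch-query service: each gene
#' expands to all probes it maps to (one-to-many allowed), unmapped genes are
#' dropped and counted, and any probe reachable from both an up gene and a
#' down gene is removed from both sides and counted as a conflict (preserving
#' the disjointness invariant conservatively). With `case_fold = TRUE`
#' (default), gene symbols are upper-cased before lookup — the usual
#' mouse-to-human symbol convention.
#'
#' Degenerate inputs never error: the result may be an empty signature whose
#' provenance carries the drop/conflict report.
#'
#' @param sig A `gene_signature` in the mapping's source namespace.
#' @param map A probe map from [read_probe_map()] (or any data frame with
#'   `gene` and `probe` columns).
#' @param case_fold Upper-case symbols before lookup?
#' @param namespace Namespace label for the mapped signature.
#' @return A `gene_signature` in the target namespace. Provenance fields
#'   `dropped_up`, `dropped_down`, `n_conflicts` report the mapping losses.
#' @export
map_to_probes <- function(sig, map, case_fold = TRUE,
                          namespace = "probe") {
  stopifnot(inherits(sig, "gene_signature"))
  if (!is.data.frame(map) || !all(c("gene", "probe") %in% names(map)))
    sc_error("schema", "`map` must have columns gene and probe")
  if (nrow(map) == 0L)
    sc_error("input", "probe map is empty")
  keys <- if (case_fold) toupper(map$gene) else map$gene
  lookup <- split(map$probe, keys)
  expand <- function(tags) {
    k <- if (case_fold) toupper(tags) else tags
    hit <- k %in% names(lookup)
    probes <- unique(unlist(lookup[k[hit]], use.names = FALSE))
    list(probes = probes, dropped = sum(!hit))
  }
  up <- expand(sig$up)
  down <- expand(sig$down)
  conflicts <- intersect(up$probes, down$probes)
  if (length(conflicts))
    log_msg("WARN", "map_to_probes",
            "%d probe(s) mapped from both sides removed", length(conflicts))
  if (up$dropped + down$dropped > 0L)
    log_msg("INFO", "map_to_probes", "%d unmapped gene(s) dropped",
            up$dropped + down$dropped)
  gene_signature(setdiff(up$probes, conflicts),
                 setdiff(down$probes, conflicts),
                 namespace = namespace,
                 provenance = c(sig$provenance,
                                list(mapped_from = sig$namespace,
                                     case_fold = case_fold,
                                     dropped_up = up$dropped,
                                     dropped_down = down$dropped,
                                     n_conflicts = length(conflicts))),
                 .allow_empty = TRUE)
}

#' Build a drug signature from treated and control expression matrices
#'
#' Per-probe amplitude is the difference of row means, treated minus control,
#' on matrices assumed already normalized on a log scale (a log-ratio of
#' linear intensities is available via `amplitude = "log_ratio"`). Probes are
#' sorted by descending amplitude (ties broken lexicographically by probe
#' identifier) and tags selected either by rank counts (`rule = "rank"`:
#' top `top_k` / bottom `bottom_k`) or by absolute amplitude cutoffs
#' (`rule = "threshold"`: amplitude `>= up_threshold` / `<= down_threshold`).
#'
#' @param treated,control Numeric matrices, probes in rows (rownames are the
#'   probe identifiers), one column per array. The two probe universes must
#'   be identical as sets.
#' @param rule Selection rule, `"rank"` (default) or `"threshold"`.
#' @param top_k,bottom_k Rank-rule tag counts per side (defaults 50/50).
#' @param up_threshold,down_threshold Threshold-rule amplitude cutoffs.
#' @param amplitude `"difference"` (default) for mean(treated) −
#'   mean(control); `"log_ratio"` for log2 of the ratio of linear-scale
#'   means.
#' @param namespace Namespace label for the signature.
#' @return A `gene_signature` whose provenance records the selection rule.
#' @export
build_drug_signature <- function(treated, control,
                                 rule = c("rank", "threshold"),
                                 top_k = 50L, bottom_k = top_k,
                                 up_threshold = NULL, down_threshold = NULL,
                                 amplitude = c("difference", "log_ratio"),
                                 namespace = NA_character_) {
  rule <- match.arg(rule)
  amplitude <- match.arg(amplitude)
  treated <- as.matrix(treated)
  control <- as.matrix(control)
  if (is.null(rownames(treated)) || is.null(rownames(control)))
    sc_error("schema", "treated and control matrices need probe rownames")
  if (ncol(treated) < 1L || ncol(control) < 1L)
    sc_error("input", "treated and control must have at least one column")
  sdiff <- length(setdiff(rownames(treated), rownames(control))) +
    length(setdiff(rownames(control), rownames(treated)))
  if (sdiff > 0L)
    sc_error("alignment",
             "probe universes differ (symmetric difference size %d)", sdiff)
  control <- control[rownames(treated), , drop = FALSE]
  amp <- switch(amplitude,
                difference = rowMeans(treated) - rowMeans(control),
                log_ratio = log2(rowMeans(treated) / rowMeans(control)))
  if (any(!is.finite(amp)))
    sc_error("input", "non-finite amplitude for %d probe(s)",
             sum(!is.finite(amp)))
  ord <- order(-amp, names(amp))
  sorted <- names(amp)[ord]
  if (rule == "rank") {
    if (top_k < 0 || bottom_k < 0)
      sc_error("config", "top_k and bottom_k must be >= 0")
    up <- utils::head(sorted, top_k)
    down <- rev(utils::tail(sorted, bottom_k))
    sel <- list(rule = "rank", top_k = top_k, bottom_k = bottom_k)
  } else {
    if (is.null(up_threshold) || is.null(down_threshold))
      sc_error("config",
               "threshold rule needs up_threshold and down_threshold")
    up <- sorted[amp[sorted] >= up_threshold]
    down <- rev(sorted[amp[sorted] <= down_threshold])
    sel <- list(rule = "threshold", up_threshold = up_threshold,
                down_threshold = down_threshold)
  }
  gene_signature(up, down, namespace = namespace,
                 provenance = c(sel, list(builder = "drug",
                                          amplitude = amplitude,
                                          n_treated = ncol(treated),
                                          n_control = ncol(control))))
}

#' Read and write GRP signature files
#'
#' GRP is the plain-text signature dialect: one identifier per line. On
#' read, blank lines and lines starting with `#` are ignored; duplicates are
#' an error. On write, only identifiers are emitted, so write-then-read is
#' the identity.
#'
#' @param path File path.
#' @return `read_grp` returns a character vector of identifiers in file
#'   order; `write_grp` returns `path` invisibly.
#' @export
read_grp <- function(path) {
  if (!file.exists(path)) sc_error("input", "file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  ids <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (anyDuplicated(ids))
    sc_error("duplicate_entry", "duplicate identifier in %s: %s", path,
             ids[duplicated(ids)][1L])
  ids
}

#' @param ids Character vector of identifiers (duplicate-free).
#' @rdname read_grp
#' @export
write_grp <- function(ids, path) {
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    sc_error("duplicate_entry", "duplicate identifier: %s",
             ids[duplicated(ids)][1L])
  writeLines(ids, path)
  invisible(path)
}

#' Write or read a signature as a GRP pair
#'
#' The on-disk form of a signature is `<prefix>_up.grp` / `<prefix>_down.grp`.
#'
#' @param sig A `gene_signature`.
#' @param prefix Path prefix for the two files.
#' @param namespace Namespace label attached on read.
#' @return `write_signature` returns the two paths invisibly;
#'   `read_signature` returns a `gene_signature`.
#' @export
write_signature <- function(sig, prefix) {
  stopifnot(inherits(sig, "gene_signature"))
  paths <- paste0(prefix, c("_up.grp", "_down.grp"))
  write_grp(sig$up, paths[1L])
  write_grp(sig$down, paths[2L])
  invisible(paths)
}

#' @rdname write_signature
#' @export
read_signature <- function(prefix, namespace = NA_character_) {
  gene_signature(read_grp(paste0(prefix, "_up.grp")),
                 read_grp(paste0(prefix, "_down.grp")),
                 namespace = namespace,
                 provenance = list(builder = "grp", prefix = prefix))
}
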