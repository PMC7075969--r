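# Instance databases: each treatment experiment ("instance") is a ranked
# probe profile — a permutation of 1..n with rank 1 the probe most
# up-regulated by the treatment — plus compound / cell-line metadata.
# Ranks, not amplitudes, are the persisted unit: the KS connectivity
# statistic consumes ranks only, which makes scoring normalization-free.

#' Rank a probe amplitude vector into an instance profile
#'
#' Rank 1 goes to the largest amplitude (most up-regulated under treatment),
#' rank n to the smallest. Ties are broken lexicographically by probe
#' identifier, so the profile is deterministic across platforms. Because
#' only the ordering matters, the result is invariant under any strictly
#' increasing transform of the amplitudes.
#'
#' @param amplitudes Named numeric vector (names are probe identifiers), all
#'   finite, length >= 2.
#' @param instance_id Unique instance identifier.
#' @param compound,cell_line Instance metadata, copied verbatim.
#' @param ... Further metadata fields (e.g. dose, batch), carried opaquely.
#' @return An object of class `instance_profile` with fields `instance_id`,
#'   `compound`, `cell_line`, `ranks` (named integer vector), `n`, `meta`.
#' @export
rank_profile_from_amplitudes <- function(amplitudes, instance_id,
                                         compound = NA_character_,
                                         cell_line = NA_character_, ...) {
  if (length(amplitudes) < 2L)
    sc_error("size", "need at least 2 probes, got %d", length(amplitudes))
  if (is.null(names(amplitudes)) || anyDuplicated(names(amplitudes)))
    sc_error("schema", "amplitudes must be named by unique probe identifiers")
  if (any(!is.finite(amplitudes)))
    sc_error("input", "non-finite amplitude for %d probe(s)",
             sum(!is.finite(amplitudes)))
  ord <- order(-amplitudes, names(amplitudes))
  ranks <- integer(length(amplitudes))
  ranks[ord] <- seq_along(amplitudes)
  names(ranks) <- names(amplitudes)
  structure(list(instance_id = as.character(instance_id),
                 compound = as.character(compound),
                 cell_line = as.character(cell_line),
                 ranks = ranks, n = length(ranks),
                 meta = list(...)),
            class = "instance_profile")
}

#' Assemble instance profiles into a searchable database
#'
#' All profiles must share one probe universe; instance identifiers must be
#' unique. The database stores ranks as an integer matrix (probes x
#' instances) plus a metadata table, and every column is validated to be a
#' permutation of 1..n.
#'
#' @param profiles List of `instance_profile` objects.
#' @return An object of class `instance_db` with fields `probes` (ordered
#'   probe universe), `ranks` (integer matrix with dimnames), `meta`
#'   (data.frame: instance_id, compound, cell_line), `n_probes`,
#'   `n_instances`.
#' @export
build_database <- function(profiles) {
  if (length(profiles) == 0L)
    sc_error("size", "no instance profiles supplied")
  stopifnot(all(vapply(profiles, inherits, logical(1), "instance_profile")))
  probes <- names(profiles[[1L]]$ranks)
  n <- length(probes)
  ids <- vapply(profiles, `[[`, character(1), "instance_id")
  if (anyDuplicated(ids))
    sc_error("identifier", "duplicate instance_id: %s",
             ids[duplicated(ids)][1L])
  ranks <- matrix(0L, nrow = n, ncol = length(profiles),
                  dimnames = list(probes, ids))
  for (j in seq_along(profiles)) {
    p <- profiles[[j]]
    if (p$n != n || !setequal(names(p$ranks), probes))
      sc_error("alignment",
               "instance %s has a different probe universe", p$instance_id)
    ranks[, j] <- p$ranks[probes]
  }
  meta <- data.frame(
    instance_id = ids,
    compound = vapply(profiles, `[[`, character(1), "compound"),
    cell_line = vapply(profiles, `[[`, character(1), "cell_line"),
    stringsAsFactors = FALSE)
  db <- structure(list(probes = probes, ranks = ranks, meta = meta,
                       n_probes = n, n_instances = length(profiles)),
                  class = "instance_db")
  validate_database(db)
  db
}

#' Validate an instance database
#'
#' Checks the structural invariants: every rank column is a permutation of
#' 1..n, metadata rows match matrix columns one-to-one, identifiers unique.
#' Called on construction and after file load; exported so simulated or
#' externally assembled databases can be re-checked.
#'
#' @param db An `instance_db`.
#' @return `db`, invisibly; errors on violation.
#' @export
validate_database <- function(db) {
  stopifnot(inherits(db, "instance_db"))
  n <- db$n_probes
  if (n < 2L) sc_error("size", "probe universe must have >= 2 probes")
  if (db$n_instances < 1L) sc_error("size", "database has no instances")
  if (anyDuplicated(db$meta$instance_id))
    sc_error("identifier", "duplicate instance_id in metadata")
  if (!identical(colnames(db$ranks), db$meta$instance_id))
    sc_error("join", "metadata rows do not match rank-matrix columns")
  for (j in seq_len(db$n_instances)) {
    col <- db$ranks[, j]
    if (anyNA(col) || any(col < 1L) || any(col > n) ||
        !all(tabulate(col, n) == 1L))
      sc_error("validation", "instance %s: ranks are not a permutation of 1..%d",
               colnames(db$ranks)[j], n)
  }
  invisible(db)
}

#' Read and write the rank-matrix database dialect
#'
#' The persisted form mirrors the public rank-matrix distribution format of
#' connectivity databases: a TSV whose first column is `probe_id` and whose
#' remaining columns hold the integer ranks of one instance each, plus a
#' companion metadata TSV with columns `instance_id`, `compound`,
#' `cell_line` (extra columns are preserved on a round trip). Paths ending
#' in `.gz` are compressed/decompressed transparently. Write-then-read is
#' the identity.
#'
#' @param path Rank-matrix TSV path.
#' @param meta_path Metadata TSV path.
#' @return `read_rank_matrix` returns an `instance_db`;
#'   `write_rank_matrix` returns `path` invisibly.
#' @export
read_rank_matrix <- function(path, meta_path) {
  mat <- read_tsv(path)
  if (names(mat)[1L] != "probe_id")
    sc_error("schema", "first column of %s must be probe_id", path)
  probes <- as.character(mat[[1L]])
  if (anyDuplicated(probes))
    sc_error("identifier", "duplicate probe_id in %s", path)
  ids <- names(mat)[-1L]
  if (length(ids) == 0L) sc_error("size", "%s holds no instance columns", path)
  n <- length(probes)
  ranks <- matrix(0L, nrow = n, ncol = length(ids),
                  dimnames = list(probes, ids))
  for (j in seq_along(ids)) {
    col <- suppressWarnings(as.integer(mat[[j + 1L]]))
    if (anyNA(col) || any(col < 1L) || any(col > n) ||
        !all(tabulate(col, n) == 1L))
      sc_error("validation",
               "instance %s: column is not a permutation of 1..%d", ids[j], n)
    ranks[, j] <- col
  }
  meta <- read_tsv(meta_path)
  need <- c("instance_id", "compound", "cell_line")
  absent <- setdiff(need, names(meta))
  if (length(absent))
    sc_error("schema", "metadata %s lacks column(s): %s", meta_path,
             paste(absent, collapse = ", "))
  meta$instance_id <- as.character(meta$instance_id)
  missing_meta <- setdiff(ids, meta$instance_id)
  if (length(missing_meta))
    sc_error("join", "instance %s absent from metadata", missing_meta[1L])
  meta <- meta[match(ids, meta$instance_id), , drop = FALSE]
  rownames(meta) <- NULL
  db <- structure(list(probes = probes, ranks = ranks, meta = meta,
                       n_probes = n, n_instances = length(ids)),
                  class = "instance_db")
  validate_database(db)
  db
}

#' @param db An `instance_db`.
#' @rdname read_rank_matrix
#' @export
write_rank_matrix <- function(db, path, meta_path) {
  stopifnot(inherits(db, "instance_db"))
  out <- data.frame(probe_id = db$probes, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (j in seq_len(db$n_instances))
    out[[colnames(db$ranks)[j]]] <- db$ranks[, j]
  write_tsv(out, path)
  write_tsv(db$meta, meta_path)
  invisible(path)
}

#' @export
print.instance_db <- function(x, ...) {
  cat(sprintf("instance_db: %d probes x %d instances (%d compounds, %d cell lines)\n",
              x$n_probes, x$n_instances,
              length(unique(x$meta$compound)),
              length(unique(x$meta$cell_line))))
  invisible(x)
}
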