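# Connectivity scoring of a gene signature against an instance database.
#
# The per-instance statistic is the signed Kolmogorov-Smirnov tag-set
# enrichment: for a tag set occupying ascending ranks V(1..t) of a ranked
# list of length n,
#     a  = max_j ( j/t − V(j)/n )        (tags crowd the top)
#     b  = max_j ( V(j)/n − (j−1)/t )    (tags crowd the bottom)
#     es = a  if a >= b,  else −b
# es = +1 means the tags sit at the very top of the list. The raw
# bidirectional score of an instance is s = es_up − es_down when the two
# sides deviate in opposite directions (a concordant or oppositional
# pattern), and 0 when they share a strict sign ("null instance"). Raw
# scores are scaled database-wide to connectivity scores c in [−1, 1].

#' Signed Kolmogorov-Smirnov tag-set enrichment statistic
#'
#' @param tag_ranks Strictly increasing integer ranks of the tag set within
#'   the ranked list, each in 1..n.
#' @param n Length of the ranked list.
#' @return An object of class `ks_result`: list with `es` (signed statistic
#'   in \[-1, 1\]), `a`, `b` (maximal positive/negative deviations, both
#'   >= 0), `t` (tag count), `n`. An exact tie a == b resolves to the
#'   positive branch; `a` and `b` are exposed so tie cases are auditable.
#' @export
#' @examples
#' ks_statistic(c(1, 2), 10)$es   # tags at the top: +0.8
#' ks_statistic(c(9, 10), 10)$es  # tags at the bottom: -0.9
ks_statistic <- function(tag_ranks, n) {
  t <- length(tag_ranks)
  if (t < 1L) sc_error("input", "tag_ranks is empty")
  if (anyNA(tag_ranks) || any(tag_ranks != floor(tag_ranks)))
    sc_error("input", "tag ranks must be integers")
  if (t > 1L && any(diff(tag_ranks) <= 0))
    sc_error("input", "tag ranks must be strictly increasing")
  if (tag_ranks[1L] < 1 || tag_ranks[t] > n)
    sc_error("input", "tag ranks must lie in 1..%d", n)
  j <- seq_len(t)
  a <- max(j / t - tag_ranks / n)
  b <- max(tag_ranks / n - (j - 1) / t)
  structure(list(es = if (a >= b) a else -b, a = a, b = b,
                 t = t, n = as.integer(n)),
            class = "ks_result")
}

# Vectorized es over rows of a matrix of sorted positions (one draw per
# row); used by the permutation machinery.
ks_es_rows <- function(V, n) {
  t <- ncol(V)
  a <- rep(-Inf, nrow(V))
  b <- rep(-Inf, nrow(V))
  for (j in seq_len(t)) {
    a <- pmax(a, j / t - V[, j] / n)
    b <- pmax(b, V[, j] / n - (j - 1) / t)
  }
  ifelse(a >= b, a, -b)
}

# Raw bidirectional score from the two side statistics. Same strict sign
# on both sides => contradictory pattern => 0; a zero on either side does
# not null the score. One-sided queries score as the es of the present side.
combine_raw_score <- function(es_up, es_down) {
  if (is.na(es_up)) return(es_down)
  if (is.na(es_down)) return(es_up)
  if ((es_up > 0 && es_down > 0) || (es_up < 0 && es_down < 0)) return(0)
  es_up - es_down
}

#' Score one instance profile against a signature
#'
#' Computes the up-side and down-side KS statistics from the tag ranks in
#' the profile and combines them into the raw score `s`. Positive `s` means
#' the instance's transcriptional change overlaps the query (up tags high,
#' down tags low); negative `s` means it opposes it. Query tags must
#' already lie in the profile's probe universe — [run_query()] performs the
#' filtering step and drops absent tags with a count.
#'
#' @param profile An `instance_profile`.
#' @param query A `gene_signature` whose tags are probe identifiers.
#' @return An object of class `instance_connectivity`: list with
#'   `instance_id`, `ks_up`, `ks_down` (a `ks_result` or NULL for an empty
#'   side), `s`, and `c` (unset, `NA`, until database-wide scaling).
#' @export
instance_connectivity <- function(profile, query) {
  stopifnot(inherits(profile, "instance_profile"),
            inherits(query, "gene_signature"))
  universe <- names(profile$ranks)
  up <- query$up[query$up %in% universe]
  down <- query$down[query$down %in% universe]
  if (length(up) + length(down) == 0L)
    sc_error("coverage", "no query tag overlaps the probe universe")
  side <- function(tags) {
    if (length(tags) == 0L) return(NULL)
    ks_statistic(sort.int(unname(profile$ranks[tags])), profile$n)
  }
  ks_up <- side(up)
  ks_down <- side(down)
  s <- combine_raw_score(if (is.null(ks_up)) NA_real_ else ks_up$es,
                         if (is.null(ks_down)) NA_real_ else ks_down$es)
  structure(list(instance_id = profile$instance_id,
                 ks_up = ks_up, ks_down = ks_down, s = s, c = NA_real_),
            class = "instance_connectivity")
}

#' Scale raw scores to connectivity scores
#'
#' Database-wide normalization: with `p_max` the maximum positive raw score
#' and `q_min` the minimum negative raw score over *all* instances for the
#' query (not per compound, so scores are comparable across compounds),
#' `c = s / p_max` for `s > 0`, `c = -(s / q_min)` for `s < 0`, and 0
#' otherwise. All `c` lie in \[-1, 1\]; the extreme instances attain +1 / -1.
#' `c` depends on the raw scores only through positive rescaling.
#'
#' @param all_s Numeric vector of raw scores, one per instance.
#' @return List with `factors` (list `p_max`, `q_min`) and `c` (numeric
#'   vector aligned with `all_s`).
#' @export
scale_scores <- function(all_s) {
  if (length(all_s) < 1L) sc_error("size", "no raw scores supplied")
  p_max <- if (any(all_s > 0)) max(all_s) else 0
  q_min <- if (any(all_s < 0)) min(all_s) else 0
  cvec <- numeric(length(all_s))
  cvec[all_s > 0] <- all_s[all_s > 0] / p_max
  cvec[all_s < 0] <- -(all_s[all_s < 0] / q_min)
  list(factors = list(p_max = p_max, q_min = q_min), c = cvec)
}

#' Query configuration
#'
#' @param group_by Aggregation level: `"compound_cell_line"` (default; the
#'   published result tables name groups like `fluphenazine:PC3`) or
#'   `"compound"`.
#' @param n_perm Number of random instance sets drawn for the empirical
#'   p-value (default 100000).
#' @param seed Integer seed for the permutation stream; recorded in output
#'   provenance.
#' @param direction_rule Permutation tail: `"signed"` (default; a draw
#'   counts when its enrichment has the same sign as, and magnitude at
#'   least, the observed one) or `"absolute"` (magnitude only).
#' @param include_null_instances Include s = 0 instances in the similarity
#'   mean denominator? Default `TRUE` (the mean is over *all* member
#'   instances).
#' @param enumeration_cap Exact enumeration replaces sampling whenever
#'   `choose(N, n_members) <=` this cap (default 100000).
#' @param pseudo_count Report `(count + 1) / (n_perm + 1)` instead of
#'   `count / n_perm` in sampling mode? Default `FALSE`: an empirical p of
#'   exactly 0 is reported verbatim, as in published result tables.
#' @return A list of class `query_config`.
#' @export
query_config <- function(group_by = c("compound_cell_line", "compound"),
                         n_perm = 100000L, seed = 1L,
                         direction_rule = c("signed", "absolute"),
                         include_null_instances = TRUE,
                         enumeration_cap = 100000,
                         pseudo_count = FALSE) {
  group_by <- match.arg(group_by)
  direction_rule <- match.arg(direction_rule)
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) sc_error("config", "n_perm must be >= 1")
  structure(list(group_by = group_by, n_perm = n_perm,
                 seed = as.integer(seed), direction_rule = direction_rule,
                 include_null_instances = isTRUE(include_null_instances),
                 enumeration_cap = enumeration_cap,
                 pseudo_count = isTRUE(pseudo_count)),
            class = "query_config")
}

#' Aggregate instance connectivity scores to compound groups
#'
#' Groups instances by compound (or compound x cell line), reporting the
#' member count n ("number of arrays"), the similarity mean (arithmetic
#' mean of member connectivity scores; null s = 0 instances included by
#' default), and the non-null member count.
#'
#' @param scores List of `instance_connectivity` objects with `c` set, or a
#'   data.frame with columns `instance_id`, `s`, `c`.
#' @param meta Instance metadata data.frame (`instance_id`, `compound`,
#'   `cell_line`).
#' @param config A [query_config()].
#' @return Data frame: `group_key`, `compound`, `cell_line`, `n_instances`,
#'   `similarity_mean`, `n_nonnull` (one row per group; enrichment, p and
#'   rank are added downstream).
#' @export
aggregate_compound <- function(scores, meta, config = query_config()) {
  if (!is.data.frame(scores)) {
    scores <- data.frame(
      instance_id = vapply(scores, `[[`, character(1), "instance_id"),
      s = vapply(scores, `[[`, numeric(1), "s"),
      c = vapply(scores, `[[`, numeric(1), "c"),
      stringsAsFactors = FALSE)
  }
  idx <- match(scores$instance_id, meta$instance_id)
  if (anyNA(idx))
    sc_error("join", "instance %s has no metadata",
             scores$instance_id[which(is.na(idx))[1L]])
  compound <- meta$compound[idx]
  cell_line <- meta$cell_line[idx]
  key <- if (config$group_by == "compound_cell_line")
    paste(compound, cell_line, sep = ":") else compound
  groups <- split(seq_len(nrow(scores)), key)
  rows <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    cv <- scores$c[i]
    nonnull <- scores$s[i] != 0
    sim <- if (config$include_null_instances) mean(cv)
    else if (any(nonnull)) mean(cv[nonnull]) else 0
    data.frame(group_key = g,
               compound = compound[i[1L]],
               cell_line = if (config$group_by == "compound_cell_line")
                 cell_line[i[1L]] else NA_character_,
               n_instances = length(i),
               similarity_mean = sim,
               n_nonnull = sum(nonnull),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group enrichment within the connectivity ordering
#'
#' The KS enrichment of a group's instances within all N instances sorted
#' by connectivity score descending (ties broken by instance identifier
#' before positioning): `ks_statistic(member_positions, t, N)$es`. +1 means
#' the group's instances occupy the very top of the ordering.
#'
#' @param member_positions Ascending positions (1..N) of the group's
#'   instances in the ordering.
#' @param n_total Total number of instances N.
#' @return The enrichment, a value in \[-1, 1\].
#' @export
set_enrichment <- function(member_positions, n_total) {
  ks_statistic(member_positions, n_total)$es
}

# Sorted random n-subsets of 1..N as an n_draws x size matrix of positions.
draw_subsets <- function(n_draws, size, N) {
  V <- matrix(0L, nrow = n_draws, ncol = size)
  for (i in seq_len(n_draws))
    V[i, ] <- sort.int(sample.int(N, size))
  V
}

# Null enrichment distribution for groups of `size` members among N
# instances: exact enumeration of all subsets when affordable, otherwise
# n_perm seeded random draws. Returns list(es = numeric, exact = logical).
null_enrichment <- function(size, N, n_perm, enumeration_cap) {
  if (choose(N, size) <= enumeration_cap) {
    V <- t(utils::combn(N, size))
    list(es = ks_es_rows(V, N), exact = TRUE)
  } else {
    list(es = ks_es_rows(draw_subsets(n_perm, size, N), N), exact = FALSE)
  }
}

# Tail probability of `observed` against a null enrichment sample.
p_from_null <- function(observed, null, direction_rule, pseudo_count) {
  es <- null$es
  count <- switch(direction_rule,
    signed = if (observed > 0) sum(es >= observed)
             else if (observed < 0) sum(es <= observed)
             else length(es),
    absolute = sum(abs(es) >= abs(observed)))
  if (!null$exact && pseudo_count) (count + 1) / (length(es) + 1)
  else count / length(es)
}

#' Empirical permutation p-value for a group enrichment
#'
#' Estimates how often a random same-size set of instances is at least as
#' enriched as the observed group. Draws `config$n_perm` uniform random
#' `n_members`-subsets of positions 1..N (without replacement within a
#' draw) and reports the fraction whose enrichment is at least as extreme
#' as `observed` — same sign and `|es| >= |observed|` under the default
#' signed rule, magnitude only under the absolute rule. When
#' `choose(N, n_members)` does not exceed the enumeration cap, all subsets
#' are enumerated and the p-value is exact. p may be exactly 0 in sampling
#' mode (reported verbatim); an optional pseudo-count mode reports
#' `(count + 1) / (n_perm + 1)` instead.
#'
#' @param observed Observed group enrichment from [set_enrichment()].
#' @param n_members Group size t.
#' @param n_total Total instance count N.
#' @param config A [query_config()]; `n_perm`, `seed`, `direction_rule`,
#'   `enumeration_cap` and `pseudo_count` are honoured.
#' @return The empirical p-value in \[0, 1\].
#' @export
permutation_p <- function(observed, n_members, n_total,
                          config = query_config()) {
  if (n_members < 1L || n_members > n_total)
    sc_error("input", "n_members must lie in 1..%d", n_total)
  null <- with_seed(config$seed,
                    null_enrichment(n_members, n_total, config$n_perm,
                                    config$enumeration_cap))
  p_from_null(observed, null, config$direction_rule, config$pseudo_count)
}

#' Rank scored compound groups
#'
#' Sort key: p-value ascending, then `|enrichment|` descending, then
#' `|similarity_mean|` descending, then group key lexicographically.
#' Rank is the 1-based position in that order.
#'
#' @param groups Data frame with columns `group_key`, `similarity_mean`,
#'   `enrichment`, `p_value` (plus any others, preserved).
#' @return The data frame sorted, with a `rank` column prepended.
#' @export
rank_results <- function(groups) {
  ord <- order(groups$p_value, -abs(groups$enrichment),
               -abs(groups$similarity_mean), groups$group_key)
  out <- groups[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Query an instance database with a gene signature
#'
#' The full scoring pipeline: filter query tags to the database probe
#' universe (absent tags dropped with a count) → per-instance KS statistics
#' and raw scores → database-wide scaling to connectivity scores →
#' compound-level aggregation → group enrichment within the connectivity
#' ordering → empirical permutation p-values → final ranking.
#'
#' The permutation null distribution is computed once per distinct group
#' size from a single seeded stream and shared by all groups of that size;
#' marginal p-values are unchanged and the whole query is deterministic
#' given `config$seed`.
#'
#' @param db An `instance_db`.
#' @param query A `gene_signature` in the database's probe namespace.
#' @param config A [query_config()].
#' @return An object of class `connectivity_result`: list with `results`
#'   (ranked group table: rank, group_key, compound, cell_line,
#'   n_instances, similarity_mean, enrichment, p_value, n_nonnull),
#'   `instances` (per-instance table: instance_id, compound, cell_line,
#'   ks_up, ks_down, s, c), and `provenance` (config, seed, dropped-tag
#'   counts, scaling factors).
#' @export
run_query <- function(db, query, config = query_config()) {
  stopifnot(inherits(db, "instance_db"), inherits(query, "gene_signature"))
  probes <- db$probes
  n <- db$n_probes
  up <- query$up[query$up %in% probes]
  down <- query$down[query$down %in% probes]
  dropped_up <- length(query$up) - length(up)
  dropped_down <- length(query$down) - length(down)
  if (length(up) + length(down) == 0L)
    sc_error("coverage", "no query tag overlaps the database probe universe")
  if (dropped_up + dropped_down > 0L)
    log_msg("WARN", "run_query", "%d query tag(s) absent from universe dropped",
            dropped_up + dropped_down)
  up_i <- match(up, probes)
  down_i <- match(down, probes)
  N <- db$n_instances

  es_up <- rep(NA_real_, N)
  es_down <- rep(NA_real_, N)
  s <- numeric(N)
  for (j in seq_len(N)) {
    col <- db$ranks[, j]
    if (length(up_i))
      es_up[j] <- ks_statistic(sort.int(col[up_i]), n)$es
    if (length(down_i))
      es_down[j] <- ks_statistic(sort.int(col[down_i]), n)$es
    s[j] <- combine_raw_score(es_up[j], es_down[j])
  }
  scaled <- scale_scores(s)
  cvec <- scaled$c

  inst <- data.frame(instance_id = db$meta$instance_id,
                     compound = db$meta$compound,
                     cell_line = db$meta$cell_line,
                     ks_up = es_up, ks_down = es_down,
                     s = s, c = cvec, stringsAsFactors = FALSE)

  groups <- aggregate_compound(inst[, c("instance_id", "s", "c")],
                               db$meta, config)

  # Positions within all instances ordered by c descending, ties broken by
  # instance identifier.
  ord <- order(-cvec, db$meta$instance_id)
  pos <- integer(N)
  pos[ord] <- seq_len(N)
  key <- if (config$group_by == "compound_cell_line")
    paste(db$meta$compound, db$meta$cell_line, sep = ":") else db$meta$compound
  member_pos <- split(pos, key)[groups$group_key]
  groups$enrichment <- vapply(member_pos, function(p)
    set_enrichment(sort.int(p), N), numeric(1))

  sizes <- sort(unique(groups$n_instances))
  nulls <- with_seed(config$seed, {
    out <- list()
    for (sz in sizes)
      out[[as.character(sz)]] <-
        null_enrichment(sz, N, config$n_perm, config$enumeration_cap)
    out
  })
  groups$p_value <- vapply(seq_len(nrow(groups)), function(i)
    p_from_null(groups$enrichment[i],
                nulls[[as.character(groups$n_instances[i])]],
                config$direction_rule, config$pseudo_count), numeric(1))

  results <- rank_results(groups)
  results <- results[, c("rank", "group_key", "compound", "cell_line",
                         "n_instances", "similarity_mean", "enrichment",
                         "p_value", "n_nonnull")]
  structure(list(results = results, instances = inst,
                 provenance = list(config = unclass(config),
                                   seed = config$seed,
                                   dropped_up = dropped_up,
                                   dropped_down = dropped_down,
                                   n_tags_up = length(up),
                                   n_tags_down = length(down),
                                   scaling = scaled$factors,
                                   exact_p_sizes = sizes[vapply(
                                     as.character(sizes),
                                     function(k) nulls[[k]]$exact,
                                     logical(1))])),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, n = 10L, ...) {
  cat(sprintf("connectivity query: %d groups over %d instances (%d up / %d down tags used)\n",
              nrow(x$results), nrow(x$instances),
              x$provenance$n_tags_up, x$provenance$n_tags_down))
  print(utils::head(x$results, n), row.names = FALSE)
  invisible(x)
}

#' Write query result tables as TSV
#'
#' The group table columns, in order: rank, group_key, compound, cell_line,
#' n_instances, similarity_mean, enrichment, p_value, n_nonnull. Floats are
#' written at 6 significant digits, making repeated runs with the same seed
#' byte-identical.
#'
#' @param x A `connectivity_result`.
#' @param path Output path for the ranked group table.
#' @param instances_path Optional output path for the per-instance table.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, instances_path = NULL) {
  stopifnot(inherits(x, "connectivity_result"))
  res <- x$results
  for (col in c("similarity_mean", "enrichment", "p_value"))
    res[[col]] <- fmt_num(res[[col]])
  write_tsv(res, path)
  if (!is.null(instances_path)) {
    inst <- x$instances
    for (col in c("ks_up", "ks_down", "s", "c"))
      inst[[col]] <- fmt_num(inst[[col]])
    write_tsv(inst, instances_path)
  }
  invisible(path)
}
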