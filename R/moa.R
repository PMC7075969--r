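# Mechanism-of-action (MOA) inference by second-order similarity: query the
# database with a drug's own signature, then tally annotation classes among
# the top-ranked neighbours. Compounds inducing similar transcriptome
# changes tend to share pharmacology, so an over-represented class among a
# drug's nearest neighbours suggests a (candidate) shared mechanism.

#' Second-order drug-similarity query
#'
#' Runs [run_query()] with a drug's own signature and returns the k
#' best-ranked groups, flagged `"similar"` (positive similarity mean),
#' `"oppositional"` (negative) or `"null"`.
#'
#' @param db An `instance_db`.
#' @param drug_signature The querying drug's `gene_signature`.
#' @param config A [query_config()].
#' @param k Number of top groups to return (>= 1). If k exceeds the number
#'   of groups, all groups are returned with a warning.
#' @return Data frame: the top-k rows of the ranked result table with a
#'   `relation` column appended. The full `connectivity_result` is attached
#'   as attribute `"full_result"`.
#' @export
second_order_query <- function(db, drug_signature, config = query_config(),
                               k = 10L) {
  if (k < 1L) sc_error("config", "k must be >= 1")
  res <- run_query(db, drug_signature, config)
  if (k > nrow(res$results)) {
    log_msg("WARN", "second_order_query",
            "k = %d exceeds the %d groups available; returning all",
            k, nrow(res$results))
    k <- nrow(res$results)
  }
  top <- utils::head(res$results, k)
  top$relation <- ifelse(top$similarity_mean > 0, "similar",
                         ifelse(top$similarity_mean < 0, "oppositional",
                                "null"))
  attr(top, "full_result") <- res
  top
}

#' Read a compound MOA annotation table
#'
#' One row per (compound, class) label; compounds may carry several labels
#' and unannotated compounds are simply absent. Compound names are matched
#' case-insensitively after whitespace normalization, because public
#' annotation tables are inconsistent.
#'
#' @param path TSV with columns `compound` and `class`.
#' @return Data frame with normalized `compound` and `class` columns.
#' @export
read_moa_annotations <- function(path) {
  df <- read_tsv(path)
  absent <- setdiff(c("compound", "class"), names(df))
  if (length(absent))
    sc_error("schema", "annotation table %s lacks column(s): %s", path,
             paste(absent, collapse = ", "))
  out <- data.frame(compound = normalize_compound(df$compound),
                    class = as.character(df$class),
                    stringsAsFactors = FALSE)
  out[!duplicated(out), , drop = FALSE]
}

normalize_compound <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

#' Tally MOA classes among top-ranked hits
#'
#' Counts, per annotation class, how many distinct compounds among the
#' top-k hits carry the class, next to the background count (distinct
#' compounds in `background` carrying it). Hits whose compound has no
#' annotation are tallied under `"unannotated"`. Optionally adds a
#' hypergeometric over-representation tail p per class (an extension beyond
#' the descriptive tally; upper tail of drawing `count_topk` or more
#' annotated compounds when sampling the top-k compounds from the
#' background).
#'
#' @param hits Ranked hit table from [second_order_query()] (needs a
#'   `compound` column, ordered by rank).
#' @param annotations Annotation table from [read_moa_annotations()].
#' @param k Number of leading hits to tally (<= nrow(hits)).
#' @param background Character vector of compound names forming the
#'   reference universe (e.g. all compounds in the database). Defaults to
#'   the annotation table's compound universe plus the top-k compounds.
#' @param test Compute the hypergeometric over-representation p?
#' @return Data frame: `class`, `count_topk`, `count_background`,
#'   `p_hypergeometric` (NA when `test = FALSE`), ordered by decreasing
#'   top-k count.
#' @export
class_tally <- function(hits, annotations, k = nrow(hits),
                        background = NULL, test = FALSE) {
  if (k > nrow(hits))
    sc_error("input", "k = %d exceeds the %d hits supplied", k, nrow(hits))
  top <- unique(normalize_compound(utils::head(hits, k)$compound))
  background <- if (is.null(background))
    unique(c(annotations$compound, top))
  else unique(normalize_compound(background))
  ann <- annotations[annotations$compound %in% background, , drop = FALSE]
  classes <- sort(unique(ann$class))
  rows <- lapply(classes, function(cl) {
    members <- unique(ann$compound[ann$class == cl])
    ct <- sum(top %in% members)
    cb <- length(members)
    p <- if (test)
      stats::phyper(ct - 1L, cb, length(background) - cb, length(top),
                    lower.tail = FALSE)
    else NA_real_
    data.frame(class = cl, count_topk = ct, count_background = cb,
               p_hypergeometric = p, stringsAsFactors = FALSE)
  })
  unannotated <- sum(!top %in% unique(ann$compound))
  rows <- c(rows, list(data.frame(class = "unannotated",
                                  count_topk = unannotated,
                                  count_background = NA_integer_,
                                  p_hypergeometric = NA_real_,
                                  stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  out <- out[order(-out$count_topk, out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}
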