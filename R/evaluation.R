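# Per-read, per-rank comparison of classification against ground truth:
# the five-way status scheme, classification rates, and taxon-level
# false-positive/false-negative accounting.

STATUS_LEVELS <- c("correct", "incorrect", "unclassified_at_this_level",
                   "unclassified_at_any_level", "truth_unknown")

#' Status of one read at one rank
#'
#' The decision cascade, applied in order:
#' 1. the truth lineage has no label at `rank` -> `truth_unknown`
#'    (correctness is undefined there, whatever the classifier did);
#' 2. the read is unclassified entirely -> `unclassified_at_any_level`;
#' 3. the assigned lineage has no label at `rank` ->
#'    `unclassified_at_this_level` (classified elsewhere in the hierarchy,
#'    e.g. an LCA fallback above `rank`, or an assignment to a taxon that
#'    itself lacks the label);
#' 4. the rank ancestors of assignment and truth coincide -> `correct`;
#' 5. otherwise `incorrect`.
#'
#' Assignments below `rank` (e.g. strain nodes) are projected up through
#' [rank_ancestor()] before comparison.
#'
#' @param db A [taxonomy_db()].
#' @param truth_taxid Taxid of the read's source genome.
#' @param assigned_taxid Assigned taxid, with 0 meaning unclassified.
#' @param rank A canonical rank name.
#'
#' @return One of `r toString(STATUS_LEVELS)`.
#' @export
assign_status <- function(db, truth_taxid, assigned_taxid, rank) {
  .check_rank(db, rank)
  .status_vec(db, as.integer(truth_taxid), as.integer(assigned_taxid), rank)
}

# vectorised cascade; assigned 0 = unclassified
.status_vec <- function(db, truth_taxid, assigned_taxid, rank) {
  truth_at <- rank_ancestor(db, truth_taxid, rank)
  assigned_at <- rep(NA_integer_, length(assigned_taxid))
  cls <- assigned_taxid != 0L
  if (any(cls)) assigned_at[cls] <- rank_ancestor(db, assigned_taxid[cls], rank)
  out <- rep(NA_character_, length(truth_taxid))
  out[is.na(truth_at)] <- "truth_unknown"
  todo <- is.na(out)
  out[todo & !cls] <- "unclassified_at_any_level"
  todo <- is.na(out)
  out[todo & is.na(assigned_at)] <- "unclassified_at_this_level"
  todo <- is.na(out)
  out[todo & assigned_at == truth_at] <- "correct"
  out[is.na(out)] <- "incorrect"
  out
}

#' Evaluate classification against ground truth
#'
#' Applies the five-way status cascade ([assign_status()]) to every read at
#' every requested rank. All percentages use the truth-table size (total
#' simulated read pairs) as denominator, so per rank the five statuses sum
#' to 100. The per-rank classification *rate* (`classified_pct`) follows the
#' truth-free semantics of a rate figure: the percentage of reads whose
#' assigned lineage carries a label at that rank, regardless of correctness.
#'
#' @param truth data.table/data.frame with `read_id`, `taxid`; must cover the
#'   classification table exactly (a classified read with no truth record, or
#'   a truth read missing from the classification, is a hard error).
#' @param classification Record table with `read_id`, `taxid` (0 =
#'   unclassified), e.g. from [classify_reads()], [read_kraken_output()] or
#'   [simulate_classifier_output()].
#' @param db A [taxonomy_db()].
#' @param ranks Canonical ranks to evaluate (default the four reported by
#'   rank-resolved benchmarks: phylum, family, genus, species).
#'
#' @return An object of class `evaluation_summary`: list with `status_pct`
#'   (data.table `rank`, `status`, `percent`), `rank_rates` (data.table
#'   `rank`, `classified_pct`, `unclassified_pct`), `overall_classified_pct`,
#'   `n_reads`, and `status_by_read` (data.table of per-read statuses).
#' @export
evaluate <- function(truth, classification, db,
                     ranks = c("phylum", "family", "genus", "species")) {
  for (r in ranks) .check_rank(db, r)
  truth <- data.table::as.data.table(truth)
  classification <- data.table::as.data.table(classification)

  m <- match(truth$read_id, classification$read_id)
  if (anyNA(m)) {
    miss <- truth$read_id[is.na(m)]
    stop("reads in truth but missing from classification output: ",
         paste(head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) sprintf(" ... (%d total)", length(miss)))
  }
  extra <- setdiff(classification$read_id, truth$read_id)
  if (length(extra)) {
    stop("reads in classification output but absent from ground truth: ",
         paste(head(extra, 5L), collapse = ", "),
         if (length(extra) > 5L) sprintf(" ... (%d total)", length(extra)))
  }
  truth_taxid <- as.integer(truth$taxid)
  assigned <- as.integer(classification$taxid[m])
  n <- length(truth_taxid)
  if (n == 0L) stop("empty truth table")

  by_read <- data.table::data.table(read_id = truth$read_id,
                                    truth_taxid = truth_taxid,
                                    assigned_taxid = assigned)
  status_pct <- list()
  rank_rates <- list()
  for (r in ranks) {
    st <- .status_vec(db, truth_taxid, assigned, r)
    by_read[[paste0("status_", r)]] <- st
    tab <- table(factor(st, levels = STATUS_LEVELS))
    status_pct[[r]] <- data.table::data.table(
      rank = r, status = STATUS_LEVELS, percent = 100 * as.vector(tab) / n)
    has_label <- assigned != 0L & !is.na(
      rank_ancestor(db, ifelse(assigned == 0L, db$root_taxid, assigned), r))
    rank_rates[[r]] <- data.table::data.table(
      rank = r,
      classified_pct = 100 * sum(has_label) / n,
      unclassified_pct = 100 * sum(!has_label) / n)
  }

  structure(list(
    status_pct = data.table::rbindlist(status_pct),
    rank_rates = data.table::rbindlist(rank_rates),
    overall_classified_pct = 100 * sum(assigned != 0L) / n,
    n_reads = n,
    status_by_read = by_read
  ), class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat("<evaluation_summary> ", x$n_reads, " reads, overall classified ",
      sprintf("%.2f%%", x$overall_classified_pct), "\n", sep = "")
  wide <- data.table::dcast(x$status_pct, rank ~ status, value.var = "percent")
  print(wide, digits = 4)
  invisible(x)
}

#' Taxon-level false positives and false negatives at a rank
#'
#' A false-positive taxon appears in the classified counts but has no reads
#' in the ground truth; a false-negative taxon has truth reads but none
#' classified.
#'
#' @param truth_counts,classified_counts data.table/data.frame with `taxid`,
#'   `reads`, both aggregated at the same rank (e.g. `truth_counts` from
#'   [simulate_reads()], classified counts from [abundance_table()]).
#' @param rank The rank both maps were aggregated at; when both carry a
#'   `"rank"` attribute these must match.
#'
#' @return A list of class `taxon_set_comparison`: `rank`,
#'   `false_positive_taxa`, `false_negative_taxa`, `n_fp`, `n_fn`.
#' @export
taxon_set_comparison <- function(truth_counts, classified_counts, rank) {
  r_t <- attr(truth_counts, "rank"); r_c <- attr(classified_counts, "rank")
  if (!is.null(r_t) && !is.null(r_c) && !identical(r_t, r_c)) {
    stop("rank mismatch between count maps: '", r_t, "' vs '", r_c, "'")
  }
  t_tax <- as.integer(truth_counts$taxid[truth_counts$reads > 0])
  c_tax <- as.integer(classified_counts$taxid[classified_counts$reads > 0])
  fp <- sort(setdiff(c_tax, t_tax))
  fn <- sort(setdiff(t_tax, c_tax))
  structure(list(rank = rank, false_positive_taxa = fp,
                 false_negative_taxa = fn,
                 n_fp = length(fp), n_fn = length(fn)),
            class = "taxon_set_comparison")
}

#' @export
print.taxon_set_comparison <- function(x, ...) {
  cat("<taxon_set_comparison> rank ", x$rank, ": ", x$n_fp,
      " false-positive taxa, ", x$n_fn, " false-negative taxa\n", sep = "")
  invisible(x)
}

#' Rank-label overlap between two genome collections
#'
#' Projects each collection's taxids to their labels at `rank` via
#' [rank_ancestor()] (members without a label at that rank drop out) and
#' partitions the two label sets three ways — the comparison used to ask
#' whether two reference collections cover the same families/genera.
#'
#' @param db A [taxonomy_db()].
#' @param taxids_a,taxids_b Taxid sets of the two collections.
#' @param rank A canonical rank.
#'
#' @return A list: `only_a`, `only_b`, `both` (counts), plus the label-taxid
#'   sets `labels_only_a`, `labels_only_b`, `labels_both`.
#' @export
collection_overlap <- function(db, taxids_a, taxids_b, rank) {
  .check_rank(db, rank)
  la <- unique(rank_ancestor(db, taxids_a, rank))
  lb <- unique(rank_ancestor(db, taxids_b, rank))
  la <- la[!is.na(la)]; lb <- lb[!is.na(lb)]
  both <- intersect(la, lb)
  list(only_a = length(setdiff(la, lb)), only_b = length(setdiff(lb, la)),
       both = length(both),
       labels_only_a = sort(setdiff(la, lb)),
       labels_only_b = sort(setdiff(lb, la)),
       labels_both = sort(both))
}
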