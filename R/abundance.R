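# Per-rank taxonomic read-abundance tables and truth-versus-classified
# concordance on log10 percentages.

#' Per-rank abundance table
#'
#' Aggregates a read->taxid table at one rank: each read whose lineage
#' carries a label at `rank` contributes to that label's count; reads from
#' label-less lineages drop out (which is why truth-side percentages need not
#' sum to 100 at ranks with incomplete lineages). The percentage denominator
#' is the total number of reads for truth tables, and the number of reads
#' with any classification for classified tables (`denominator = "per_rank"`
#' switches the latter to reads with a label at this rank).
#'
#' @param reads data.table/data.frame with `read_id`, `taxid` (taxid 0 =
#'   unclassified, only meaningful for `source = "classified"`).
#' @param db A [taxonomy_db()].
#' @param rank A canonical rank.
#' @param source `"truth"` or `"classified"`.
#' @param denominator For classified tables: `"any_rank"` (default; reads
#'   classified anywhere) or `"per_rank"` (reads with a label at this rank).
#'
#' @return A data.table of class `abundance_table` with `taxid`, `name`,
#'   `reads`, `percent`, ordered by taxid; attributes `rank`, `source`,
#'   `denominator`.
#' @export
abundance_table <- function(reads, db, rank, source = c("truth", "classified"),
                            denominator = c("any_rank", "per_rank")) {
  source <- match.arg(source)
  denominator <- match.arg(denominator)
  .check_rank(db, rank)
  reads <- data.table::as.data.table(reads)
  taxid_col <- as.integer(reads$taxid)
  if (source == "truth" && any(taxid_col == 0L)) {
    stop("truth table contains taxid 0; ground truth must be total")
  }
  cls <- taxid_col != 0L
  lab <- rep(NA_integer_, length(taxid_col))
  if (any(cls)) lab[cls] <- rank_ancestor(db, taxid_col[cls], rank)

  denom <- if (source == "truth") length(taxid_col)
           else if (denominator == "any_rank") sum(cls)
           else sum(!is.na(lab))
  dt <- data.table::data.table(taxid = lab)[!is.na(taxid), .(reads = .N), by = taxid]
  data.table::setorder(dt, taxid)
  dt[, name := db$name[match(taxid, db$taxid)]]
  dt[, percent := if (denom > 0) 100 * reads / denom else NA_real_]
  data.table::setcolorder(dt, c("taxid", "name", "reads", "percent"))
  data.table::setattr(dt, "rank", rank)
  data.table::setattr(dt, "source", source)
  data.table::setattr(dt, "denominator", denom)
  data.table::setattr(dt, "class", c("abundance_table", class(dt)))
  dt
}

#' Abundance table from a Kraken-style report file
#'
#' Uses the clade read counts of report rows whose rank code matches `rank`
#' as the classified per-taxon counts.
#'
#' @param report A data.table from [read_kraken_report()].
#' @param db A [taxonomy_db()].
#' @param rank A canonical rank.
#' @param total_classified Denominator: reads classified anywhere. Defaults
#'   to the root clade count found in the report.
#'
#' @return An `abundance_table` (see [abundance_table()]).
#' @export
abundance_from_report <- function(report, db, rank, total_classified = NULL) {
  .check_rank(db, rank)
  code <- toupper(substr(rank, 1L, 1L))
  if (is.null(total_classified)) {
    root_row <- report[report$taxid == db$root_taxid, ]
    total_classified <- if (nrow(root_row)) root_row$clade_reads[1L] else sum(report$direct_reads)
  }
  dt <- data.table::as.data.table(report)[rank_code == code,
                                          .(taxid, reads = clade_reads)]
  data.table::setorder(dt, taxid)
  dt[, name := db$name[match(taxid, db$taxid)]]
  dt[, percent := if (total_classified > 0) 100 * reads / total_classified else NA_real_]
  data.table::setcolorder(dt, c("taxid", "name", "reads", "percent"))
  data.table::setattr(dt, "rank", rank)
  data.table::setattr(dt, "source", "classified")
  data.table::setattr(dt, "denominator", total_classified)
  data.table::setattr(dt, "class", c("abundance_table", class(dt)))
  dt
}

#' Truth-versus-classified abundance concordance
#'
#' Pairs the taxa with nonzero percentage in *both* tables, transforms both
#' percentages by log10, and reports two statistics side by side:
#' `r_squared_ols`, the coefficient of determination of the ordinary
#' least-squares fit of classified on truth (the regression-R² of a log-log
#' scatter), and `r_squared_identity`, `1 - SS(deviation from the y = x
#' line) / SS(total)` — agreement with the identity rather than with the
#' best-fit line. The two coincide at 1 exactly when classified equals truth
#' on the shared taxa; a constant log-scale shift keeps `r_squared_ols` at 1
#' while pushing `r_squared_identity` below it.
#'
#' Zero-valued taxa are excluded (they have no position on a log scatter); a
#' pseudo-percentage can be added to both tables instead via `pseudo`.
#'
#' @param truth_table,classified_table Two [abundance_table()]s at the same
#'   rank.
#' @param pseudo Optional pseudo-percentage added to every taxon present in
#'   either table before pairing (default 0 = exclusion rule).
#'
#' @return A list of class `concordance_result`: `rank`, `points`
#'   (data.table `taxid`, `truth_percent`, `classified_percent`, `log10_truth`,
#'   `log10_classified`), `slope`, `intercept`, `r_squared_ols`,
#'   `r_squared_identity`, `n_points`, `insufficient_data`. With fewer than 3
#'   shared nonzero taxa, `insufficient_data` is `TRUE` and the statistics
#'   are `NA`.
#' @export
concordance <- function(truth_table, classified_table, pseudo = 0) {
  r_t <- attr(truth_table, "rank"); r_c <- attr(classified_table, "rank")
  if (!identical(r_t, r_c)) {
    stop("rank mismatch: truth '", r_t, "' vs classified '", r_c, "'")
  }
  all_tax <- sort(union(truth_table$taxid, classified_table$taxid))
  tp <- truth_table$percent[match(all_tax, truth_table$taxid)]
  cp <- classified_table$percent[match(all_tax, classified_table$taxid)]
  tp[is.na(tp)] <- 0; cp[is.na(cp)] <- 0
  tp <- tp + pseudo; cp <- cp + pseudo
  keep <- tp > 0 & cp > 0
  pts <- data.table::data.table(taxid = all_tax[keep],
                                truth_percent = tp[keep],
                                classified_percent = cp[keep])
  pts[, `:=`(log10_truth = log10(truth_percent),
             log10_classified = log10(classified_percent))]
  out <- list(rank = r_t, points = pts, n_points = nrow(pts))
  if (nrow(pts) < 3L) {
    out$insufficient_data <- TRUE
    out[c("slope", "intercept", "r_squared_ols", "r_squared_identity")] <- NA_real_
    class(out) <- "concordance_result"
    return(out)
  }
  x <- pts$log10_truth; y <- pts$log10_classified
  fit <- lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(residuals(fit)^2)
  out$slope <- unname(coef(fit)[2L])
  out$intercept <- unname(coef(fit)[1L])
  out$r_squared_ols <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  out$r_squared_identity <- if (ss_tot > 0) 1 - sum((y - x)^2) / ss_tot else NA_real_
  out$insufficient_data <- FALSE
  class(out) <- "concordance_result"
  out
}

#' @export
print.concordance_result <- function(x, ...) {
  if (isTRUE(x$insufficient_data)) {
    cat("<concordance_result> rank ", x$rank, ": insufficient data (",
        x$n_points, " shared nonzero taxa)\n", sep = "")
  } else {
    cat(sprintf("<concordance_result> rank %s: %d taxa, R2(ols) = %.4f, R2(y=x) = %.4f, slope = %.3f\n",
                x$rank, x$n_points, x$r_squared_ols, x$r_squared_identity, x$slope))
  }
  invisible(x)
}

#' Top-N most abundant taxa, truth versus classified
#'
#' Orders taxa by truth percentage (descending, ties by taxid) and reports
#' the classified percentage alongside, 0 for taxa the classifier never
#' assigned — surfacing abundant taxa that were missed entirely.
#'
#' @param truth_table,classified_table Two [abundance_table()]s at the same
#'   rank.
#' @param n Number of taxa to report (all, if fewer exist).
#'
#' @return A data.table with `taxid`, `name`, `truth_percent`,
#'   `classified_percent`.
#' @export
top_n_comparison <- function(truth_table, classified_table, n = 10L) {
  stopifnot(n >= 1L)
  r_t <- attr(truth_table, "rank"); r_c <- attr(classified_table, "rank")
  if (!identical(r_t, r_c)) {
    stop("rank mismatch: truth '", r_t, "' vs classified '", r_c, "'")
  }
  dt <- data.table::data.table(taxid = truth_table$taxid,
                               name = truth_table$name,
                               truth_percent = truth_table$percent)
  data.table::setorder(dt, -truth_percent, taxid)
  dt <- head(dt, n)
  cp <- classified_table$percent[match(dt$taxid, classified_table$taxid)]
  dt[, classified_percent := ifelse(is.na(cp), 0, cp)]
  dt[]
}
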