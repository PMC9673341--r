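# Readers and writers for the formats the pipeline speaks: Kraken-dialect
# per-read output, Kraken-style report files, the truth TSV, and FASTQ.

#' Read Kraken-dialect classification output
#'
#' Tab-separated, one record per read (pair): column 1 "C"/"U", column 2 read
#' id, column 3 taxid (0 iff "U"), column 4 length field (e.g. "150|150"),
#' column 5 space-separated "taxid:count" tokens with a literal "|:|"
#' separator between mates. Columns 4-5 are optional and preserved verbatim;
#' trailing extra columns are kept in `extra`.
#'
#' @param path File path.
#'
#' @return A data.table with `status`, `read_id`, `taxid`, `length_field`,
#'   `lca_map` (and `extra` when present).
#' @export
read_kraken_output <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.table::data.table(status = character(0), read_id = character(0),
                                  taxid = integer(0), length_field = character(0),
                                  lca_map = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed classification line ", which(nf < 3L)[1L],
         ": fewer than 3 tab-separated columns")
  }
  status <- vapply(fields, `[[`, "", 1L)
  bad <- !status %in% c("C", "U")
  if (any(bad)) {
    stop("malformed classification line ", which(bad)[1L],
         ": status must be 'C' or 'U'")
  }
  taxid <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(taxid)) {
    stop("malformed classification line ", which(is.na(taxid))[1L],
         ": non-integer taxid")
  }
  inconsistent <- (status == "U") != (taxid == 0L)
  if (any(inconsistent)) {
    stop("malformed classification line ", which(inconsistent)[1L],
         ": status flag and taxid disagree ('U' <=> taxid 0)")
  }
  get_or <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, "")
  }
  dt <- data.table::data.table(status = status,
                               read_id = vapply(fields, `[[`, "", 2L),
                               taxid = taxid,
                               length_field = get_or(4L, NA_character_),
                               lca_map = get_or(5L, NA_character_))
  if (any(nf > 5L)) {
    dt[, extra := vapply(fields, function(f) {
      if (length(f) > 5L) paste(f[-(1:5)], collapse = "\t") else NA_character_
    }, "")]
  }
  dt
}

#' Write Kraken-dialect classification output
#'
#' @param records A record table as returned by [classify_reads()],
#'   [simulate_classifier_output()] or [read_kraken_output()].
#' @param path Output path.
#'
#' @return Invisibly, `path`.
#' @export
write_kraken_output <- function(records, path) {
  records <- data.table::as.data.table(records)
  inconsistent <- (records$status == "U") != (records$taxid == 0L)
  if (any(inconsistent)) {
    stop("record ", which(inconsistent)[1L],
         ": status flag and taxid disagree ('U' <=> taxid 0)")
  }
  cols <- list(records$status, records$read_id, records$taxid)
  lenf <- if ("length_field" %in% names(records)) records$length_field else NA_character_
  lcam <- if ("lca_map" %in% names(records)) records$lca_map else NA_character_
  lenf[is.na(lenf)] <- "0"
  lcam[is.na(lcam)] <- ""
  lines <- paste(records$status, records$read_id, records$taxid, lenf, lcam,
                 sep = "\t")
  if ("extra" %in% names(records)) {
    has_extra <- !is.na(records$extra)
    lines[has_extra] <- paste(lines[has_extra], records$extra[has_extra], sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write the ground-truth table
#'
#' Two tab-separated columns, no header: read id, truth taxid.
#'
#' @param path File path.
#' @return `read_truth()`: a data.table with `read_id`, `taxid`.
#' @export
read_truth <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("read_id", "taxid"),
                          colClasses = list(character = 1L, integer = 2L))
  if (anyNA(dt$taxid)) stop("malformed truth line ", which(is.na(dt$taxid))[1L],
                            ": non-integer taxid")
  dt
}

#' @rdname read_truth
#' @param truth data.table/data.frame with `read_id`, `taxid`.
#' @return `write_truth()`: invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  data.table::fwrite(data.table::as.data.table(truth)[, .(read_id, taxid)],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write paired reads as FASTQ
#'
#' Four-line FASTQ records with constant quality 'I' (the pipeline never
#' consumes base qualities).
#'
#' @param reads A named [Biostrings::DNAStringSet].
#' @param path Output path.
#'
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = qual)
  invisible(path)
}

# rank code letter for report files: canonical rank initial, R for root,
# K for superkingdom, "-" otherwise
.rank_code <- function(db, idx) {
  rk <- db$rank[idx]
  code <- rep("-", length(idx))
  canon <- rk %in% db$canonical_ranks
  code[canon] <- toupper(substr(rk[canon], 1L, 1L))
  code[rk == "superkingdom"] <- "K"
  code[db$taxid[idx] == db$root_taxid] <- "R"
  code
}

#' Write a Kraken-style report file
#'
#' Six tab-separated columns: percentage of reads in the clade, clade read
#' count (reads assigned to the taxon or any descendant), direct read count,
#' rank code, taxid, and the scientific name indented two spaces per
#' taxonomy depth. Rows appear in depth-first order; taxa with an empty
#' clade are omitted. An initial "unclassified" row carries the unclassified
#' read count.
#'
#' @param records A classification record table (`read_id`, `taxid`).
#' @param db A [taxonomy_db()].
#' @param path Output path.
#'
#' @return Invisibly, `path`.
#' @export
write_kraken_report <- function(records, db, path) {
  records <- data.table::as.data.table(records)
  n_total <- nrow(records)
  n_uncl <- sum(records$taxid == 0L)
  direct <- integer(length(db$taxid))
  tab <- table(records$taxid[records$taxid != 0L])
  idx <- .tax_idx(db, as.integer(names(tab)))
  direct[idx] <- as.integer(tab)

  # clade counts: push direct counts up the tree, deepest first
  clade <- direct
  ord <- order(db$depth, decreasing = TRUE)
  for (i in ord) {
    pi <- match(db$parent[i], db$taxid)
    if (pi != i) clade[pi] <- clade[pi] + clade[i]
  }

  # depth-first traversal from the root, children by taxid order
  non_root <- which(db$parent != db$taxid)
  kids <- split(non_root, factor(db$parent[non_root], levels = db$taxid))
  root_i <- match(db$root_taxid, db$taxid)
  out_idx <- integer(0)
  stack <- root_i
  while (length(stack)) {
    i <- stack[1L]; stack <- stack[-1L]
    if (clade[i] == 0L) next
    out_idx <- c(out_idx, i)
    ch <- kids[[as.character(db$taxid[i])]]
    if (length(ch)) stack <- c(ch[order(db$taxid[ch])], stack)
  }

  pct <- function(x) sprintf("%.2f", if (n_total > 0) 100 * x / n_total else 0)
  lines <- paste(pct(n_uncl), n_uncl, n_uncl, "U", 0L, "unclassified", sep = "\t")
  if (length(out_idx)) {
    lines <- c(lines, paste(pct(clade[out_idx]), clade[out_idx], direct[out_idx],
                            .rank_code(db, out_idx), db$taxid[out_idx],
                            paste0(strrep("  ", db$depth[out_idx]), db$name[out_idx]),
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Kraken-style report file
#'
#' @param path File path (format as written by [write_kraken_report()];
#'   standard 6-column reports parse the same way).
#'
#' @return A data.table with `percent`, `clade_reads`, `direct_reads`,
#'   `rank_code`, `taxid`, `name` (indentation stripped), `depth` (indent
#'   level).
#' @export
read_kraken_report <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("malformed report line ", which(nf < 6L)[1L], ": expected 6 columns")
  }
  raw_name <- vapply(fields, `[[`, "", 6L)
  indent <- nchar(raw_name) - nchar(sub("^ +", "", raw_name))
  dt <- data.table::data.table(
    percent = as.numeric(vapply(fields, `[[`, "", 1L)),
    clade_reads = as.integer(vapply(fields, `[[`, "", 2L)),
    direct_reads = as.integer(vapply(fields, `[[`, "", 3L)),
    rank_code = vapply(fields, `[[`, "", 4L),
    taxid = as.integer(vapply(fields, `[[`, "", 5L)),
    name = sub("^ +", "", raw_name),
    depth = as.integer(indent %/% 2L))
  if (anyNA(dt$taxid) || anyNA(dt$clade_reads)) {
    stop("malformed report line ",
         which(is.na(dt$taxid) | is.na(dt$clade_reads))[1L])
  }
  dt
}
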