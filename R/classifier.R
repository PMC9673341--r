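# R surface of the exact-k-mer LCA classifier. The index lives in C++ as an
# external pointer; it is rebuilt from its inputs rather than serialised.

#' Build an exact-k-mer LCA index
#'
#' Stores, for every canonical k-mer occurring in at least one genome, the
#' lowest common ancestor of the taxids of all genomes containing it
#' (canonical k-mer = lexicographic minimum of the k-mer and its reverse
#' complement). K-mers containing non-ACGT symbols are skipped.
#'
#' @param genomes Named [Biostrings::DNAStringSet]; headers must parse as
#'   `"taxid|<id>|<name>"`.
#' @param db A [taxonomy_db()] containing every genome taxid.
#' @param k Odd k-mer size in `[3, 31]`. Default 21.
#'
#' @return An object of class `kmer_index`.
#' @export
build_kmer_index <- function(genomes, db, k = 21L) {
  taxids <- .header_taxids(names(genomes))
  .tax_idx(db, taxids)
  ptr <- .cpp_build_index(as.character(genomes), as.integer(taxids),
                          as.integer(k), db$taxid, db$parent, db$depth)
  structure(list(ptr = ptr, k = as.integer(k), db = db,
                 genome_taxids = taxids),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  st <- .cpp_index_stats(x$ptr)
  cat("<kmer_index> k = ", st$k, ", ", format(st$n_kmers, big.mark = ","),
      " k-mers over ", length(x$genome_taxids), " genomes\n", sep = "")
  invisible(x)
}

#' Classify a single read or read pair
#'
#' Counts index hits per taxid over all canonical k-mers of the read (and its
#' mate, if given); the score of a node is the sum of hit counts over the
#' nodes on its root-to-node path. The answer is the deepest node with
#' maximal score among the nodes lying on a hit taxid's root path; several
#' maxima at equal depth collapse to their LCA. A read with no index hit at
#' all (including reads shorter than k) is unclassified (taxid 0).
#'
#' @param index A [build_kmer_index()] result.
#' @param seq Character or [Biostrings::DNAString], the (first) read.
#' @param mate Optional second mate.
#' @param details If `TRUE`, also return the per-taxid hit table and the
#'   winning path score.
#'
#' @return The assigned taxid (0 = unclassified), or with `details = TRUE` a
#'   list with `taxid`, `score`, `hits`.
#' @export
classify_read <- function(index, seq, mate = NULL, details = FALSE) {
  stopifnot(inherits(index, "kmer_index"))
  s1 <- as.character(seq)
  s2 <- if (is.null(mate)) NULL else as.character(mate)
  res <- .cpp_classify(index$ptr, s1, s2, FALSE)
  if (!details) return(res$taxid[1L])
  hits <- .cpp_read_hits(index$ptr, s1, if (is.null(s2)) "" else s2, !is.null(s2))
  list(taxid = res$taxid[1L], score = res$score[1L],
       hits = data.table::as.data.table(hits))
}

#' Classify a batch of read pairs
#'
#' One classification per pair, per the rule documented in
#' [classify_read()].
#'
#' @param index A [build_kmer_index()] result.
#' @param r1 [Biostrings::DNAStringSet] (or character vector) of first mates;
#'   names are read ids (a trailing `/1`/`/2` is stripped for the pair id).
#' @param r2 Optional second mates, same length and order.
#' @param emit_map If `TRUE`, fill the Kraken-style per-k-mer LCA-map column
#'   (slower; off by default).
#'
#' @return A data.table with `status` ("C"/"U"), `read_id`, `taxid`,
#'   `length_field`, `lca_map` — the in-memory Kraken-dialect record table.
#' @export
classify_reads <- function(index, r1, r2 = NULL, emit_map = FALSE) {
  stopifnot(inherits(index, "kmer_index"))
  ids <- names(r1)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(r1))
  ids <- sub("/[12]$", "", ids)
  if (!is.null(r2) && length(r2) != length(r1)) {
    stop("mate count mismatch: ", length(r1), " vs ", length(r2))
  }
  res <- .cpp_classify(index$ptr, as.character(r1),
                       if (is.null(r2)) NULL else as.character(r2), emit_map)
  data.table::data.table(status = ifelse(res$taxid == 0L, "U", "C"),
                         read_id = ids, taxid = res$taxid,
                         length_field = res$length_field,
                         lca_map = res$lca_map)
}

#' Classify FASTQ files and write Kraken-dialect output
#'
#' Reads one or two FASTQ files (mates in consistent order), classifies each
#' pair, and optionally writes the 5-column Kraken-dialect output file.
#'
#' @param index A [build_kmer_index()] result.
#' @param r1_path,r2_path FASTQ paths (`r2_path = NULL` for single-end).
#' @param output_path Optional path for the Kraken-dialect output file.
#' @param emit_map See [classify_reads()].
#'
#' @return The classification record table (invisibly carries the output
#'   path in attribute `path` when one was written).
#' @export
classify_file <- function(index, r1_path, r2_path = NULL, output_path = NULL,
                          emit_map = TRUE) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  r2 <- if (is.null(r2_path)) NULL else Biostrings::readDNAStringSet(r2_path, format = "fastq")
  if (!is.null(r2) && length(r2) != length(r1)) {
    stop("mate count mismatch between ", r1_path, " (", length(r1), ") and ",
         r2_path, " (", length(r2), ")")
  }
  # FASTQ titles may carry descriptions; the id is the first token
  names(r1) <- sub("\\s.*$", "", names(r1))
  rec <- classify_reads(index, r1, r2, emit_map = emit_map)
  if (!is.null(output_path)) {
    write_kraken_output(rec, output_path)
    attr(rec, "path") <- output_path
  }
  rec
}
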