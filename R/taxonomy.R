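# Taxonomy trees in the NCBI taxdump dialect: rank-aware lineage queries,
# LCA, and lineage-completeness accounting. Ranks form an open vocabulary;
# only `canonical_ranks` take part in per-rank queries, and a rank may be
# genuinely absent from a lineage (MAG-style incomplete taxonomy).

DEFAULT_CANONICAL_RANKS <- c("phylum", "class", "order", "family", "genus", "species")

#' Construct a taxonomy database
#'
#' Builds a validated taxonomy tree from parallel node vectors. Most users
#' will call [load_taxdump()] or [generate_taxonomy()] instead; this is the
#' common constructor behind both.
#'
#' @param taxid Integer vector of node identifiers (unique, positive).
#' @param parent_taxid Integer vector of parent identifiers; the root points
#'   to itself.
#' @param rank Character vector of rank names (open vocabulary; values not in
#'   `canonical_ranks` are kept verbatim and never match canonical queries).
#' @param name Character vector of scientific names.
#' @param canonical_ranks Ordered character vector of the ranks used by
#'   per-rank queries, from most to least inclusive.
#'
#' @return An object of class `taxonomy_db` with elements `taxid`, `parent`,
#'   `rank`, `name`, `depth`, `root_taxid` and `canonical_ranks`.
#' @export
taxonomy_db <- function(taxid, parent_taxid, rank, name,
                        canonical_ranks = DEFAULT_CANONICAL_RANKS) {
  taxid <- as.integer(taxid)
  parent_taxid <- as.integer(parent_taxid)
  n <- length(taxid)
  stopifnot(length(parent_taxid) == n, length(rank) == n, length(name) == n)
  if (n == 0L) stop("taxonomy must contain at least one node")
  if (anyNA(taxid) || any(taxid <= 0L)) stop("taxids must be positive integers")
  dup <- taxid[duplicated(taxid)]
  if (length(dup)) stop("duplicate taxid in taxonomy: ", dup[1L])
  pidx <- match(parent_taxid, taxid)
  if (anyNA(pidx)) {
    bad <- parent_taxid[is.na(pidx)][1L]
    stop("parent taxid ", bad, " is absent from the taxonomy")
  }
  is_root <- parent_taxid == taxid
  if (sum(is_root) != 1L) {
    stop("taxonomy must contain exactly one root (node whose parent is itself); found ",
         sum(is_root))
  }
  root_taxid <- taxid[is_root]

  # depth by breadth-first sweep from the root; unreached nodes imply a cycle
  depth <- rep(NA_integer_, n)
  depth[is_root] <- 0L
  frontier <- which(is_root)
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- which(pidx %in% frontier & is.na(depth))
    depth[nxt] <- d
    frontier <- nxt
  }
  if (anyNA(depth)) {
    stop("taxonomy contains a cycle involving taxid ", taxid[which(is.na(depth))[1L]])
  }

  structure(
    list(taxid = taxid, parent = parent_taxid, rank = as.character(rank),
         name = as.character(name), depth = depth, root_taxid = root_taxid,
         canonical_ranks = canonical_ranks),
    class = "taxonomy_db"
  )
}

#' @export
print.taxonomy_db <- function(x, ...) {
  cat("<taxonomy_db> ", length(x$taxid), " taxa, root ", x$root_taxid,
      ", height ", max(x$depth), "\n", sep = "")
  rk <- table(x$rank)
  canon <- intersect(x$canonical_ranks, names(rk))
  if (length(canon)) {
    cat("  ", paste(sprintf("%s: %d", canon, rk[canon]), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# index of taxids in db, hard error on unknowns
.tax_idx <- function(db, taxids) {
  idx <- match(as.integer(taxids), db$taxid)
  if (anyNA(idx)) {
    stop("unknown taxid: ", paste(unique(taxids[is.na(idx)]), collapse = ", "))
  }
  idx
}

.check_rank <- function(db, rank) {
  if (length(rank) != 1L || !rank %in% db$canonical_ranks) {
    stop("unknown rank '", paste(rank, collapse = ","),
         "'; canonical ranks are: ", paste(db$canonical_ranks, collapse = ", "))
  }
  rank
}

#' Ancestor of a taxon at a given rank
#'
#' Walks parent links from each query taxid (inclusive) towards the root and
#' returns the first node whose rank equals `rank`, or `NA` when the lineage
#' has no node of that rank. An absent rank is a property of real MAG
#' taxonomies, not an error: e.g. a species attached directly to an order has
#' no family or genus ancestor.
#'
#' @param db A [taxonomy_db()].
#' @param taxids Integer vector of query taxids (all must exist in `db`).
#' @param rank A single canonical rank name.
#'
#' @return Integer vector of ancestor taxids, `NA` where the rank is absent.
#' @export
rank_ancestor <- function(db, taxids, rank) {
  .check_rank(db, rank)
  idx <- .tax_idx(db, taxids)
  res <- rep(NA_integer_, length(idx))
  if (!length(idx)) return(res)
  cur <- idx
  active <- rep(TRUE, length(idx))
  repeat {
    hit <- active & db$rank[cur] == rank
    res[hit] <- db$taxid[cur[hit]]
    active <- active & !hit
    at_root <- db$parent[cur] == db$taxid[cur]
    active <- active & !at_root
    if (!any(active)) break
    cur[active] <- match(db$parent[cur[active]], db$taxid)
  }
  res
}

# taxids on the path taxid -> root, inclusive, ordered leaf-first
.root_path <- function(db, taxid) {
  idx <- .tax_idx(db, taxid)
  path <- integer(0)
  repeat {
    path <- c(path, db$taxid[idx])
    if (db$parent[idx] == db$taxid[idx]) break
    idx <- match(db$parent[idx], db$taxid)
  }
  path
}

#' Canonical-rank lineage of a taxon
#'
#' @param db A [taxonomy_db()].
#' @param taxid A single taxid.
#'
#' @return A data.frame of class `lineage` with columns `rank`, `taxid`,
#'   `name`, one row per canonical rank *present* on the root path (absent
#'   ranks are simply missing), ordered from most to least inclusive.
#'   The query taxid is kept in attribute `source_taxid`.
#' @export
lineage <- function(db, taxid) {
  stopifnot(length(taxid) == 1L)
  path_idx <- match(.root_path(db, taxid), db$taxid)
  keep <- path_idx[db$rank[path_idx] %in% db$canonical_ranks]
  keep <- keep[order(match(db$rank[keep], db$canonical_ranks))]
  out <- data.frame(rank = db$rank[keep], taxid = db$taxid[keep],
                    name = db$name[keep], stringsAsFactors = FALSE)
  attr(out, "source_taxid") <- as.integer(taxid)
  class(out) <- c("lineage", "data.frame")
  out
}

# LCA of exactly two taxids via depth equalisation
.lca2 <- function(db, a, b) {
  ia <- match(a, db$taxid); ib <- match(b, db$taxid)
  while (db$depth[ia] > db$depth[ib]) ia <- match(db$parent[ia], db$taxid)
  while (db$depth[ib] > db$depth[ia]) ib <- match(db$parent[ib], db$taxid)
  while (ia != ib) {
    ia <- match(db$parent[ia], db$taxid)
    ib <- match(db$parent[ib], db$taxid)
  }
  db$taxid[ia]
}

#' Lowest common ancestor
#'
#' Deepest node lying on the root path of every member of `taxids`.
#' `lca(db, x)` of a single taxid is `x` itself.
#'
#' @param db A [taxonomy_db()].
#' @param taxids Nonempty integer vector of taxids present in `db`.
#'
#' @return A single taxid.
#' @export
lca <- function(db, taxids) {
  taxids <- unique(as.integer(taxids))
  if (!length(taxids)) stop("lca() of an empty taxid collection")
  .tax_idx(db, taxids)
  Reduce(function(a, b) .lca2(db, a, b), taxids)
}

#' Lineage-completeness report for a set of genomes
#'
#' For each canonical rank, counts how many of the input taxids have no label
#' at that rank; additionally counts how many carry an informal species name
#' (among those that have a species label at all), per [is_informal_name()].
#'
#' @param db A [taxonomy_db()].
#' @param taxids Taxids of the genome set (typically species or strain nodes).
#' @param informal_tokens Passed to [is_informal_name()].
#'
#' @return A list with `per_rank` (data.frame `rank`, `n_missing`),
#'   `n_informal`, and `n` (input size).
#' @export
completeness_report <- function(db, taxids,
                                informal_tokens = c("uncultured", "candidate", "candidatus")) {
  taxids <- as.integer(taxids)
  .tax_idx(db, taxids)
  per_rank <- data.frame(
    rank = db$canonical_ranks,
    n_missing = vapply(db$canonical_ranks, function(r) {
      sum(is.na(rank_ancestor(db, taxids, r)))
    }, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  sp <- rank_ancestor(db, taxids, "species")
  sp_names <- db$name[match(sp[!is.na(sp)], db$taxid)]
  list(per_rank = per_rank,
       n_informal = sum(is_informal_name(sp_names, tokens = informal_tokens)),
       n = length(taxids))
}

#' Informal species-name predicate
#'
#' A name is informal when it contains one of the placeholder tokens
#' ("uncultured", "candidate", "candidatus" by default, case-insensitive),
#' ends in "bacterium"/"archaeon" optionally followed by an alphanumeric
#' strain tag (e.g. "Bacteroidales bacterium KHT7"), or contains " sp."
#' — the naming patterns characteristic of uncultured or
#' metagenome-assembled genomes.
#'
#' @param name Character vector of species names.
#' @param tokens Placeholder tokens treated as informal markers.
#'
#' @return Logical vector.
#' @export
is_informal_name <- function(name, tokens = c("uncultured", "candidate", "candidatus")) {
  stopifnot(is.character(name), all(nzchar(name)))
  low <- tolower(name)
  has_token <- Reduce(`|`, lapply(tokens, function(tk) {
    grepl(paste0("\\b", tk, "\\b"), low, perl = TRUE)
  }), init = rep(FALSE, length(name)))
  placeholder_tail <- grepl("\\b(bacterium|archaeon)( [A-Za-z0-9.-]+)?$", low, perl = TRUE)
  has_sp <- grepl(" sp\\.", low, fixed = FALSE)
  has_token | placeholder_tail | has_sp
}

# ---- taxdump dialect I/O -----------------------------------------------

.read_dmp_lines <- function(source) {
  if (length(source) == 1L && !grepl("\t", source)) readLines(source) else source
}

.parse_dmp <- function(lines, min_fields, what) {
  lines <- lines[nzchar(lines)]
  ok_term <- grepl("\t\\|$", lines)
  if (any(!ok_term)) {
    stop("malformed ", what, " line ", which(!ok_term)[1L], ": missing '\\t|' terminator")
  }
  body <- sub("\t\\|$", "", lines)
  fields <- strsplit(body, "\t|\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_fields)) {
    stop("malformed ", what, " line ", which(nf < min_fields)[1L],
         ": expected at least ", min_fields, " fields")
  }
  fields
}

#' Read an NCBI-taxdump-style taxonomy
#'
#' Parses the nodes/names dump dialect: fields joined by `"\t|\t"`, each line
#' terminated by `"\t|"`. From the nodes file the first three fields (taxid,
#' parent taxid, rank) are used; from the names file the first four (taxid,
#' name, unique name, name class), keeping only records of class
#' `"scientific name"`. Nodes with no scientific name are named
#' `"taxid:<id>"`.
#'
#' @param nodes_source,names_source File path, or a character vector of
#'   already-read lines.
#' @param canonical_ranks See [taxonomy_db()].
#'
#' @return A [taxonomy_db()].
#' @export
load_taxdump <- function(nodes_source, names_source,
                         canonical_ranks = DEFAULT_CANONICAL_RANKS) {
  nodes <- .parse_dmp(.read_dmp_lines(nodes_source), 3L, "nodes")
  taxid <- suppressWarnings(as.integer(vapply(nodes, `[[`, "", 1L)))
  parent <- suppressWarnings(as.integer(vapply(nodes, `[[`, "", 2L)))
  rank <- vapply(nodes, `[[`, "", 3L)
  if (anyNA(taxid) || anyNA(parent)) {
    stop("malformed nodes line ", which(is.na(taxid) | is.na(parent))[1L],
         ": non-integer taxid field")
  }
  dup <- taxid[duplicated(taxid)]
  if (length(dup)) stop("duplicate taxid in nodes file: ", dup[1L])

  names_f <- .parse_dmp(.read_dmp_lines(names_source), 4L, "names")
  n_taxid <- suppressWarnings(as.integer(vapply(names_f, `[[`, "", 1L)))
  if (anyNA(n_taxid)) {
    stop("malformed names line ", which(is.na(n_taxid))[1L], ": non-integer taxid field")
  }
  n_name <- vapply(names_f, `[[`, "", 2L)
  n_class <- vapply(names_f, `[[`, "", 4L)
  sci <- n_class == "scientific name"
  name <- paste0("taxid:", taxid)
  hit <- match(taxid, n_taxid[sci])
  name[!is.na(hit)] <- n_name[sci][hit[!is.na(hit)]]

  taxonomy_db(taxid, parent, rank, name, canonical_ranks = canonical_ranks)
}

#' Write a taxonomy in the taxdump dialect
#'
#' Inverse of [load_taxdump()]: emits a nodes file (taxid, parent, rank) and a
#' names file with one `"scientific name"` record per node, in the bit-exact
#' NCBI field layout.
#'
#' @param db A [taxonomy_db()].
#' @param nodes_path,names_path Output file paths.
#'
#' @return Invisibly, the two paths.
#' @export
write_taxdump <- function(db, nodes_path, names_path) {
  nodes <- paste0(db$taxid, "\t|\t", db$parent, "\t|\t", db$rank, "\t|")
  names_l <- paste0(db$taxid, "\t|\t", db$name, "\t|\t", "", "\t|\t",
                    "scientific name", "\t|")
  writeLines(nodes, nodes_path)
  writeLines(names_l, names_path)
  invisible(c(nodes = nodes_path, names = names_path))
}
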