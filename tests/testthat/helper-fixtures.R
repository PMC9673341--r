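# Fixture taxonomies and independent brute-force oracles. The oracles share
# no code with the package internals: ancestry is recomputed by explicit
# parent-chasing on plain vectors.

# Hand-built 13-node taxonomy covering complete lineages, a species with no
# family/genus (KHT7-style, attached to an order), a species with family but
# no genus (RUG10048-style), and a strain node below a species.
tax_hand <- function() {
  taxonomy_db(
    taxid  = c(1L, 10L, 20L, 30L, 40L, 41L, 50L, 51L, 60L, 61L, 62L, 63L, 70L),
    parent_taxid = c(1L, 1L, 10L, 20L, 30L, 30L, 40L, 41L, 50L, 30L, 40L, 51L, 60L),
    rank   = c("no rank", "phylum", "class", "order", "family", "family",
               "genus", "genus", "species", "species", "species", "species",
               "no rank"),
    name   = c("root", "Phylumota", "Classia", "Orderales", "Famaceae",
               "Otheraceae", "Genusium", "Altgenus", "Genusium fullum",
               "Orderales bacterium KHT7", "Famaceae bacterium",
               "Altgenus altum", "Genusium fullum strain s1")
  )
}

# plain-vector root path, leaf first (independent of taxbench:::.root_path)
oracle_path <- function(db, taxid) {
  path <- integer(0)
  cur <- taxid
  repeat {
    path <- c(path, cur)
    i <- which(db$taxid == cur)
    if (db$parent[i] == cur) break
    cur <- db$parent[i]
  }
  path
}

oracle_rank_ancestor <- function(db, taxid, rank) {
  path <- oracle_path(db, taxid)
  rk <- db$rank[match(path, db$taxid)]
  hit <- path[rk == rank]
  if (length(hit)) hit[1L] else NA_integer_
}

oracle_lca <- function(db, taxids) {
  common <- Reduce(intersect, lapply(taxids, function(t) oracle_path(db, t)))
  depths <- db$depth[match(common, db$taxid)]
  common[which.max(depths)]
}

# a random tree over n nodes: node i's parent drawn among earlier nodes,
# ranks drawn from an open vocabulary
random_tax <- function(n, seed) {
  withr::with_seed(seed, {
    parent <- c(1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
    rank <- c("no rank",
              sample(c("phylum", "class", "order", "family", "genus",
                       "species", "no rank", "tribe", "subspecies"),
                     n - 1L, replace = TRUE))
    taxonomy_db(seq_len(n), parent, rank, paste0("node", seq_len(n)))
  })
}

# ---- classifier oracle --------------------------------------------------

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, 1:(n - k + 1), k:n)
  ok <- !grepl("[^ACGT]", km)
  km <- km[ok]
  rc <- vapply(km, revcomp_chr, "")
  pmin(km, rc)
}

# brute-force index: enumerate all k-mers per genome, group, LCA via oracle
oracle_kmer_index <- function(seqs, taxids, db, k) {
  per_genome <- lapply(seqs, function(s) unique(canonical_kmers(s, k)))
  all_km <- unique(unlist(per_genome))
  vals <- vapply(all_km, function(km) {
    src <- taxids[vapply(per_genome, function(g) km %in% g, logical(1))]
    oracle_lca(db, unique(src))
  }, integer(1))
  setNames(vals, all_km)
}

# exhaustive path-score classification: hits per taxid, candidates = union of
# root paths of hit taxids, score = hit counts summed along the candidate's
# own root path; deepest max, ties at equal depth -> LCA
oracle_classify <- function(index_map, db, seqs) {
  km <- unlist(lapply(seqs, canonical_kmers, k = nchar(names(index_map)[1L])))
  hit_tax <- unname(index_map[km[km %in% names(index_map)]])
  if (!length(hit_tax)) return(0L)
  hits <- table(hit_tax)
  hit_ids <- as.integer(names(hits))
  cand <- unique(unlist(lapply(hit_ids, function(t) oracle_path(db, t))))
  score <- vapply(cand, function(n) {
    p <- oracle_path(db, n)
    sum(as.integer(hits[as.character(intersect(p, hit_ids))]))
  }, integer(1))
  depth <- db$depth[match(cand, db$taxid)]
  best <- cand[score == max(score)]
  bdepth <- depth[score == max(score)]
  deepest <- best[bdepth == max(bdepth)]
  if (length(deepest) == 1L) deepest else oracle_lca(db, deepest)
}

random_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

# small community used by several end-to-end tests
small_sim <- function(n_species = 15, n_pairs = 1500, seed = 42,
                      mean_genome_length = 4000, ...) {
  cc <- community_config(n_species = n_species, n_read_pairs = n_pairs,
                         mean_genome_length = mean_genome_length, seed = seed, ...)
  tax <- generate_taxonomy(cc)
  genomes <- generate_genomes(tax$db, tax$genome_taxids, cc, seed = seed + 1)
  sim <- simulate_reads(genomes, tax$db, cc, seed = seed + 2)
  list(cc = cc, db = tax$db, genome_taxids = tax$genome_taxids,
       genomes = genomes, sim = sim)
}
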