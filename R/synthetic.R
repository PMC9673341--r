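# Synthetic study material: taxonomies with controllable lineage
# incompleteness, random genomes, abundance-weighted paired-end reads with a
# per-read truth table, and directly simulated classifier output with an
# injected error structure. Every generator is a pure function of
# (config, seed).

#' Community simulation configuration
#'
#' Parameters of the simulated microbial community and sequencing run.
#' Defaults emulate a scaled-down rumen-style simulation: paired-end short
#' reads drawn from genomes whose abundances follow an exponential
#' distribution, with a configurable fraction of species lacking family or
#' genus labels or carrying informal species names — the lineage structure
#' observed in metagenome-assembled genome collections.
#'
#' @param n_species Number of genomes/species in the community.
#' @param mean_genome_length Mean genome length in bases (individual lengths
#'   are uniform within ±20%).
#' @param abundance_model One of `"exponential"` (i.i.d. Exp(1) draws
#'   normalised to sum 1), `"lognormal"`, `"uniform"`.
#' @param n_read_pairs Total read pairs to simulate.
#' @param read_length Read length in bases.
#' @param insert_mean,insert_sd Fragment (insert) length distribution, bases.
#' @param substitution_rate Per-base substitution error probability.
#' @param missing_family_frac,missing_genus_frac Fractions of species whose
#'   lineage lacks the family / genus label. A species without a family label
#'   has no genus label either, so `missing_family_frac` must not exceed
#'   `missing_genus_frac` (this mirrors how the gaps occur in real MAG
#'   taxonomies).
#' @param informal_species_frac Fraction of fully-labelled species that
#'   nevertheless receive an informal species name (genus-less species always
#'   do; see [is_informal_name()]).
#' @param seed Default seed used by the generators.
#'
#' @return A validated list of class `community_config`.
#' @export
community_config <- function(n_species = 100L,
                             mean_genome_length = 20000L,
                             abundance_model = c("exponential", "lognormal", "uniform"),
                             n_read_pairs = 50000L,
                             read_length = 150L,
                             insert_mean = 400L,
                             insert_sd = 40L,
                             substitution_rate = 0,
                             missing_family_frac = 0,
                             missing_genus_frac = 0,
                             informal_species_frac = 0,
                             seed = 1L) {
  abundance_model <- match.arg(abundance_model)
  cfg <- list(n_species = as.integer(n_species),
              mean_genome_length = as.integer(mean_genome_length),
              abundance_model = abundance_model,
              n_read_pairs = as.integer(n_read_pairs),
              read_length = as.integer(read_length),
              insert_mean = as.integer(insert_mean),
              insert_sd = as.integer(insert_sd),
              substitution_rate = substitution_rate,
              missing_family_frac = missing_family_frac,
              missing_genus_frac = missing_genus_frac,
              informal_species_frac = informal_species_frac,
              seed = as.integer(seed))
  probs <- c("substitution_rate", "missing_family_frac", "missing_genus_frac",
             "informal_species_frac")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1) stop(p, " must lie in [0, 1]")
  }
  for (p in c("n_species", "n_read_pairs", "read_length", "insert_mean")) {
    if (is.na(cfg[[p]]) || cfg[[p]] < 1L) stop(p, " must be a positive count")
  }
  if (cfg$read_length > cfg$mean_genome_length) {
    stop("read_length must not exceed mean_genome_length")
  }
  if (cfg$missing_family_frac > cfg$missing_genus_frac) {
    stop("missing_family_frac must not exceed missing_genus_frac ",
         "(a genome without a family label has no genus label either)")
  }
  class(cfg) <- "community_config"
  cfg
}

# random latinate name stems, vectorised; deterministic under the caller's seed
.name_stems <- function(n) {
  syl <- c("ba", "ru", "mi", "co", "lac", "ther", "fi", "bre", "vi", "sel",
           "pre", "do", "ne", "cu", "ros", "ter", "ga", "lo", "xy", "me")
  k <- sample(2:4, n, replace = TRUE)
  stems <- vapply(k, function(m) paste0(sample(syl, m, replace = TRUE), collapse = ""),
                  "")
  # disambiguate repeats so scientific names stay unique
  make.unique(stems, sep = "")
}

.capitalise <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

#' Generate a taxonomy with controllable lineage incompleteness
#'
#' Builds a rooted taxonomy with superkingdom/phylum/class/order/family/genus
#' strata and one species node per community member. A `missing_genus_frac`
#' fraction of species have their genus omitted (the species is parented
#' directly to a family, or — for the `missing_family_frac` subset — to an
#' order, so those species lack both family and genus, the pattern of
#' "Bacteroidales bacterium KHT7"-style records). Genus-less species receive
#' informal names; an `informal_species_frac` fraction of the remaining
#' species do too.
#'
#' @param config A [community_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param strain_frac Fraction of species that additionally get one unranked
#'   strain child node (needed only to exercise over-resolved assignments).
#'
#' @return A list with `db` (a [taxonomy_db()]) and `genome_taxids` (the
#'   species taxids, one per community member).
#' @export
generate_taxonomy <- function(config, seed = config$seed, strain_frac = 0) {
  n <- config$n_species
  if (is.na(n) || n < 1L) stop("n_species must be >= 1")
  withr::with_seed(seed, {
    n_phy <- max(2L, ceiling(n / 40))
    n_cla <- max(n_phy, ceiling(n / 25))
    n_ord <- max(n_cla, ceiling(n / 12))
    n_fam <- max(n_ord, ceiling(n / 6))
    n_gen <- max(n_fam, ceiling(n / 2.5))

    taxid <- 1:2
    parent <- c(1L, 1L)
    rank <- c("no rank", "superkingdom")
    name <- c("root", "Bacteria")
    add_level <- function(n_new, rk, parents, names_new) {
      new_ids <- seq.int(length(taxid) + 1L, length.out = n_new)
      taxid <<- c(taxid, new_ids)
      parent <<- c(parent, parents)
      rank <<- c(rank, rep(rk, n_new))
      name <<- c(name, names_new)
      new_ids
    }
    phy <- add_level(n_phy, "phylum", rep(2L, n_phy),
                     paste0(.capitalise(.name_stems(n_phy)), "ota"))
    cla <- add_level(n_cla, "class", sample(phy, n_cla, replace = TRUE),
                     paste0(.capitalise(.name_stems(n_cla)), "ia"))
    ord <- add_level(n_ord, "order", sample(cla, n_ord, replace = TRUE),
                     paste0(.capitalise(.name_stems(n_ord)), "ales"))
    fam <- add_level(n_fam, "family", sample(ord, n_fam, replace = TRUE),
                     paste0(.capitalise(.name_stems(n_fam)), "aceae"))
    gen_names <- .capitalise(.name_stems(n_gen))
    gen <- add_level(n_gen, "genus", sample(fam, n_gen, replace = TRUE), gen_names)

    # one uniform draw per species; family-less species form a subset of the
    # genus-less ones, so the marginal genus-missing fraction is exact
    u <- runif(n)
    miss_gen <- u < config$missing_genus_frac
    miss_fam <- u < config$missing_family_frac
    sp_parent <- integer(n)
    sp_parent[!miss_gen] <- sample(gen, sum(!miss_gen), replace = TRUE)
    sp_parent[miss_gen & !miss_fam] <- sample(fam, sum(miss_gen & !miss_fam), replace = TRUE)
    sp_parent[miss_fam] <- sample(ord, sum(miss_fam), replace = TRUE)

    epithet <- paste0(.name_stems(n), sample(c("is", "um", "a", "ii"), n, replace = TRUE))
    sp_name <- character(n)
    full <- !miss_gen
    sp_name[full] <- paste(name[match(sp_parent[full], taxid)], epithet[full])
    informal_extra <- full & runif(n) < config$informal_species_frac
    sp_name[informal_extra] <- paste0("uncultured ",
                                      name[match(sp_parent[informal_extra], taxid)],
                                      " sp. TB", which(informal_extra))
    sp_name[miss_gen] <- paste0(name[match(sp_parent[miss_gen], taxid)],
                                " bacterium TB", which(miss_gen))
    sp <- add_level(n, "species", sp_parent, sp_name)

    if (strain_frac > 0) {
      with_strain <- which(runif(n) < strain_frac)
      if (length(with_strain)) {
        add_level(length(with_strain), "no rank", sp[with_strain],
                  paste0(sp_name[with_strain], " strain s", with_strain))
      }
    }

    list(db = taxonomy_db(taxid, parent, rank, name), genome_taxids = sp)
  })
}

#' Generate random genome sequences
#'
#' One record per taxid, i.i.d. uniform A/C/G/T, length uniform within
#' ±20% of `mean_genome_length`. Headers encode the taxid as
#' `"taxid|<id>|<name>"`, the format consumed by [build_kmer_index()].
#'
#' @param db A [taxonomy_db()].
#' @param genome_taxids Taxids (present in `db`) to generate genomes for.
#' @param config A [community_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#'
#' @return A named [Biostrings::DNAStringSet].
#' @export
generate_genomes <- function(db, genome_taxids, config, seed = config$seed) {
  idx <- .tax_idx(db, genome_taxids)
  withr::with_seed(seed, {
    n <- length(genome_taxids)
    len <- pmax(config$read_length,
                round(config$mean_genome_length * runif(n, 0.8, 1.2)))
    seqs <- vapply(len, function(L) {
      paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, "")
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- paste0("taxid|", db$taxid[idx], "|", db$name[idx])
    dss
  })
}

# parse "taxid|<id>|<name>" headers; hard error on anything else
.header_taxids <- function(headers) {
  parts <- strsplit(headers, "|", fixed = TRUE)
  ok <- lengths(parts) >= 2 & vapply(parts, `[[`, "", 1L) == "taxid"
  if (any(!ok)) stop("unparseable genome header (expected 'taxid|<id>|<name>'): ",
                     headers[!ok][1L])
  ids <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  if (anyNA(ids)) stop("unparseable taxid in genome header: ", headers[is.na(ids)][1L])
  ids
}

# in-place per-base substitution of a DNAStringSet, rate per base
.mutate_reads <- function(dss, rate) {
  if (rate <= 0) return(dss)
  n <- length(dss)
  L <- Biostrings::width(dss)
  nmut <- rbinom(n, L, rate)
  hit <- which(nmut > 0L)
  if (!length(hit)) return(dss)
  chars <- strsplit(as.character(dss[hit]), "", fixed = TRUE)
  bases <- c("A", "C", "G", "T")
  for (j in seq_along(hit)) {
    pos <- sample.int(L[hit[j]], nmut[hit[j]])
    cur <- chars[[j]][pos]
    chars[[j]][pos] <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), "")
  }
  dss[hit] <- Biostrings::DNAStringSet(vapply(chars, paste0, "", collapse = ""))
  dss
}

#' Simulate abundance-weighted paired-end reads with ground truth
#'
#' Draws per-genome relative abundances from the configured model, allocates
#' read pairs multinomially, samples fragments uniformly along each genome
#' (insert length normal, clipped to `[read_length, genome_length]`), takes
#' the forward mate from the fragment start and the reverse-complemented mate
#' from the fragment end, and applies per-base substitution errors. Each read
#' pair carries the taxid of its source genome in the truth table.
#'
#' Genomes shorter than `read_length` are skipped with a warning; if all are
#' skipped this is an error.
#'
#' @param genomes Named [Biostrings::DNAStringSet] with `"taxid|<id>|<name>"`
#'   headers, e.g. from [generate_genomes()].
#' @param db A [taxonomy_db()].
#' @param config A [community_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#'
#' @return A list: `r1`, `r2` ([Biostrings::DNAStringSet], names
#'   `"<id>/1"`/`"<id>/2"`), `truth` (data.table `read_id`, `taxid`; one row
#'   per pair), `truth_counts` (per canonical rank, data.table `taxid`,
#'   `reads` aggregated through [rank_ancestor()]), and `abundance`
#'   (data.table `taxid`, `fraction`, `read_pairs`).
#' @export
simulate_reads <- function(genomes, db, config, seed = config$seed) {
  taxids <- .header_taxids(names(genomes))
  .tax_idx(db, taxids)
  glen <- Biostrings::width(genomes)
  keep <- glen >= config$read_length
  if (any(!keep)) {
    warning("skipping ", sum(!keep), " genome(s) shorter than read_length")
    genomes <- genomes[keep]; taxids <- taxids[keep]; glen <- glen[keep]
  }
  if (!length(genomes)) stop("no genome is at least read_length bases long")

  withr::with_seed(seed, {
    ng <- length(genomes)
    ab <- switch(config$abundance_model,
                 exponential = rexp(ng, 1),
                 lognormal   = rlnorm(ng, 0, 1),
                 uniform     = runif(ng))
    ab <- ab / sum(ab)
    counts <- as.vector(rmultinom(1L, config$n_read_pairs, ab))

    rl <- config$read_length
    r1_parts <- vector("list", ng)
    r2_parts <- vector("list", ng)
    for (g in seq_len(ng)) {
      m <- counts[g]
      if (m == 0L) {
        r1_parts[[g]] <- Biostrings::DNAStringSet()
        r2_parts[[g]] <- Biostrings::DNAStringSet()
        next
      }
      ins <- pmin(pmax(round(rnorm(m, config$insert_mean, config$insert_sd)), rl),
                  glen[g])
      start <- 1L + floor(runif(m) * (glen[g] - ins + 1))
      frag <- Biostrings::extractAt(genomes[[g]],
                                    IRanges::IRanges(start = start, width = ins))
      r1_parts[[g]] <- Biostrings::subseq(frag, 1L, rl)
      r2_parts[[g]] <- Biostrings::reverseComplement(
        Biostrings::subseq(frag, ins - rl + 1L, ins))
    }
    r1 <- do.call(c, r1_parts)
    r2 <- do.call(c, r2_parts)
    truth_taxid <- rep(taxids, counts)

    perm <- sample.int(length(r1))
    r1 <- .mutate_reads(r1[perm], config$substitution_rate)
    r2 <- .mutate_reads(r2[perm], config$substitution_rate)
    truth_taxid <- truth_taxid[perm]

    ids <- sprintf("sim_%d", seq_along(r1))
    names(r1) <- paste0(ids, "/1")
    names(r2) <- paste0(ids, "/2")
    truth <- data.table::data.table(read_id = ids, taxid = truth_taxid)

    truth_counts <- lapply(db$canonical_ranks, function(r) {
      lab <- rank_ancestor(db, truth$taxid, r)
      dt <- data.table::data.table(taxid = lab)[!is.na(taxid), .(reads = .N), by = taxid]
      data.table::setorder(dt, taxid)
      dt
    })
    names(truth_counts) <- db$canonical_ranks

    list(r1 = r1, r2 = r2, truth = truth, truth_counts = truth_counts,
         abundance = data.table::data.table(taxid = taxids, fraction = ab,
                                            read_pairs = counts))
  })
}

#' Classifier error specification
#'
#' Per-read error structure for [simulate_classifier_output()]. Each read
#' pair is, independently: unclassified with probability `unclassified_frac`;
#' otherwise misassigned at rank r (to a uniformly chosen *other* node of
#' rank r) with probability `misassignment_frac[r]`; otherwise under-resolved
#' (assigned a uniformly chosen canonical-rank strict ancestor of its truth
#' taxon) with `under_resolution_frac`; otherwise over-resolved (assigned a
#' child node below its truth taxon, where one exists) with
#' `over_resolution_frac`; otherwise assigned its truth taxid.
#'
#' @param unclassified_frac Probability of an unclassified read.
#' @param misassignment_frac Named numeric vector, rank name -> probability.
#' @param under_resolution_frac,over_resolution_frac Probabilities.
#'
#' @return A validated list of class `error_spec`.
#' @export
error_spec <- function(unclassified_frac = 0,
                       misassignment_frac = numeric(0),
                       under_resolution_frac = 0,
                       over_resolution_frac = 0) {
  all_p <- c(unclassified_frac, misassignment_frac,
             under_resolution_frac, over_resolution_frac)
  if (any(is.na(all_p)) || any(all_p < 0) || any(all_p > 1)) {
    stop("error fractions must lie in [0, 1]")
  }
  if (sum(all_p) > 1 + 1e-12) {
    stop("error fractions sum to ", signif(sum(all_p), 4), " > 1")
  }
  if (length(misassignment_frac) && is.null(names(misassignment_frac))) {
    stop("misassignment_frac must be named by rank")
  }
  structure(list(unclassified_frac = unclassified_frac,
                 misassignment_frac = misassignment_frac,
                 under_resolution_frac = under_resolution_frac,
                 over_resolution_frac = over_resolution_frac),
            class = "error_spec")
}

#' Simulate classifier output with a known error structure
#'
#' Produces a classification record table exhibiting, at controlled rates,
#' exactly the pathologies seen in real read classification: unclassified
#' reads, reads assigned to the wrong taxon at a given rank, and assignments
#' above (under-resolved LCA fallback) or below the true node. Useful for
#' validating that the evaluation stage recovers injected error rates.
#'
#' @param truth data.table/data.frame with `read_id`, `taxid` (ground truth).
#' @param db A [taxonomy_db()] containing every truth taxid.
#' @param spec An [error_spec()].
#' @param seed Integer seed.
#'
#' @return A data.table with `status` ("C"/"U"), `read_id`, `taxid`
#'   (0 when unclassified), `length_field`, `lca_map` — the in-memory form of
#'   a Kraken-dialect output file (see [write_kraken_output()]).
#' @export
simulate_classifier_output <- function(truth, db, spec, seed = 1L) {
  stopifnot(inherits(spec, "error_spec"))
  truth_taxid <- as.integer(truth$taxid)
  .tax_idx(db, truth_taxid)
  n <- length(truth_taxid)

  withr::with_seed(seed, {
    u <- runif(n)
    assigned <- truth_taxid
    lo <- 0
    take <- function(p) {
      sel <- u >= lo & u < lo + p
      lo <<- lo + p
      sel
    }
    uncl <- take(spec$unclassified_frac)
    assigned[uncl] <- 0L

    for (r in names(spec$misassignment_frac)) {
      .check_rank(db, r)
      sel <- which(take(spec$misassignment_frac[[r]]))
      if (!length(sel)) next
      cand <- db$taxid[db$rank == r]
      if (length(cand) < 2L) stop("cannot misassign at rank '", r,
                                  "': fewer than two nodes of that rank")
      anc <- rank_ancestor(db, truth_taxid[sel], r)
      pick <- sample(cand, length(sel), replace = TRUE)
      while (any(bad <- !is.na(anc) & pick == anc)) {
        pick[bad] <- sample(cand, sum(bad), replace = TRUE)
      }
      assigned[sel] <- pick
    }

    sel_under <- which(take(spec$under_resolution_frac))
    if (length(sel_under)) {
      uniq <- unique(truth_taxid[sel_under])
      anc_list <- lapply(uniq, function(t) {
        path <- .root_path(db, t)[-1L]                      # strict ancestors
        path[db$rank[match(path, db$taxid)] %in% db$canonical_ranks]
      })
      names(anc_list) <- as.character(uniq)
      assigned[sel_under] <- vapply(truth_taxid[sel_under], function(t) {
        opts <- anc_list[[as.character(t)]]
        if (length(opts)) opts[sample.int(length(opts), 1L)] else t
      }, integer(1))
    }

    sel_over <- which(take(spec$over_resolution_frac))
    if (length(sel_over)) {
      uniq <- unique(truth_taxid[sel_over])
      kid_list <- lapply(uniq, function(t) db$taxid[db$parent == t & db$taxid != t])
      names(kid_list) <- as.character(uniq)
      assigned[sel_over] <- vapply(truth_taxid[sel_over], function(t) {
        opts <- kid_list[[as.character(t)]]
        if (length(opts)) opts[sample.int(length(opts), 1L)] else t
      }, integer(1))
    }

    data.table::data.table(status = ifelse(assigned == 0L, "U", "C"),
                           read_id = as.character(truth$read_id),
                           taxid = assigned,
                           length_field = "0|0",
                           lca_map = "")
  })
}
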