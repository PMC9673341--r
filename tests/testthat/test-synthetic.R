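test_that("generated taxonomies honour the lineage-incompleteness dials", {
  cc0 <- community_config(n_species = 60, seed = 3)
  gen0 <- generate_taxonomy(cc0)
  rep0 <- completeness_report(gen0$db, gen0$genome_taxids)
  expect_true(all(rep0$per_rank$n_missing == 0L))

  cc1 <- community_config(n_species = 60, missing_genus_frac = 1, seed = 3)
  gen1 <- generate_taxonomy(cc1)
  rep1 <- completeness_report(gen1$db, gen1$genome_taxids)
  expect_identical(rep1$per_rank$n_missing[rep1$per_rank$rank == "genus"], 60L)

  expect_error(community_config(n_species = 0), "positive")
  expect_error(community_config(missing_genus_frac = 1.2), "\\[0, 1\\]")
  expect_error(community_config(missing_family_frac = 0.5, missing_genus_frac = 0.1),
               "missing_family_frac")
})

test_that("the MAG-like preset fraction of genus-less species is recovered", {
  # 3849 of 4941 genomes without a genus label ~ 0.78
  frac <- 0.78
  cc <- community_config(n_species = 500, missing_genus_frac = frac,
                         missing_family_frac = 0.35, seed = 21)
  gen <- generate_taxonomy(cc)
  rep <- completeness_report(gen$db, gen$genome_taxids)
  miss_g <- rep$per_rank$n_missing[rep$per_rank$rank == "genus"]
  tol <- 3 * sqrt(500 * frac * (1 - frac))
  expect_lt(abs(miss_g - 500 * frac), tol + 1e-9)
  # family-less species are a subset of genus-less species
  miss_f <- rep$per_rank$n_missing[rep$per_rank$rank == "family"]
  expect_lte(miss_f, miss_g)
  # genus-less species carry informal names
  expect_gte(rep$n_informal, miss_g)
})

test_that("informal_species_frac adds informal names among labelled species", {
  cc <- community_config(n_species = 300, informal_species_frac = 0.4, seed = 5)
  gen <- generate_taxonomy(cc)
  rep <- completeness_report(gen$db, gen$genome_taxids)
  tol <- 3 * sqrt(300 * 0.4 * 0.6)
  expect_lt(abs(rep$n_informal - 120), tol + 1e-9)
})

test_that("genome generation is deterministic with plausible lengths and composition", {
  cc <- community_config(n_species = 3, mean_genome_length = 1000, seed = 9)
  gen <- generate_taxonomy(cc)
  g1 <- generate_genomes(gen$db, gen$genome_taxids, cc)
  g2 <- generate_genomes(gen$db, gen$genome_taxids, cc)
  expect_identical(as.character(g1), as.character(g2))
  expect_length(g1, 3L)
  expect_true(all(Biostrings::width(g1) >= 800 & Biostrings::width(g1) <= 1200))
  expect_match(names(g1), "^taxid\\|[0-9]+\\|")

  # dinucleotide composition of a long genome is uniform (chi-square)
  cc_big <- community_config(n_species = 1, mean_genome_length = 100000, seed = 10)
  gb <- generate_genomes(gen$db, gen$genome_taxids[1], cc_big)
  counts <- as.vector(Biostrings::dinucleotideFrequency(gb[[1]]))
  p <- chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("error-free reads are exact genome substrings and mates reverse-complement", {
  cc <- community_config(n_species = 1, mean_genome_length = 2000,
                         n_read_pairs = 10, seed = 13)
  gen <- generate_taxonomy(cc)
  genomes <- generate_genomes(gen$db, gen$genome_taxids, cc)
  sim <- simulate_reads(genomes, gen$db, cc)
  gseq <- as.character(genomes[[1]])
  for (i in seq_along(sim$r1)) {
    expect_true(grepl(as.character(sim$r1[[i]]), gseq, fixed = TRUE))
    expect_true(grepl(revcomp_chr(as.character(sim$r2[[i]])), gseq, fixed = TRUE))
  }
  expect_identical(sort(sim$truth$read_id),
                   sort(sub("/1$", "", names(sim$r1))))
})

test_that("uniform abundances spread read pairs evenly across genomes", {
  cc <- community_config(n_species = 4, mean_genome_length = 2000,
                         n_read_pairs = 10000, abundance_model = "uniform",
                         seed = 17)
  gen <- generate_taxonomy(cc)
  genomes <- generate_genomes(gen$db, gen$genome_taxids, cc)
  sim <- simulate_reads(genomes, gen$db, cc)
  counts <- sim$abundance$read_pairs
  expect_identical(sum(counts), 10000L)
  # multinomial with cell prob from uniform draws is not exactly 1/4; compare
  # against the drawn fractions instead
  exp_counts <- 10000 * sim$abundance$fraction
  se <- sqrt(10000 * sim$abundance$fraction * (1 - sim$abundance$fraction))
  expect_true(all(abs(counts - exp_counts) <= 3 * se + 1e-9))
})

test_that("exponential abundances follow an exponential Q-Q line", {
  cc <- community_config(n_species = 100, mean_genome_length = 600,
                         n_read_pairs = 100, seed = 19)
  gen <- generate_taxonomy(cc)
  genomes <- generate_genomes(gen$db, gen$genome_taxids, cc)
  sim <- simulate_reads(genomes, gen$db, cc)
  ab <- sort(sim$abundance$fraction)
  theo <- qexp(ppoints(100))
  r2 <- summary(lm(ab ~ theo))$r.squared
  expect_gte(r2, 0.9)
})

test_that("per-taxon truth counts aggregate the truth table through rank_ancestor", {
  env <- small_sim(n_species = 20, n_pairs = 2000, seed = 23,
                   missing_genus_frac = 0.4)
  for (r in env$db$canonical_ranks) {
    lab <- rank_ancestor(env$db, env$sim$truth$taxid, r)
    want <- table(lab[!is.na(lab)])
    got <- env$sim$truth_counts[[r]]
    expect_mapequal(setNames(got$reads, as.character(got$taxid)),
                    setNames(as.integer(want), names(want)))
    # shortfall at a rank equals reads from label-less genomes
    expect_identical(sum(got$reads) + sum(is.na(lab)), nrow(env$sim$truth))
  }
})

test_that("read simulation is a pure function of config and seed", {
  env1 <- small_sim(seed = 29)
  env2 <- small_sim(seed = 29)
  expect_identical(as.character(env1$sim$r1), as.character(env2$sim$r1))
  expect_identical(as.character(env1$sim$r2), as.character(env2$sim$r2))
  expect_identical(env1$sim$truth, env2$sim$truth)
})

test_that("substitution errors appear at roughly the configured rate", {
  cc <- community_config(n_species = 1, mean_genome_length = 5000,
                         n_read_pairs = 500, substitution_rate = 0.05, seed = 31)
  gen <- generate_taxonomy(cc)
  genomes <- generate_genomes(gen$db, gen$genome_taxids, cc)
  sim <- simulate_reads(genomes, gen$db, cc)
  # align by position: count mismatches of r1 against the source window
  gseq <- as.character(genomes[[1]])
  n_mm <- 0L; n_bases <- 0L
  for (i in seq_len(100)) {
    r <- as.character(sim$r1[[i]])
    # locate the closest error-free anchor by scanning all windows is costly;
    # instead just count reads that are no longer exact substrings
    n_mm <- n_mm + !grepl(r, gseq, fixed = TRUE)
    n_bases <- n_bases + 1L
  }
  # P(read untouched) = (1-0.05)^150 ~ 0.00045, so essentially all mutated
  expect_gte(n_mm / n_bases, 0.95)
})

test_that("simulated classifier output reproduces the error structure exactly at the extremes", {
  env <- small_sim(seed = 37)
  out0 <- simulate_classifier_output(env$sim$truth, env$db, error_spec(), seed = 1)
  expect_identical(out0$taxid, env$sim$truth$taxid)
  expect_true(all(out0$status == "C"))

  out1 <- simulate_classifier_output(env$sim$truth, env$db,
                                     error_spec(unclassified_frac = 1), seed = 1)
  expect_true(all(out1$taxid == 0L))
  expect_true(all(out1$status == "U"))

  expect_error(error_spec(unclassified_frac = 0.6,
                          misassignment_frac = c(genus = 0.5)), "sum")
})

test_that("misassignment lands on a different taxon of the requested rank", {
  env <- small_sim(n_species = 25, n_pairs = 3000, seed = 41)
  out <- simulate_classifier_output(
    env$sim$truth, env$db,
    error_spec(misassignment_frac = c(genus = 0.5)), seed = 2)
  moved <- out$taxid != env$sim$truth$taxid
  expect_gt(mean(moved), 0.4); expect_lt(mean(moved), 0.6)
  bad_rank <- env$db$rank[match(out$taxid[moved], env$db$taxid)]
  expect_true(all(bad_rank == "genus"))
  truth_g <- rank_ancestor(env$db, env$sim$truth$taxid[moved], "genus")
  expect_true(all(is.na(truth_g) | truth_g != out$taxid[moved]))
})
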