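# Hand-written status expectations on the hand-built taxonomy. Truth 61 is
# the species with no family/genus (KHT7-style); 62 has family but no genus
# (RUG10048-style); 60 and 63 have complete lineages; 70 is a strain below 60.

test_that("assign_status follows the five-way cascade on hand-picked cases", {
  db <- tax_hand()
  cases <- rbind(
    # truth, assigned, rank, expected
    data.frame(t = 61, a = 60, r = "family",  e = "truth_unknown"),
    data.frame(t = 61, a = 0,  r = "genus",   e = "truth_unknown"),
    data.frame(t = 61, a = 61, r = "species", e = "correct"),
    data.frame(t = 61, a = 61, r = "phylum",  e = "correct"),
    data.frame(t = 60, a = 62, r = "genus",   e = "unclassified_at_this_level"),
    data.frame(t = 60, a = 0,  r = "genus",   e = "unclassified_at_any_level"),
    data.frame(t = 60, a = 40, r = "genus",   e = "unclassified_at_this_level"),
    data.frame(t = 60, a = 40, r = "family",  e = "correct"),
    data.frame(t = 60, a = 60, r = "species", e = "correct"),
    data.frame(t = 60, a = 70, r = "species", e = "correct"),   # strain projects up
    data.frame(t = 60, a = 63, r = "species", e = "incorrect"),
    data.frame(t = 60, a = 63, r = "genus",   e = "incorrect"),
    data.frame(t = 60, a = 63, r = "phylum",  e = "correct"),
    data.frame(t = 62, a = 62, r = "genus",   e = "truth_unknown"),
    data.frame(t = 62, a = 62, r = "family",  e = "correct"),
    data.frame(t = 70, a = 60, r = "species", e = "correct"),
    data.frame(t = 63, a = 61, r = "family",  e = "unclassified_at_this_level"),
    data.frame(t = 63, a = 61, r = "species", e = "incorrect")
  )
  for (i in seq_len(nrow(cases))) {
    expect_identical(
      assign_status(db, cases$t[i], cases$a[i], cases$r[i]),
      cases$e[i],
      label = sprintf("truth=%d assigned=%d rank=%s", cases$t[i], cases$a[i],
                      cases$r[i]))
  }
  expect_error(assign_status(db, 999, 60, "genus"), "unknown taxid")
  expect_error(assign_status(db, 60, 60, "kingdom"), "unknown rank")
})

test_that("the status partition is an exhaustive single-valued function", {
  db <- tax_hand()
  truths <- c(60L, 61L, 62L, 63L, 70L)
  assigned <- c(db$taxid, 0L)
  # independent cascade built on the brute-force path oracle
  oracle_status <- function(t, a, r) {
    t_at <- oracle_rank_ancestor(db, t, r)
    if (is.na(t_at)) return("truth_unknown")
    if (a == 0L) return("unclassified_at_any_level")
    a_at <- oracle_rank_ancestor(db, a, r)
    if (is.na(a_at)) return("unclassified_at_this_level")
    if (a_at == t_at) "correct" else "incorrect"
  }
  for (r in c("phylum", "family", "genus", "species")) {
    for (t in truths) {
      got <- vapply(assigned, function(a) assign_status(db, t, a, r), "")
      want <- vapply(assigned, function(a) oracle_status(t, a, r), "")
      expect_identical(got, want)
      expect_true(all(got %in% c("correct", "incorrect",
                                 "unclassified_at_this_level",
                                 "unclassified_at_any_level", "truth_unknown")))
    }
  }
})

test_that("evaluate: identity classification gives 100% correct on complete lineages", {
  env <- small_sim(n_species = 10, n_pairs = 500, seed = 51)
  out <- simulate_classifier_output(env$sim$truth, env$db, error_spec(), seed = 1)
  ev <- evaluate(env$sim$truth, out, env$db)
  correct <- ev$status_pct[status == "correct"]
  expect_true(all(abs(correct$percent - 100) < 1e-9))
  expect_identical(ev$overall_classified_pct, 100)
  # hierarchical consistency on complete lineages: correct at species implies
  # correct everywhere above
  sbr <- ev$status_by_read
  at_sp <- sbr$status_species == "correct"
  expect_true(all(sbr$status_genus[at_sp] == "correct"))
  expect_true(all(sbr$status_phylum[at_sp] == "correct"))
})

test_that("evaluate: fully unclassified input is 100% unclassified_at_any_level", {
  env <- small_sim(n_species = 10, n_pairs = 400, seed = 53)
  out <- simulate_classifier_output(env$sim$truth, env$db,
                                    error_spec(unclassified_frac = 1), seed = 1)
  ev <- evaluate(env$sim$truth, out, env$db)
  uc <- ev$status_pct[status == "unclassified_at_any_level"]
  expect_true(all(abs(uc$percent - 100) < 1e-9))
  expect_identical(ev$overall_classified_pct, 0)
})

test_that("per rank the five status percentages always sum to 100", {
  env <- small_sim(n_species = 20, n_pairs = 2000, seed = 59,
                   missing_genus_frac = 0.5, missing_family_frac = 0.2)
  out <- simulate_classifier_output(
    env$sim$truth, env$db,
    error_spec(unclassified_frac = 0.2, misassignment_frac = c(genus = 0.1),
               under_resolution_frac = 0.15), seed = 3)
  ev <- evaluate(env$sim$truth, out, env$db)
  sums <- ev$status_pct[, .(s = sum(percent)), by = rank]$s
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("evaluate recovers an injected genus misassignment rate", {
  env <- small_sim(n_species = 30, n_pairs = 20000, seed = 61,
                   mean_genome_length = 2000)
  rate <- 0.10
  out <- simulate_classifier_output(
    env$sim$truth, env$db, error_spec(misassignment_frac = c(genus = rate)),
    seed = 4)
  ev <- evaluate(env$sim$truth, out, env$db)
  inc_g <- ev$status_pct[rank == "genus" & status == "incorrect"]$percent
  se <- sqrt(rate * (1 - rate) / 20000) * 100
  expect_lt(abs(inc_g - 100 * rate), 3 * se)
})

test_that("evaluate is invariant to read order and strict about coverage", {
  env <- small_sim(n_species = 10, n_pairs = 500, seed = 67)
  out <- simulate_classifier_output(env$sim$truth, env$db,
                                    error_spec(unclassified_frac = 0.3), seed = 5)
  ev1 <- evaluate(env$sim$truth, out, env$db)
  perm <- withr::with_seed(1, sample(nrow(out)))
  ev2 <- evaluate(env$sim$truth, out[perm], env$db)
  expect_equal(ev1$status_pct, ev2$status_pct)
  expect_identical(ev1$overall_classified_pct, ev2$overall_classified_pct)

  expect_error(evaluate(env$sim$truth, out[-1], env$db), "missing from classification")
  extra <- rbind(out, data.table::data.table(
    status = "C", read_id = "ghost_read", taxid = env$sim$truth$taxid[1],
    length_field = "0|0", lca_map = ""))
  expect_error(evaluate(env$sim$truth, extra, env$db), "absent from ground truth")
})

test_that("per-rank classification rate follows the assigned lineage's labels", {
  db <- tax_hand()
  truth <- data.table::data.table(read_id = c("r1", "r2", "r3", "r4"),
                                  taxid = c(60L, 60L, 60L, 60L))
  cls <- data.table::data.table(read_id = c("r1", "r2", "r3", "r4"),
                                taxid = c(60L, 62L, 40L, 0L),
                                status = c("C", "C", "C", "U"))
  ev <- evaluate(truth, cls, db)
  rates <- setNames(ev$rank_rates$classified_pct, ev$rank_rates$rank)
  expect_identical(rates[["species"]], 50)  # r1, r2 carry species labels
  expect_identical(rates[["genus"]], 25)    # only r1
  expect_identical(rates[["family"]], 75)   # r1, r2, r3
  expect_identical(ev$overall_classified_pct, 75)
})

test_that("taxon-level FP/FN comparison equals direct set algebra", {
  t_counts <- data.table::data.table(taxid = c(1L, 2L, 3L), reads = c(5L, 1L, 4L))
  c_counts <- data.table::data.table(taxid = c(2L, 3L, 9L), reads = c(2L, 1L, 7L))
  cmp <- taxon_set_comparison(t_counts, c_counts, "genus")
  expect_identical(cmp$false_positive_taxa, 9L)
  expect_identical(cmp$false_negative_taxa, 1L)
  expect_identical(cmp$n_fp, 1L); expect_identical(cmp$n_fn, 1L)

  same <- taxon_set_comparison(t_counts, t_counts, "genus")
  expect_identical(same$n_fp, 0L); expect_identical(same$n_fn, 0L)

  withr::with_seed(3, for (i in 1:20) {
    a <- data.table::data.table(taxid = sample(50, 20), reads = rbinom(20, 5, 0.5))
    b <- data.table::data.table(taxid = sample(50, 20), reads = rbinom(20, 5, 0.5))
    cmp <- taxon_set_comparison(a, b, "species")
    expect_setequal(cmp$false_positive_taxa,
                    setdiff(b$taxid[b$reads > 0], a$taxid[a$reads > 0]))
    expect_setequal(cmp$false_negative_taxa,
                    setdiff(a$taxid[a$reads > 0], b$taxid[b$reads > 0]))
  })
})

test_that("collection overlap projects to rank labels and partitions them", {
  db <- tax_hand()
  # A = {60, 61}: family labels {40}; B = {62, 63}: family labels {40, 41}
  ov <- collection_overlap(db, c(60L, 61L), c(62L, 63L), "family")
  expect_identical(ov$only_a, 0L)
  expect_identical(ov$only_b, 1L)
  expect_identical(ov$both, 1L)

  same <- collection_overlap(db, c(60L, 63L), c(60L, 63L), "genus")
  expect_identical(same$only_a, 0L); expect_identical(same$only_b, 0L)
  expect_identical(same$both, 2L)

  # disjoint label sets
  dis <- collection_overlap(db, 60L, 63L, "genus")
  expect_identical(dis$both, 0L)

  # random sets against a brute-force partition
  for (seed in 1:3) {
    rdb <- random_tax(80, seed + 200)
    withr::with_seed(seed, {
      A <- sample(rdb$taxid, 20); B <- sample(rdb$taxid, 20)
    })
    for (r in c("family", "genus")) {
      la <- unique(na.omit(vapply(A, oracle_rank_ancestor, integer(1),
                                  db = rdb, rank = r)))
      lb <- unique(na.omit(vapply(B, oracle_rank_ancestor, integer(1),
                                  db = rdb, rank = r)))
      ov <- collection_overlap(rdb, A, B, r)
      expect_identical(ov$only_a, length(setdiff(la, lb)))
      expect_identical(ov$only_b, length(setdiff(lb, la)))
      expect_identical(ov$both, length(intersect(la, lb)))
    }
  }
})
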