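test_that("tree simulation is deterministic and has the requested tips", {
  cfg <- simulate_config(n_taxa = 7, seed = 123)
  t1 <- simulate_tree(cfg)
  t2 <- simulate_tree(cfg)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(ape::Ntip(t1), 8L)  # 7 ingroup + outgroup
  expect_true("outgroup" %in% t1$tip.label)
  cfg3 <- simulate_config(n_taxa = 3, seed = 5)
  expect_equal(ape::Ntip(simulate_tree(cfg3)), 4L)
})

test_that("a zero event rate leaves every leaf at the root order", {
  cfg <- simulate_config(n_taxa = 5, seed = 31, lambda = 0)
  tr <- simulate_tree(cfg)
  evo <- evolve_orders(tr, cfg)
  for (go in evo$leaf_orders) {
    expect_true(go_equal(go, cfg$root_order))
  }
  expect_equal(sum(evo$truth$n_events_per_edge), 0L)
})

test_that("a forced reversal produces exactly one differing clade", {
  cfg <- simulate_config(n_taxa = 6, seed = 8, lambda = 0.4,
                         event_weights = c(T = 0, r = 1, rT = 0, tdrl = 0,
                                           d = 0, x = 0),
                         branch_mode = "at_most_one")
  tr <- simulate_tree(cfg)
  evo <- evolve_orders(tr, cfg)
  types <- unlist(lapply(evo$truth$events, function(evs)
    vapply(evs, `[[`, character(1), "type")))
  expect_true(all(types == "r"))
})

test_that("planted event totals follow the Poisson expectation", {
  tot <- 0; expect_tot <- 0
  for (seed in 1:30) {
    cfg <- simulate_config(n_taxa = 6, seed = 4000 + seed, lambda = 0.5)
    tr <- simulate_tree(cfg)
    evo <- evolve_orders(tr, cfg)
    tot <- tot + sum(evo$truth$n_events_per_edge)
    expect_tot <- expect_tot + cfg$lambda * sum(tr$edge.length)
  }
  # within 3 SE of the expectation
  expect_lt(abs(tot - expect_tot), 3 * sqrt(expect_tot))
})

test_that("truth ledger replays planted events to every leaf", {
  cfg <- simulate_config(n_taxa = 6, seed = 61, lambda = 0.5)
  tr <- simulate_tree(cfg)
  evo <- evolve_orders(tr, cfg)
  tree <- evo$truth$tree
  ntip <- length(tree$tip.label)
  for (e in seq_len(nrow(tree$edge))) {
    parent_go <- evo$truth$node_orders[[tree$edge[e, 1]]]
    cur <- parent_go
    for (ev in evo$truth$events[[e]]) cur <- apply_event(cur, ev)
    expect_true(go_equal(cur, evo$truth$node_orders[[tree$edge[e, 2]]]))
  }
})

test_that("synthesised sequences hit composition targets", {
  cfg <- simulate_config(n_taxa = 4, seed = 20, lambda = 0, at_skew = 0.3,
                         at_percent = 72, ur_percent = 12, ur_jitter = 0,
                         composition_noise = c(at_percent = 0, at_skew = 0,
                                               gc_skew = 0))
  sim <- simulate_dataset(cfg)
  for (rec in sim$records) {
    bc <- base_composition(rec)
    expect_lt(abs(bc$at_skew - 0.3), 0.03)
    expect_lt(abs(bc$at_percent - 72), 3)
    expect_lt(abs(unassigned_fraction(rec) - 12), 0.1)
    expect_true(rec$length > 14000 && rec$length < 20000)
  }
})

test_that("codon bias leaves a detectable RSCU signature", {
  cfg <- simulate_config(n_taxa = 3, seed = 21, lambda = 0, codon_bias = 1)
  rec <- simulate_dataset(cfg)$records[[1]]
  r <- rscu(codon_usage(rec))
  expect_gt(max(r), 1.3)
  cfg0 <- simulate_config(n_taxa = 3, seed = 21, lambda = 0, codon_bias = 0)
  rec0 <- simulate_dataset(cfg0)$records[[1]]
  r0 <- rscu(codon_usage(rec0))
  expect_lt(stats::sd(r0), stats::sd(r))
})

test_that("emitted GenBank files reproduce the planted orders exactly", {
  dir <- withr::local_tempdir()
  cfg <- simulate_config(n_taxa = 8, seed = 33, lambda = 0.4,
                         event_weights = c(T = 0.35, r = 0.25, rT = 0.1,
                                           tdrl = 0.3, d = 0, x = 0))
  sim <- simulate_dataset(cfg, out_dir = dir)
  files <- list.files(file.path(dir, "genbank"), full.names = TRUE)
  expect_length(files, 9L)  # 8 ingroup + outgroup
  for (f in files) {
    rec <- read_genbank(f, quiet = TRUE)
    expect_length(rec$diagnostics, 0)
    expect_true(go_equal(extract_gene_order(rec),
                         sim$leaf_orders[[rec$taxon_id]]))
  }
})

test_that("rate tables are deterministic and mode-dependent", {
  cfg <- simulate_config(n_taxa = 10, seed = 71, lambda = 0.8)
  tr <- simulate_tree(cfg)
  evo <- evolve_orders(tr, cfg)
  r1 <- make_rate_table(tr, evo$truth, cfg, mode = "null")
  r2 <- make_rate_table(tr, evo$truth, cfg, mode = "null")
  expect_identical(r1, r2)
  expect_equal(attr(r1, "linkage"), 0)
  rl <- make_rate_table(tr, evo$truth, cfg, mode = "linked", b = 0.5)
  expect_equal(attr(rl, "linkage"), 0.5)
  if (stats::sd(rl$true_events) > 0) {
    expect_gt(stats::cor(rl$rate, rl$true_events, method = "spearman"), 0)
  }
})
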