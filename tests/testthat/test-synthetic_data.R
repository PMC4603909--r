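test_that("simulation is deterministic given config and seed", {
  s1 <- simulate_genomes(quick_cfg(21))
  s2 <- simulate_genomes(quick_cfg(21))
  expect_identical(s1$tips$A$genes, s2$tips$A$genes)
  expect_identical(s1$tips$A$proteins, s2$tips$A$proteins)
  expect_identical(s1$tips$B$ssu, s2$tips$B$ssu)
  expect_identical(s1$truth$events, s2$truth$events)
  expect_identical(s1$reference, s2$reference)
  # and different seeds give different genomes
  s3 <- simulate_genomes(quick_cfg(22))
  expect_false(identical(s1$tips$A$proteins, s3$tips$A$proteins))
})

test_that("no TCS foci means no TCS proteins", {
  sim <- simulate_genomes(sim_config(seed = 3, n_background_genes = 30,
                                     n_tcs_foci = 0, ssu_length = 300,
                                     rates = zero_rates()))
  tcs <- classify_bundle(sim$tips$A)
  expect_equal(sum(tcs$tcs_class != "NONE"), 0L)
})

test_that("planted focus mixes classify as planted", {
  cfg <- sim_config(seed = 5, n_background_genes = 80, n_tcs_foci = 8,
                    focus_mix = c(orphan = 0, paired = 1, complex = 0,
                                  intricate = 0),
                    rates = zero_rates(), protein_rate_scaling = 0,
                    ssu_length = 300)
  sim <- simulate_genomes(cfg)
  b <- sim$ancestor
  f <- build_foci(b, classify_bundle(b))
  expect_equal(nrow(f), 8L)
  expect_true(all(f$category == "PAIRED"))

  cfg2 <- sim_config(seed = 6, n_background_genes = 80, n_tcs_foci = 6,
                     focus_mix = c(orphan = 0, paired = 0, complex = 0,
                                   intricate = 1),
                     rates = zero_rates(), protein_rate_scaling = 0,
                     ssu_length = 300)
  b2 <- simulate_genomes(cfg2)$ancestor
  f2 <- build_foci(b2, classify_bundle(b2))
  expect_true(all(f2$intricate))
})

test_that("zero rates and zero divergence reproduce the ancestor at tips", {
  cfg <- quick_cfg(9, rates = zero_rates(), protein_rate_scaling = 0)
  cfg$tree <- "(A:0,B:0);"
  sim <- simulate_genomes(cfg)
  anc <- sim$ancestor
  for (tp in c("A", "B")) {
    b <- sim$tips[[tp]]
    expect_equal(b$proteins$sequence, anc$proteins$sequence)
    expect_equal(b$genes$strand, anc$genes$strand)
    expect_equal(b$genes$rank, anc$genes$rank)
    expect_equal(b$ssu, anc$ssu)
  }
  expect_equal(nrow(sim$truth$events), 0L)
})

test_that("tip TCS counts obey the truth-log conservation arithmetic", {
  for (s in 1:5) {
    sim <- simulate_genomes(quick_cfg(s, rates = list(gene_loss = 12,
                                                      focus_loss = 4,
                                                      duplication = 8,
                                                      hgt_insertion = 250)))
    anc_tcs <- sum(classify_bundle(sim$ancestor)$tcs_class != "NONE")
    ev <- sim$truth$events
    for (tp in names(sim$tips)) {
      path <- sim$truth$paths[[tp]]
      on_path <- ev[ev$branch %in% path, , drop = FALSE]
      lost <- sum(on_path$n_genes[on_path$event_type %in%
                                    c("gene_loss", "focus_loss")])
      gained <- sum(on_path$event_type %in% c("duplication",
                                              "hgt_insertion"))
      tip_tcs <- sum(classify_bundle(sim$tips[[tp]])$tcs_class != "NONE")
      expect_equal(tip_tcs, anc_tcs - lost + gained, info = paste(s, tp))
    }
  }
})

test_that("event counts match their Poisson expectations (moment check)", {
  # gene_loss only, on a small genome; 120 replicates
  n_rep <- 120
  rate <- 3
  t_branch <- 0.02
  counts <- vapply(seq_len(n_rep), function(s) {
    cfg <- sim_config(seed = 5000 + s, n_background_genes = 30,
                      n_tcs_foci = 6, ssu_length = 120,
                      rates = c(zero_rates()[-1], list(gene_loss = rate)),
                      protein_rate_scaling = 0,
                      tree = sprintf("(A:%g,B:%g);", t_branch, t_branch))
    sim <- simulate_genomes(cfg)
    sum(sim$truth$events$event_type == "gene_loss")
  }, numeric(1))
  n_tcs <- sum(classify_bundle(simulate_genomes(
    sim_config(seed = 5001, n_background_genes = 30, n_tcs_foci = 6,
               ssu_length = 120, rates = zero_rates(),
               protein_rate_scaling = 0))$ancestor)$tcs_class != "NONE")
  expected <- 2 * rate * t_branch * n_tcs   # two branches
  se <- sqrt(expected / n_rep)
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.05)
})

test_that("distance regimes are increasing and degenerate input errors", {
  regs <- make_distance_regimes(quick_cfg(1))
  expect_length(regs, 4L)
  expect_named(regs, c("genus", "family", "sub-order", "order"))
  expect_error(make_distance_regimes(quick_cfg(1),
                                     distances = c(0.05, 0.05, 0.1, 0.2)),
               "degenerate-regimes")
})

test_that("frameshifts produce flagged, truncated pseudogenes", {
  cfg <- quick_cfg(13, rates = c(zero_rates()[-7], list(frameshift = 60)),
                   protein_rate_scaling = 0)
  sim <- simulate_genomes(cfg)
  ev <- sim$truth$events
  expect_gt(sum(ev$event_type == "frameshift"), 0)
  hit_tip <- sim$truth$paths[["A"]]
  fs <- ev[ev$event_type == "frameshift" & ev$branch %in% hit_tip, ]
  if (nrow(fs)) {
    o <- sim$truth$orthology$A
    tags <- o$locus_tag[o$origin %in% fs$origin]
    expect_true(all(sim$tips$A$genes$pseudogene[
      sim$tips$A$genes$locus_tag %in% tags]))
  }
})
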