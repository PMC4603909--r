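test_that("pairwise similarity handles the boundary cases", {
  s <- rand_aa(80)
  expect_equal(pairwise_similarity(s, s)$similarity, 1.0)
  # shorter-sequence denominator: perfect prefix in a longer protein
  set.seed(11)
  expect_equal(pairwise_similarity("ACDEFG",
                                   paste0("ACDEFG", rand_aa(60)))$similarity,
               1.0)
  expect_error(pairwise_similarity("", "ACD"), "empty-sequence")
})

test_that("similarity equals the independent DP oracle on random pairs", {
  set.seed(23)
  for (rep in 1:40) {
    a <- rand_aa(sample(10:60, 1))
    b <- if (runif(1) < 0.5) rand_aa(sample(10:60, 1)) else
      perturb(a, runif(1, 0, 0.5))
    expect_equal(pairwise_similarity(a, b)$similarity,
                 oracle_similarity(a, b), info = paste(a, b))
  }
})

test_that("greedy clustering follows the documented rule", {
  p3 <- data.frame(genome_id = "g", protein_id = c("p1", "p2", "p3"),
                   sequence = rep(rand_aa(100), 3))
  cl <- greedy_cluster(p3, 0.9)
  expect_equal(length(unique(cl$cluster_id)), 1L)

  # {AB: ~0.97, AC/BC: random}, cutoff 0.9 -> {A,B}, {C}
  set.seed(5)
  a <- rand_aa(120)
  p <- data.frame(genome_id = "g", protein_id = c("A", "B", "C"),
                  sequence = c(a, perturb(a, 0.03), rand_aa(120)))
  cl2 <- greedy_cluster(p, 0.9)
  grp <- split(cl2$protein_id, cl2$cluster_id)
  expect_true(any(vapply(grp, setequal, logical(1), c("A", "B"))))
  expect_true(any(vapply(grp, setequal, logical(1), "C")))

  # cutoff 1.0 on distinct sequences: all singletons
  pd <- data.frame(genome_id = "g", protein_id = paste0("q", 1:4),
                   sequence = vapply(1:4, function(i) rand_aa(90),
                                     character(1)))
  expect_equal(length(unique(greedy_cluster(pd, 1.0)$cluster_id)), 4L)
})

test_that("two-tier clustering splits paralogue agglomerations", {
  set.seed(9)
  a <- rand_aa(200)
  # genome-internal near-identical duplicates plus a divergent orthologue
  p <- data.frame(genome_id = c("g1", "g1", "g2"),
                  protein_id = c("d1", "d2", "o1"),
                  sequence = c(a, perturb(a, 0.02), perturb(a, 0.45)))
  cl <- two_tier_cluster(p, high = 0.90, low = 0.30)
  grp <- split(cl$members$protein_id, cl$members$cluster_id)
  expect_true(any(vapply(grp, setequal, logical(1), c("d1", "d2"))))
  expect_true(any(vapply(grp, setequal, logical(1), "o1")))
  expect_true(all(cl$members$tier[cl$members$protein_id %in%
                                    c("d1", "d2")] == "high"))

  # 1:1 pair at moderate similarity survives at the low tier
  b <- rand_aa(180)
  p2 <- data.frame(genome_id = c("g1", "g2"), protein_id = c("x", "y"),
                   sequence = c(b, perturb(b, 0.40)))
  cl2 <- two_tier_cluster(p2)
  expect_equal(length(unique(cl2$members$cluster_id)), 1L)
  expect_equal(unique(cl2$members$tier), "low")

  # mutually dissimilar proteins: all singletons
  p3 <- data.frame(genome_id = "g1", protein_id = paste0("s", 1:3),
                   sequence = vapply(1:3, function(i) rand_aa(150),
                                     character(1)))
  cl3 <- two_tier_cluster(p3)
  expect_equal(length(unique(cl3$members$cluster_id)), 3L)
})

test_that("emitted partition refines the low-tier partition (property)", {
  set.seed(31)
  for (rep in 1:20) {
    base <- replicate(sample(3:5, 1), rand_aa(sample(60:120, 1)))
    seqs <- unlist(lapply(base, function(s)
      replicate(sample(1:4, 1), perturb(s, runif(1, 0, 0.6)))))
    p <- data.frame(genome_id = sample(c("g1", "g2"), length(seqs), TRUE),
                    protein_id = sprintf("p%02d", seq_along(seqs)),
                    sequence = seqs)
    cl <- two_tier_cluster(p)
    # each emitted cluster must sit inside exactly one low-tier cluster
    low_of <- setNames(cl$low_tier$cluster_id, cl$low_tier$protein_id)
    for (cid in unique(cl$members$cluster_id)) {
      ids <- cl$members$protein_id[cl$members$cluster_id == cid]
      expect_equal(length(unique(low_of[ids])), 1L)
    }
    # both partitions are total and disjoint
    expect_setequal(cl$members$protein_id, p$protein_id)
    expect_false(any(duplicated(cl$members$protein_id)))
  }
})

test_that("reciprocal best hits require mutual unique maxima", {
  set.seed(13)
  a1 <- rand_aa(100); a2 <- rand_aa(100)
  protA <- data.frame(protein_id = c("A1", "A2"), sequence = c(a1, a2))
  protB <- data.frame(protein_id = c("B1", "B2"),
                      sequence = c(perturb(a1, 0.1), perturb(a2, 0.1)))
  rbh <- reciprocal_best_hits(protA, protB)
  expect_equal(nrow(rbh), 2L)
  expect_setequal(paste(rbh$a_id, rbh$b_id), c("A1 B1", "A2 B2"))
  # brute force: each pair is the row and column maximum
  m <- tcsevo:::similarity_matrix(setNames(protA$sequence, protA$protein_id),
                                  setNames(protB$sequence, protB$protein_id))
  for (r in seq_len(nrow(rbh))) {
    i <- rbh$a_id[r]; j <- rbh$b_id[r]
    expect_equal(max(m[i, ]), m[i, j])
    expect_equal(max(m[, j]), m[i, j])
  }
  # empty input
  expect_equal(nrow(reciprocal_best_hits(protA[0, ], protB)), 0L)
})

test_that("non-mutual best hits are excluded", {
  # B1 is closest to both A1 and A2, but B1's best is A2 only
  set.seed(17)
  base <- rand_aa(120)
  protA <- data.frame(protein_id = c("A1", "A2"),
                      sequence = c(perturb(base, 0.30), perturb(base, 0.05)))
  protB <- data.frame(protein_id = "B1", sequence = base)
  rbh <- reciprocal_best_hits(protA, protB)
  expect_equal(nrow(rbh), 1L)
  expect_equal(rbh$a_id, "A2")
})

test_that("cluster flags reflect member heterogeneity", {
  sim <- simulate_genomes(quick_cfg(2, rates = zero_rates(),
                                    protein_rate_scaling = 0))
  det <- run_pair_detection(sim)
  cl <- det$clusters
  # identical sister genomes: flag-free except benign cases
  expect_false(any(c("SIZE_DIFF", "ARCH_DIFF", "FAMILY_DIFF", "ORG_DIFF")
                   %in% cl$flags$flag))
  # manufactured heterogeneity
  ann <- data.frame(protein_id = c("x", "y"), genome_id = c("g1", "g2"),
                    locus_tag = c("x", "y"), tcs_class = "RR",
                    architecture = c("RT", "T"),
                    rr_family = c("NtrC", "LytTR"),
                    length = c(400L, 520L), pseudogene = FALSE,
                    focus_id = NA, category = c("PAIRED", "ORPHAN"),
                    notation = c("RT", "T"), rank = c(1L, 2L))
  fake <- structure(list(members = data.frame(
    cluster_id = "C0001", tier = "low", genome_id = c("g1", "g2"),
    protein_id = c("x", "y"), representative = "x"),
    low_tier = NULL, flags = NULL), class = "ortho_clusters")
  fl <- flag_clusters(fake, ann)
  expect_setequal(fl$flags$flag,
                  c("SIZE_DIFF", "ARCH_DIFF", "FAMILY_DIFF", "ORG_DIFF"))
  # singleton clusters never carry flags
  solo <- fake
  solo$members <- solo$members[1, ]
  expect_equal(nrow(flag_clusters(solo, ann)$flags), 0L)
})

test_that("orthology_fraction counts proteins in shared clusters", {
  members <- data.frame(
    cluster_id = c("C1", "C1", "C2", "C2", "C3"),
    tier = "low", genome_id = c("A", "B", "A", "B", "A"),
    protein_id = paste0("p", 1:5), representative = "r")
  cl <- structure(list(members = members), class = "ortho_clusters")
  expect_equal(orthology_fraction(cl, "A", "B"), 4 / 5)
  # all paired
  cl$members <- members[1:4, ]
  expect_equal(orthology_fraction(cl, "A", "B"), 1.0)
  # disjoint
  cl$members <- members[5, ]
  expect_equal(orthology_fraction(cl, "A", "B"), 0.0)
})
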