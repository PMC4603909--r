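mk_clusters <- function(...) {
  rows <- list(...)
  members <- do.call(rbind, lapply(seq_along(rows), function(i)
    data.frame(cluster_id = sprintf("C%02d", i), tier = "low",
               genome_id = rows[[i]]$g, protein_id = rows[[i]]$p,
               representative = rows[[i]]$p[1], stringsAsFactors = FALSE)))
  structure(list(members = members, low_tier = NULL, flags = NULL),
            class = "ortho_clusters")
}

test_that("singletons are proteins whose cluster lacks the other genome", {
  cl <- mk_clusters(list(g = c("A", "B"), p = c("a1", "b1")),
                    list(g = "A", p = "a2"))
  ev <- detect_singletons(cl, "A", "B")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$protein_id, "a2")
  # only 1:1 pairs: none
  cl2 <- mk_clusters(list(g = c("A", "B"), p = c("a1", "b1")))
  expect_equal(nrow(detect_singletons(cl2, "A", "B")), 0L)
})

test_that("duplications need >=2 copies in exactly one genome", {
  cl <- mk_clusters(list(g = c("A", "A", "B"), p = c("a1", "a2", "b1")),
                    list(g = c("A", "B"), p = c("a3", "b2")))
  ev <- detect_duplications(cl)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$genome_id, "A")
  expect_equal(ev$protein_id, "a1;a2")
  # local vs distal detail from ranks
  ann <- data.frame(protein_id = c("a1", "a2"), rank = c(10L, 11L))
  expect_equal(detect_duplications(cl, ann)$detail, "local")
  ann$rank <- c(10L, 300L)
  expect_equal(detect_duplications(cl, ann)$detail, "distal")
})

test_that("character changes are flagged per cluster and type", {
  cl <- mk_clusters(list(g = c("A", "B"), p = c("a1", "b1")))
  ann <- data.frame(protein_id = c("a1", "b1"), genome_id = c("A", "B"),
                    architecture = c("RT", "RT"),
                    rr_family = c(NA, NA), length = c(500L, 510L),
                    pseudogene = c(FALSE, FALSE),
                    category = c("PAIRED", "PAIRED"),
                    notation = c("RT,R", "RT"), stringsAsFactors = FALSE)
  ev <- detect_changes(cl, ann)
  expect_equal(ev$event_type, "ORG_CHANGE")   # notation differs

  ann2 <- ann
  ann2$notation <- "R"
  ann2$architecture <- "R"
  ann2$rr_family <- c("NtrC", "LytTR")
  expect_true("FAMILY_CHANGE" %in% detect_changes(cl, ann2)$event_type)

  ann3 <- ann
  ann3$notation <- "RT"
  expect_equal(nrow(detect_changes(cl, ann3)), 0L)

  ann4 <- ann3
  ann4$pseudogene <- c(TRUE, FALSE)
  expect_true("PSEUDOGENE" %in% detect_changes(cl, ann4)$event_type)

  ann5 <- ann3
  ann5$length <- c(400L, 520L)
  expect_true("SIZE_CHANGE" %in% detect_changes(cl, ann5)$event_type)
})

test_that("HGT flags depend on the best reference hit's clade label", {
  set.seed(19)
  foreign <- rand_aa(150)
  native <- rand_aa(150)
  sing <- data.frame(event_type = "SINGLETON", genome_id = c("A", "A"),
                     cluster_id = c("C1", "C2"),
                     protein_id = c("pF", "pN"), detail = "")
  prot <- data.frame(protein_id = c("pF", "pN"),
                     sequence = c(perturb(foreign, 0.05),
                                  perturb(native, 0.05)))
  ref <- data.frame(ref_id = c("r_for", "r_nat"),
                    label = c("other-order", "focal"),
                    sequence = c(foreign, native))
  ev <- flag_hgt(sing, prot, ref, focal_clade = "focal")
  expect_equal(ev$protein_id, "pF")
  expect_equal(ev$event_type, "HGT_CANDIDATE")
})

test_that("dot-plots recover identity, inversion and relocation patterns", {
  sim <- simulate_genomes(quick_cfg(4, rates = zero_rates(),
                                    protein_rate_scaling = 0))
  det <- run_pair_detection(sim)
  pts <- dotplot_points(det$clusters, sim$tips$A, sim$tips$B)
  expect_true(all(pts$a_rank == pts$b_rank))
  expect_equal(nrow(detect_relocations(pts)), 0L)

  # planted inversion: one anti-diagonal segment, no relocations
  bB <- plant_inversion(sim$tips$B)
  tcsB <- classify_bundle(bB)
  cl <- two_tier_cluster(rbind(tcs_proteins(sim$tips$A,
                                            classify_bundle(sim$tips$A)),
                               tcs_proteins(bB, tcsB)))
  pts2 <- dotplot_points(cl, sim$tips$A, bB)
  dirs <- tapply(pts2$direction, pts2$segment_id, function(x) x[1])
  expect_equal(sum(dirs == -1), 1L)
  expect_equal(nrow(detect_relocations(pts2)), 0L)

  # empty input
  e <- dotplot_points(structure(list(members = det$clusters$members[0, ]),
                                class = "ortho_clusters"),
                      sim$tips$A, sim$tips$B)
  expect_equal(nrow(e), 0L)
})

test_that("a single off-diagonal point is called as a relocation", {
  pts <- data.frame(cluster_id = sprintf("C%02d", 1:7),
                    a_locus = paste0("a", 1:7), b_locus = paste0("b", 1:7),
                    a_rank = c(1, 5, 9, 40, 13, 17, 21),
                    b_rank = c(1, 5, 9, 200, 13, 17, 21))
  pts <- pts[order(pts$a_rank), ]
  ev <- detect_relocations(pts)
  expect_equal(nrow(ev), 1L)
  expect_match(ev$protein_id, "a4;b4")
})

test_that("event frequencies respect their denominators", {
  cl <- mk_clusters(list(g = c("A", "B"), p = c("a1", "b1")),
                    list(g = c("A", "B"), p = c("a2", "b2")),
                    list(g = "A", p = "a3"))
  ev <- rbind(
    data.frame(event_type = "ORG_CHANGE", genome_id = NA,
               cluster_id = "C01", protein_id = "a1;b1", detail = ""),
    data.frame(event_type = "SINGLETON", genome_id = "A",
               cluster_id = "C03", protein_id = "a3", detail = ""))
  ft <- event_frequency_table(ev, cl)
  expect_true(all(ft$numerator <= ft$denominator))
  expect_equal(ft$percentage[ft$event_type == "ORG_CHANGE"], 50.0)  # 1 of 2
  expect_equal(ft$percentage[ft$event_type == "SINGLETON"],
               round_half_up(100 / 3, 1))
  # no events: all zeros
  ft0 <- event_frequency_table(ev[0, ], cl)
  expect_true(all(ft0$numerator == 0))
  # invariance under cluster relabelling
  cl2 <- cl
  map <- c(C01 = "K9", C02 = "K1", C03 = "K5")
  cl2$members$cluster_id <- unname(map[cl2$members$cluster_id])
  ev2 <- ev
  ev2$cluster_id <- unname(map[ev2$cluster_id])
  expect_equal(event_frequency_table(ev2, cl2)$percentage, ft$percentage)
})
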