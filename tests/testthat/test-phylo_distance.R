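test_that("gap-stripping removes exactly the gapped columns", {
  aln <- c(t1 = "ACGT", t2 = "ACGT")
  expect_equal(strip_gap_columns(aln), aln)

  aln2 <- c(t1 = "A-GT", t2 = "ACGT")
  expect_equal(unname(strip_gap_columns(aln2)), c("AGT", "AGT"))

  # random gapped alignment vs a per-column brute-force filter
  set.seed(3)
  for (rep in 1:10) {
    m <- matrix(sample(c("A", "C", "G", "T", "-"), 5 * 40, TRUE,
                       prob = c(rep(0.22, 4), 0.12)), nrow = 5)
    rownames(m) <- paste0("t", 1:5)
    aln3 <- apply(m, 1, paste, collapse = "")
    keep <- apply(m, 2, function(col) all(col != "-"))
    if (!any(keep)) {
      expect_error(strip_gap_columns(aln3), "no-ungapped-columns")
    } else {
      want <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
      expect_equal(strip_gap_columns(aln3), want)
    }
  }
  expect_error(strip_gap_columns(c(a = "--", b = "A-")),
               "no-ungapped-columns")
})

test_that("p-distances count mismatching columns, excluding N pairwise", {
  expect_equal(p_distance_matrix(c(a = "ACGTACGTAC",
                                   b = "ACGTACGTAC"))["a", "b"], 0)
  expect_equal(p_distance_matrix(c(a = "ACGTACGTAC",
                                   b = "ACGTACGTAT"))["a", "b"], 0.1)
  # N sites drop out of numerator and denominator
  d <- p_distance_matrix(c(a = "ANGT", b = "ACGA"))["a", "b"]
  expect_equal(d, 1 / 3)
  # column-scan oracle on random alignments
  set.seed(8)
  for (rep in 1:10) {
    m <- matrix(sample(c("A", "C", "G", "T", "N"), 4 * 60, TRUE,
                       prob = c(rep(0.23, 4), 0.08)), nrow = 4)
    rownames(m) <- paste0("t", 1:4)
    aln <- apply(m, 1, paste, collapse = "")
    D <- p_distance_matrix(aln)
    expect_true(isSymmetric(D))
    expect_true(all(diag(D) == 0))
    i <- sample(4, 1); j <- sample(setdiff(1:4, i), 1)
    ok <- m[i, ] != "N" & m[j, ] != "N"
    expect_equal(D[i, j], sum(m[i, ok] != m[j, ok]) / sum(ok))
  }
})

test_that("NJ reproduces additive distances and the 3-taxon closed form", {
  expect_error(nj_tree(matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "too-few-taxa")
  # closed form: d(ab)=2, d(ac)=3, d(bc)=4 -> branches 0.5, 1.5, 2.5
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d3)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(sort(unname(bl)), c(0.5, 1.5, 2.5))
  expect_equal(max(abs(ape::cophenetic.phylo(tr)[rownames(d3),
                                                 colnames(d3)] - d3)), 0,
               tolerance = 1e-12)
  # additive matrices from random trees are reproduced exactly
  set.seed(12)
  for (n in c(4, 5, 8)) {
    tr0 <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.4))
    d <- ape::cophenetic.phylo(tr0)
    t2 <- nj_tree(d)
    expect_lt(max(abs(ape::cophenetic.phylo(t2)[rownames(d),
                                                colnames(d)] - d)), 1e-9)
  }
})

test_that("bootstrap support behaves at the extremes", {
  # identical sequences: no internal splits at all
  aln <- setNames(rep(strrep("ACGT", 30), 4), paste0("t", 1:4))
  expect_length(bootstrap_support(aln, n = 20, seed = 1), 0L)
  # clearly structured data: supports within [0, 100]
  set.seed(2)
  root <- rand_dna(300)
  c1 <- perturb(root, 0.12, c("A", "C", "G", "T"))
  c2 <- perturb(root, 0.12, c("A", "C", "G", "T"))
  aln2 <- c(a1 = perturb(c1, 0.01, c("A", "C", "G", "T")),
            a2 = perturb(c1, 0.01, c("A", "C", "G", "T")),
            b1 = perturb(c2, 0.01, c("A", "C", "G", "T")),
            b2 = perturb(c2, 0.01, c("A", "C", "G", "T")))
  bs <- bootstrap_support(aln2, n = 50, seed = 4)
  expect_true(all(bs >= 0 & bs <= 100))
  expect_true(any(grepl("a1", names(bs))))
})

test_that("distance bands land on the largest sorted gaps", {
  d <- c(0.01, 0.012, 0.05, 0.055, 0.12, 0.13, 0.22, 0.23)
  pairs <- data.frame(a = letters[1:8], b = "z", distance = d)
  bands <- discretise_distances(pairs, k = 4)
  expect_equal(bands$assignment$band,
               rep(c("genus", "family", "sub-order", "order"), each = 2))
  expect_length(bands$boundaries, 3L)
  expect_true(all(diff(bands$boundaries) > 0))
  # permutation invariance
  perm <- sample(nrow(pairs))
  b2 <- discretise_distances(pairs[perm, ], k = 4)
  expect_equal(b2$assignment$band[order(perm)], bands$assignment$band)
  # degenerate inputs
  expect_error(discretise_distances(data.frame(a = 1:4, b = 1,
                                               distance = rep(0.1, 4))),
               "too-few-distinct")
  one <- discretise_distances(pairs, k = 1)
  expect_equal(unique(one$assignment$band), "band1")
})

test_that("exponential fit recovers parameters and rejects bad input", {
  d <- c(0.01, 0.05, 0.1, 0.2)
  f <- fit_exponential(d, 0.9 * exp(-25 * d))
  expect_equal(f$a, 0.9, tolerance = 1e-6)
  expect_equal(f$b, 25, tolerance = 1e-6)
  expect_lt(f$residual, 1e-10)
  # two points: exact interpolation
  f2 <- fit_exponential(c(0.02, 0.1), c(0.8, 0.3))
  expect_equal(f2$residual, 0, tolerance = 1e-12)
  expect_error(fit_exponential(c(0.1), c(0.5)), "too-few-points")
  expect_error(fit_exponential(c(0.1, 0.2), c(0.5, 0)), "non-positive-y")
  # noisy decay agrees with an independently computed log-linear fit
  set.seed(6)
  dd <- seq(0.01, 0.2, length.out = 12)
  yy <- 0.85 * exp(-12 * dd) * exp(rnorm(12, 0, 0.05))
  f3 <- fit_exponential(dd, yy)
  ly <- log(yy)
  slope <- sum((dd - mean(dd)) * (ly - mean(ly))) / sum((dd - mean(dd))^2)
  expect_equal(f3$b, -slope, tolerance = 1e-10)
  expect_equal(f3$a, exp(mean(ly) - slope * mean(dd)), tolerance = 1e-10)
})
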