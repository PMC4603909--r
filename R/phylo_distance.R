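#' Remove alignment columns containing gaps
#'
#' Distances are computed on gap-free columns only, so any column holding
#' a `-` in any row is dropped from every row.
#'
#' @param aln named character vector of equal-length gapped nucleotide
#'   strings (alphabet A, C, G, T, N, -).
#' @return the alignment with gapped columns removed.
#' @export
strip_gap_columns <- function(aln) {
  m <- aln_matrix(aln)
  keep <- colSums(m == "-") == 0
  if (!any(keep)) abort("no-ungapped-columns", "every column contains a gap")
  m <- m[, keep, drop = FALSE]
  setNames(apply(m, 1, paste, collapse = ""), names(aln))
}

aln_matrix <- function(aln) {
  if (length(unique(nchar(aln))) > 1)
    abort("ragged-alignment", "rows differ in length")
  do.call(rbind, strsplit(unname(aln), ""))
}

#' Pairwise p-distance matrix
#'
#' d(i, j) is the proportion of mismatching columns (substitutions per
#' nucleotide position). `N` is uninformative: columns where either row
#' has `N` are excluded from that pair's numerator and denominator.
#'
#' @param aln gap-stripped alignment (see [strip_gap_columns()]).
#' @return symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
p_distance_matrix <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      ok <- m[i, ] != "N" & m[j, ] != "N"
      d[i, j] <- d[j, i] <-
        if (any(ok)) sum(m[i, ok] != m[j, ok]) / sum(ok) else 0
    }
  }
  d
}

#' Neighbour-joining tree
#'
#' Standard neighbour-joining agglomeration (via \pkg{ape}), with negative
#' branch-length estimates clamped to zero.
#'
#' @param d symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return an [ape::phylo] object (unrooted, with branch lengths).
#' @export
nj_tree <- function(d) {
  if (nrow(as.matrix(d)) < 3)
    abort("too-few-taxa", "neighbour-joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(as.matrix(d)))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# internal: canonical non-trivial bipartitions of an unrooted tree.
# Zero-length internal edges are collapsed first, so star-like trees
# report no splits. Each split is the lexicographically smaller side,
# sorted, pasted with "|".
tree_splits <- function(tree, collapse_zero = TRUE) {
  if (collapse_zero && !is.null(tree$edge.length))
    tree <- ape::di2multi(tree, tol = 1e-10)
  tips <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  out <- character(0)
  for (cl in pp) {
    side <- sort(attr(pp, "labels")[cl])
    comp <- setdiff(tips, side)
    if (length(side) < 2 || length(comp) < 2) next
    a <- paste(side, collapse = "|")
    b <- paste(comp, collapse = "|")
    out <- c(out, if (a < b) a else b)
  }
  unique(out)
}

#' Bootstrap support for neighbour-joining splits
#'
#' Resamples alignment columns with replacement `n` times, rebuilds the NJ
#' tree for each replicate, and reports for each internal split of the
#' point-estimate tree the percentage of replicate trees containing it.
#'
#' @param aln gap-stripped alignment (named character vector).
#' @param n number of replicates.
#' @param seed RNG seed (randomness is always explicit).
#' @return named numeric vector, split -> support in \[0, 100\]; empty
#'   when the point tree has no internal splits.
#' @export
bootstrap_support <- function(aln, n = 1000, seed = 1) {
  m <- aln_matrix(aln)
  point <- nj_tree(p_distance_matrix(aln))
  splits <- tree_splits(point)
  if (!length(splits)) return(setNames(numeric(0), character(0)))
  counts <- setNames(numeric(length(splits)), splits)
  set.seed(seed)
  for (r in seq_len(n)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_aln <- setNames(apply(m[, cols, drop = FALSE], 1, paste,
                              collapse = ""), rownames(m))
    names(rep_aln) <- names(aln)
    rs <- tree_splits(nj_tree(p_distance_matrix(rep_aln)),
                      collapse_zero = FALSE)  # topology counts as-is
    hit <- splits %in% rs
    counts[hit] <- counts[hit] + 1
  }
  100 * counts / n
}

#' Discretise pairwise distances into bands
#'
#' Sorts the distances and places the k-1 band boundaries at the k-1
#' largest gaps between adjacent values in the sorted sequence. For k = 4
#' the bands are labelled, in ascending distance order, `genus`, `family`,
#' `sub-order`, `order`; otherwise `band1..bandk`.
#'
#' @param pairs data.frame with columns `a`, `b`, `distance` (or a named
#'   numeric vector of distances, in which case pair labels are taken from
#'   the names).
#' @param k number of bands (default 4).
#' @return list of class `distance_bands`: `k`, `boundaries` (strictly
#'   increasing thresholds, length k-1) and `assignment` (the input pairs
#'   with a `band` column).
#' @export
discretise_distances <- function(pairs, k = 4) {
  if (is.numeric(pairs)) {
    pairs <- data.frame(a = names(pairs) %||% as.character(seq_along(pairs)),
                        b = NA_character_, distance = unname(pairs),
                        stringsAsFactors = FALSE)
  }
  d <- pairs$distance
  if (length(unique(d)) < k)
    abort("too-few-distinct-distances",
          "need at least k distinct distances, got ",
          length(unique(d)), " for k = ", k)
  labels <- if (k == 4) c("genus", "family", "sub-order", "order") else
    paste0("band", seq_len(k))
  if (k == 1) {
    pairs$band <- labels[1]
    return(structure(list(k = k, boundaries = numeric(0),
                          assignment = pairs), class = "distance_bands"))
  }
  s <- sort(d)
  gaps <- diff(s)
  cut_idx <- sort(order(gaps, decreasing = TRUE)[seq_len(k - 1)])
  boundaries <- (s[cut_idx] + s[cut_idx + 1]) / 2
  band <- findInterval(d, boundaries) + 1L
  pairs$band <- labels[band]
  structure(list(k = k, boundaries = boundaries, assignment = pairs),
            class = "distance_bands")
}

#' @export
print.distance_bands <- function(x, ...) {
  cat(sprintf("distance_bands: k = %d, boundaries = %s\n", x$k,
              paste(signif(x$boundaries, 4), collapse = ", ")))
  print(table(x$assignment$band))
  invisible(x)
}

#' Fit an exponential decay y = a * exp(-b * d)
#'
#' Least-squares fit via linear regression on log(y); used for the
#' orthology-fraction versus 16S-distance relationship.
#'
#' @param d distances.
#' @param y positive fractions.
#' @return list `a`, `b`, `residual` (RMS of log-space residuals).
#' @export
fit_exponential <- function(d, y) {
  if (length(d) < 2) abort("too-few-points", "need at least 2 points")
  if (any(y <= 0)) abort("non-positive-y", "fractions must be > 0")
  fit <- lm(log(y) ~ d)
  list(a = unname(exp(coef(fit)[1])), b = unname(-coef(fit)[2]),
       residual = sqrt(mean(residuals(fit)^2)))
}
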