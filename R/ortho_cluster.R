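#' Alignment scoring parameters
#'
#' Similarity is the identity fraction of a global (end-to-end) alignment:
#' identities divided by the shorter sequence's length, the semantics of
#' greedy incremental clustering tools. Among equal-scoring alignments the
#' one with most identities is used, which makes the statistic exact and
#' implementation-independent. Substitution preference beyond
#' match/mismatch is irrelevant to identity counting, so a simple
#' match/mismatch matrix is used; gap costs are affine (a gap of length L
#' costs `gap_open + gap_ext * L`).
#'
#' @param match,mismatch per-residue scores.
#' @param gap_open,gap_ext affine gap penalties (positive costs).
#' @export
align_scoring <- function(match = 2, mismatch = -1, gap_open = 10,
                          gap_ext = 1) {
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext))
}

#' Pairwise global-alignment similarity
#'
#' @param a,b amino-acid sequences (non-empty strings).
#' @param a_id,b_id optional ids recorded in the result.
#' @param scoring see [align_scoring()].
#' @return one-row data.frame `a_id`, `b_id`, `similarity` (fraction in
#'   \[0, 1\]).
#' @export
pairwise_similarity <- function(a, b, a_id = "a", b_id = "b",
                                scoring = align_scoring()) {
  if (!nzchar(a) || !nzchar(b))
    abort("empty-sequence", "cannot align an empty sequence")
  r <- align_matches_cpp(a, b, scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_ext)
  data.frame(a_id = a_id, b_id = b_id,
             similarity = unname(r[["matches"]]) / min(nchar(a), nchar(b)),
             stringsAsFactors = FALSE)
}

# internal: similarity matrix between two sequence sets
similarity_matrix <- function(seqs_a, seqs_b, scoring = align_scoring()) {
  m <- similarity_matrix_cpp(unname(seqs_a), unname(seqs_b),
                             scoring$match, scoring$mismatch,
                             scoring$gap_open, scoring$gap_ext)
  dimnames(m) <- list(names(seqs_a), names(seqs_b))
  m
}

#' TCS protein sequence table for clustering
#'
#' @param b a `genome_bundle`.
#' @param tcs classification table from [classify_bundle()].
#' @return data.frame `genome_id`, `protein_id`, `sequence` restricted to
#'   proteins with a TCS class other than NONE.
#' @export
tcs_proteins <- function(b, tcs) {
  keep <- tcs$protein_id[tcs$tcs_class != "NONE"]
  p <- b$proteins[b$proteins$protein_id %in% keep, , drop = FALSE]
  data.frame(genome_id = b$genome_id, protein_id = p$protein_id,
             sequence = p$sequence, stringsAsFactors = FALSE)
}

#' Greedy incremental clustering at a single similarity cut-off
#'
#' Proteins are sorted by length descending (ties: protein id ascending).
#' Each protein joins the first existing cluster (in founding order) whose
#' representative it matches at `similarity >= cutoff`, otherwise it
#' founds a new cluster with itself as representative. Deterministic.
#'
#' @param proteins data.frame with `genome_id`, `protein_id`, `sequence`.
#' @param cutoff similarity threshold in (0, 1].
#' @param scoring see [align_scoring()].
#' @param tier label recorded on each emitted cluster row.
#' @return data.frame `cluster_id`, `tier`, `genome_id`, `protein_id`,
#'   `representative`.
#' @export
greedy_cluster <- function(proteins, cutoff, scoring = align_scoring(),
                           tier = as.character(cutoff)) {
  stopifnot(cutoff > 0, cutoff <= 1)
  p <- proteins[order(-nchar(proteins$sequence), proteins$protein_id), ,
                drop = FALSE]
  rep_idx <- integer(0)            # row index of each cluster's representative
  assignment <- integer(nrow(p))   # cluster number per row of p
  for (i in seq_len(nrow(p))) {
    hit <- 0L
    if (length(rep_idx)) {
      sims <- similarity_matrix_cpp(p$sequence[i], p$sequence[rep_idx],
                                    scoring$match, scoring$mismatch,
                                    scoring$gap_open, scoring$gap_ext)
      ok <- which(sims[1, ] >= cutoff)
      if (length(ok)) hit <- ok[1]
    }
    if (hit == 0L) {
      rep_idx <- c(rep_idx, i)
      hit <- length(rep_idx)
    }
    assignment[i] <- hit
  }
  data.frame(cluster_id = sprintf("C%04d", assignment), tier = tier,
             genome_id = p$genome_id, protein_id = p$protein_id,
             representative = p$protein_id[rep_idx[assignment]],
             stringsAsFactors = FALSE)
}

#' Two-tier clustering with automated curation split
#'
#' Clusters at the permissive cut-off first. Any low-tier cluster in which
#' some genome contributes more than one member (a paralogue
#' agglomeration) is replaced by its high-confidence sub-clusters,
#' obtained by re-running the greedy procedure within the cluster at the
#' strict cut-off; this automates the manual curation split. Emitted
#' clusters therefore always refine the low-tier partition.
#'
#' @param proteins data.frame with `genome_id`, `protein_id`, `sequence`.
#' @param high,low strict and permissive cut-offs (`high > low`).
#' @param scoring see [align_scoring()].
#' @return object of class `ortho_clusters`: list with `members` (the
#'   emitted partition, with per-cluster provenance in `tier`) and
#'   `low_tier` (the unsplit low cut-off partition).
#' @export
two_tier_cluster <- function(proteins, high = 0.90, low = 0.30,
                             scoring = align_scoring()) {
  stopifnot(high > low)
  lowm <- greedy_cluster(proteins, low, scoring, tier = "low")
  seqs <- setNames(proteins$sequence, proteins$protein_id)
  genomes <- setNames(proteins$genome_id, proteins$protein_id)
  out <- list()
  k <- 0L
  for (cid in unique(lowm$cluster_id)) {
    mem <- lowm[lowm$cluster_id == cid, , drop = FALSE]
    multi <- any(table(mem$genome_id) >= 2)
    if (multi && nrow(mem) > 1) {
      sub <- greedy_cluster(
        data.frame(genome_id = unname(genomes[mem$protein_id]),
                   protein_id = mem$protein_id,
                   sequence = unname(seqs[mem$protein_id]),
                   stringsAsFactors = FALSE),
        high, scoring, tier = "high")
      for (scid in unique(sub$cluster_id)) {
        k <- k + 1L
        s <- sub[sub$cluster_id == scid, , drop = FALSE]
        s$cluster_id <- sprintf("C%04d", k)
        out[[length(out) + 1L]] <- s
      }
    } else {
      k <- k + 1L
      mem$cluster_id <- sprintf("C%04d", k)
      out[[length(out) + 1L]] <- mem
    }
  }
  structure(list(members = do.call(rbind, out), low_tier = lowm,
                 flags = NULL),
            class = "ortho_clusters")
}

#' @export
print.ortho_clusters <- function(x, ...) {
  cat(sprintf("ortho_clusters: %d proteins in %d clusters (%d split at high tier)\n",
              nrow(x$members), length(unique(x$members$cluster_id)),
              sum(tapply(x$members$tier, x$members$cluster_id,
                         function(t) t[1] == "high"))))
  invisible(x)
}

#' Reciprocal best hits between two genomes
#'
#' Pairs where each protein is the other's unique best cross-genome hit;
#' ties for the best score exclude the pair (conservative).
#'
#' @param protA,protB data.frames with `protein_id`, `sequence`.
#' @param scoring see [align_scoring()].
#' @return data.frame `a_id`, `b_id`, `similarity`.
#' @export
reciprocal_best_hits <- function(protA, protB, scoring = align_scoring()) {
  empty <- data.frame(a_id = character(), b_id = character(),
                      similarity = numeric(), stringsAsFactors = FALSE)
  if (!nrow(protA) || !nrow(protB)) return(empty)
  m <- similarity_matrix(setNames(protA$sequence, protA$protein_id),
                         setNames(protB$sequence, protB$protein_id),
                         scoring)
  rows <- list()
  for (i in seq_len(nrow(m))) {
    mx <- max(m[i, ])
    js <- which(m[i, ] == mx)
    if (length(js) != 1L) next
    j <- js
    if (max(m[, j]) != m[i, j]) next
    if (sum(m[, j] == m[i, j]) != 1L) next
    rows[[length(rows) + 1L]] <- data.frame(
      a_id = rownames(m)[i], b_id = colnames(m)[j], similarity = m[i, j],
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else empty
}

#' Per-protein annotation table for flagging and event inference
#'
#' Joins classification, focus membership and pseudogene status into one
#' row per TCS protein.
#'
#' @param b a `genome_bundle`.
#' @param tcs classification table from [classify_bundle()].
#' @param foci focus table from [build_foci()].
#' @return data.frame `protein_id`, `genome_id`, `locus_tag`,
#'   `architecture`, `rr_family`, `length`, `pseudogene`, `focus_id`,
#'   `category`, `notation`, `rank`.
#' @export
annotate_proteins <- function(b, tcs, foci) {
  ann <- tcs[tcs$tcs_class != "NONE",
             c("protein_id", "genome_id", "locus_tag", "tcs_class",
               "architecture", "rr_family", "length", "pseudogene")]
  focus_of <- list()
  for (i in seq_len(nrow(foci))) {
    for (tag in foci$members[[i]]) focus_of[[tag]] <- i
  }
  idx <- vapply(ann$locus_tag, function(t) focus_of[[t]] %||% NA_integer_,
                integer(1))
  ann$focus_id <- ifelse(is.na(idx), NA_character_, foci$focus_id[idx])
  ann$category <- ifelse(is.na(idx), NA_character_, foci$category[idx])
  ann$notation <- ifelse(is.na(idx), NA_character_, foci$notation[idx])
  rk <- setNames(b$genes$rank, b$genes$locus_tag)
  ann$rank <- unname(rk[ann$locus_tag])
  rownames(ann) <- NULL
  ann
}

#' Flag clusters with heterogeneous members
#'
#' `SIZE_DIFF`: member length span exceeds `size_threshold` residues.
#' `ARCH_DIFF`: more than one distinct architecture string.
#' `FAMILY_DIFF`: more than one distinct RR family among members that have
#' one. `ORG_DIFF`: more than one distinct focus category. `MULTIPLICITY`:
#' some genome contributes two or more members. Singleton clusters carry
#' no flags.
#'
#' @param clusters an `ortho_clusters` object.
#' @param ann annotation table ([annotate_proteins()], rbind-ed across
#'   genomes).
#' @param size_threshold residue difference regarded as a size change
#'   (default 100).
#' @return the `ortho_clusters` object with `flags` set: data.frame
#'   `cluster_id`, `flag`.
#' @export
flag_clusters <- function(clusters, ann, size_threshold = 100) {
  a <- ann[match(clusters$members$protein_id, ann$protein_id), ]
  rows <- list()
  add <- function(cid, flag)
    rows[[length(rows) + 1L]] <<- data.frame(cluster_id = cid, flag = flag,
                                             stringsAsFactors = FALSE)
  for (cid in unique(clusters$members$cluster_id)) {
    sel <- clusters$members$cluster_id == cid
    if (sum(sel) < 2) next
    ai <- a[sel, , drop = FALSE]
    if (diff(range(ai$length)) > size_threshold) add(cid, "SIZE_DIFF")
    if (length(unique(ai$architecture)) > 1) add(cid, "ARCH_DIFF")
    fams <- unique(ai$rr_family[!is.na(ai$rr_family)])
    if (length(fams) > 1) add(cid, "FAMILY_DIFF")
    cats <- unique(ai$category[!is.na(ai$category)])
    if (length(cats) > 1) add(cid, "ORG_DIFF")
    if (any(table(ai$genome_id) >= 2)) add(cid, "MULTIPLICITY")
  }
  clusters$flags <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = character(), flag = character(),
               stringsAsFactors = FALSE)
  clusters
}

#' Fraction of two genomes' proteins grouped as orthologues
#'
#' @param clusters an `ortho_clusters` object whose members cover the two
#'   genomes' TCS proteins.
#' @param genomeA,genomeB genome ids.
#' @return fraction in \[0, 1\] of the two genomes' proteins residing in
#'   clusters containing both genomes.
#' @export
orthology_fraction <- function(clusters, genomeA, genomeB) {
  m <- clusters$members
  m <- m[m$genome_id %in% c(genomeA, genomeB), , drop = FALSE]
  if (!nrow(m)) return(0)
  both <- tapply(m$genome_id, m$cluster_id,
                 function(g) all(c(genomeA, genomeB) %in% g))
  sum(m$cluster_id %in% names(both)[both]) / nrow(m)
}
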