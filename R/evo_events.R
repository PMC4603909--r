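event_record <- function(event_type, genome_id = NA_character_,
                         cluster_id = NA_character_,
                         protein_id = NA_character_, detail = "") {
  data.frame(event_type = event_type, genome_id = genome_id,
             cluster_id = cluster_id, protein_id = protein_id,
             detail = detail, stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(event_type = character(), genome_id = character(),
             cluster_id = character(), protein_id = character(),
             detail = character(), stringsAsFactors = FALSE)
}

#' Singleton detection between two genomes
#'
#' A singleton is a protein whose cluster contains no member from the
#' other genome, i.e. a gene unique to one organism in the comparison.
#'
#' @param clusters an `ortho_clusters` object restricted to (or filtered
#'   for) the two genomes.
#' @param genomeA,genomeB genome ids.
#' @return data.frame of `SINGLETON` events, one per protein.
#' @export
detect_singletons <- function(clusters, genomeA, genomeB) {
  m <- clusters$members
  m <- m[m$genome_id %in% c(genomeA, genomeB), , drop = FALSE]
  if (!nrow(m)) return(empty_events())
  rows <- list()
  for (cid in unique(m$cluster_id)) {
    mem <- m[m$cluster_id == cid, , drop = FALSE]
    gs <- unique(mem$genome_id)
    if (length(gs) == 2) next
    for (i in seq_len(nrow(mem)))
      rows[[length(rows) + 1L]] <-
        event_record("SINGLETON", mem$genome_id[i], cid, mem$protein_id[i])
  }
  if (length(rows)) do.call(rbind, rows) else empty_events()
}

#' Lineage-specific duplication detection
#'
#' A cluster shows a duplication when exactly one genome contributes two
#' or more members while every other genome contributes at most one. The
#' detail field marks the copies as `local` when the smallest rank gap
#' between two of them is at most `local_gap`, else `distal` (requires
#' `ann` for ranks).
#'
#' @param clusters an `ortho_clusters` object.
#' @param ann optional annotation table ([annotate_proteins()]) for rank
#'   lookup.
#' @param local_gap gene-order distance regarded as local (default 5).
#' @return data.frame of `DUPLICATION` events, one per affected cluster.
#' @export
detect_duplications <- function(clusters, ann = NULL, local_gap = 5) {
  m <- clusters$members
  rows <- list()
  for (cid in unique(m$cluster_id)) {
    mem <- m[m$cluster_id == cid, , drop = FALSE]
    tb <- table(mem$genome_id)
    if (sum(tb >= 2) != 1) next   # exactly one genome with >= 2 copies
    g <- names(tb)[tb >= 2]
    ids <- sort(mem$protein_id[mem$genome_id == g])
    detail <- ""
    if (!is.null(ann)) {
      rk <- sort(ann$rank[match(ids, ann$protein_id)])
      if (!anyNA(rk) && length(rk) >= 2)
        detail <- if (min(diff(rk)) <= local_gap) "local" else "distal"
    }
    rows[[length(rows) + 1L]] <- event_record(
      "DUPLICATION", g, cid, paste(ids, collapse = ";"), detail)
  }
  if (length(rows)) do.call(rbind, rows) else empty_events()
}

#' Character changes within clusters
#'
#' For each cluster with two or more members, emits one record per change
#' type present: `ORG_CHANGE` (members differ in focus category or
#' notation), `ARCH_CHANGE` (distinct architecture strings),
#' `FAMILY_CHANGE` (distinct RR families among members that have one),
#' `SIZE_CHANGE` (length span beyond `size_threshold`), `PSEUDOGENE`
#' (pseudogene alongside an intact member).
#'
#' @param clusters an `ortho_clusters` object.
#' @param ann annotation table ([annotate_proteins()], rbind-ed across
#'   genomes).
#' @param size_threshold residue difference regarded as a size change.
#' @return data.frame of events; `protein_id` carries the sorted member
#'   ids joined with `;`.
#' @export
detect_changes <- function(clusters, ann, size_threshold = 100) {
  m <- clusters$members
  a <- ann[match(m$protein_id, ann$protein_id), ]
  rows <- list()
  for (cid in unique(m$cluster_id)) {
    sel <- m$cluster_id == cid
    if (sum(sel) < 2) next
    ai <- a[sel, , drop = FALSE]
    ids <- paste(sort(ai$protein_id), collapse = ";")
    add <- function(type, detail = "")
      rows[[length(rows) + 1L]] <<- event_record(type, NA, cid, ids, detail)
    org <- unique(paste(ai$category, ai$notation))
    if (length(org) > 1)
      add("ORG_CHANGE", paste(sort(unique(ai$notation)), collapse = " vs "))
    if (length(unique(ai$architecture)) > 1)
      add("ARCH_CHANGE",
          paste(sort(unique(ai$architecture)), collapse = " vs "))
    fams <- unique(ai$rr_family[!is.na(ai$rr_family)])
    if (length(fams) > 1) add("FAMILY_CHANGE",
                              paste(sort(fams), collapse = " vs "))
    span <- diff(range(ai$length))
    if (span > size_threshold) add("SIZE_CHANGE", paste0("delta=", span))
    if (any(ai$pseudogene) && !all(ai$pseudogene)) add("PSEUDOGENE")
  }
  if (length(rows)) do.call(rbind, rows) else empty_events()
}

#' Horizontal-acquisition candidates among singletons
#'
#' Each singleton is compared against a labelled reference-homolog set;
#' when its best non-self hit carries a clade label outside the focal
#' clade the singleton is flagged as horizontally acquired. Ties between
#' inside- and outside-clade best hits are not flagged (conservative).
#'
#' @param singletons `SINGLETON` events from [detect_singletons()].
#' @param proteins data.frame `protein_id`, `sequence` covering the
#'   singleton proteins.
#' @param reference data.frame `ref_id`, `label`, `sequence`.
#' @param focal_clade label(s) regarded as vertical descent.
#' @param scoring see [align_scoring()].
#' @return data.frame of `HGT_CANDIDATE` events (subset of singletons).
#' @export
flag_hgt <- function(singletons, proteins, reference,
                     focal_clade = "focal", scoring = align_scoring()) {
  if (!nrow(singletons) || !nrow(reference)) return(empty_events())
  seqs <- setNames(proteins$sequence, proteins$protein_id)
  m <- similarity_matrix(seqs[singletons$protein_id],
                         setNames(reference$sequence, reference$ref_id),
                         scoring)
  rows <- list()
  for (i in seq_len(nrow(singletons))) {
    sims <- m[i, reference$ref_id != singletons$protein_id[i]]
    labs <- reference$label[reference$ref_id != singletons$protein_id[i]]
    if (!length(sims)) next
    best <- which(sims == max(sims))
    outside <- !labs[best] %in% focal_clade
    if (all(outside)) {
      rows[[length(rows) + 1L]] <- event_record(
        "HGT_CANDIDATE", singletons$genome_id[i], singletons$cluster_id[i],
        singletons$protein_id[i],
        paste0("best_hit=", names(sims)[best[1]], " label=",
               labs[best[1]], " sim=", signif(max(sims), 3)))
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty_events()
}

#' Synteny dot-plot points for 1:1 orthologue pairs
#'
#' One point per cluster containing exactly one member from each genome,
#' using gene-order ranks as coordinates. Points are grouped into
#' collinear segments (runs with consistent +1/-1 direction) by the same
#' rule as [detect_relocations()].
#'
#' @param clusters an `ortho_clusters` object.
#' @param bundleA,bundleB the two `genome_bundle`s.
#' @param min_segment,max_gap see [detect_relocations()].
#' @return data.frame `cluster_id`, `a_locus`, `b_locus`, `a_rank`,
#'   `b_rank`, `segment_id` (NA for outliers), `direction` (+1/-1 per
#'   segment), `outlier`.
#' @export
dotplot_points <- function(clusters, bundleA, bundleB,
                           min_segment = 3, max_gap = 25) {
  m <- clusters$members
  ga <- bundleA$genome_id
  gb <- bundleB$genome_id
  la <- setNames(bundleA$genes$locus_tag, bundleA$genes$protein_id)
  lb <- setNames(bundleB$genes$locus_tag, bundleB$genes$protein_id)
  ra <- setNames(bundleA$genes$rank, bundleA$genes$locus_tag)
  rb <- setNames(bundleB$genes$rank, bundleB$genes$locus_tag)
  rows <- list()
  for (cid in unique(m$cluster_id)) {
    mem <- m[m$cluster_id == cid, , drop = FALSE]
    if (nrow(mem) != 2) next
    if (!setequal(mem$genome_id, c(ga, gb))) next
    pa <- mem$protein_id[mem$genome_id == ga]
    pb <- mem$protein_id[mem$genome_id == gb]
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = cid, a_locus = unname(la[pa]), b_locus = unname(lb[pb]),
      a_rank = unname(ra[la[pa]]), b_rank = unname(rb[lb[pb]]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(cluster_id = character(), a_locus = character(),
                      b_locus = character(), a_rank = integer(),
                      b_rank = integer(), segment_id = integer(),
                      direction = integer(), outlier = logical(),
                      stringsAsFactors = FALSE))
  }
  pts <- do.call(rbind, rows)
  assign_segments(pts, min_segment = min_segment, max_gap = max_gap)
}

# internal: greedy extraction of maximal collinear runs over points
# sorted by a_rank. A run continues while both rank steps are within
# max_gap and the sign of the b step matches the run direction.
assign_segments <- function(pts, min_segment = 3, max_gap = 25) {
  pts <- pts[order(pts$a_rank), , drop = FALSE]
  rownames(pts) <- NULL
  n <- nrow(pts)
  run <- integer(n)
  run_id <- 1L
  run[1] <- run_id
  dir <- 0L
  for (i in seq_len(n)[-1]) {
    da <- pts$a_rank[i] - pts$a_rank[i - 1]
    db <- pts$b_rank[i] - pts$b_rank[i - 1]
    step_ok <- da <= max_gap && abs(db) <= max_gap && db != 0
    if (step_ok && (dir == 0L || sign(db) == dir)) {
      if (dir == 0L) dir <- sign(db)
      run[i] <- run_id
    } else {
      run_id <- run_id + 1L
      run[i] <- run_id
      dir <- 0L
    }
  }
  sizes <- table(run)
  keep <- as.integer(names(sizes)[sizes >= min_segment])
  seg_map <- setNames(seq_along(keep), keep)
  pts$segment_id <- ifelse(run %in% keep, seg_map[as.character(run)],
                           NA_integer_)
  dirs <- vapply(keep, function(r) {
    b <- pts$b_rank[run == r]
    as.integer(sign(b[length(b)] - b[1]))
  }, integer(1))
  pts$direction <- ifelse(is.na(pts$segment_id), NA_integer_,
                          dirs[pts$segment_id])
  pts$outlier <- is.na(pts$segment_id)
  pts
}

#' Relocation detection from dot-plot points
#'
#' Points that belong to no collinear run of at least `min_segment`
#' orthologue pairs are reported as relocations: genes whose relative
#' genomic position is inconsistent with the conserved (possibly
#' inverted) segments around them. A pure diagonal, or a diagonal broken
#' by one contiguous inversion, yields no relocations.
#'
#' @param points output of [dotplot_points()] (or a data.frame with
#'   `a_rank`, `b_rank`, plus ids).
#' @param min_segment minimum run length (default 3).
#' @param max_gap rank-gap tolerance within a run (default 25).
#' @return data.frame of `RELOCATION` events, one per outlying point.
#' @export
detect_relocations <- function(points, min_segment = 3, max_gap = 25) {
  if (!nrow(points)) return(empty_events())
  if (is.null(points$outlier))
    points <- assign_segments(points, min_segment, max_gap)
  out <- points[points$outlier, , drop = FALSE]
  if (!nrow(out)) return(empty_events())
  do.call(rbind, lapply(seq_len(nrow(out)), function(i)
    event_record("RELOCATION", NA, out$cluster_id[i],
                 paste0(out$a_locus[i], ";", out$b_locus[i]),
                 sprintf("a_rank=%d b_rank=%d", out$a_rank[i],
                         out$b_rank[i]))))
}

#' Event frequency table
#'
#' Percentage of clusters showing each event type. Change-type events
#' (duplications, organisation/architecture/family/size changes,
#' pseudogene mixes, relocations) use the multi-member clusters as
#' denominator; singleton-type events (`SINGLETON`, `HGT_CANDIDATE`) use
#' all clusters, since a singleton is by construction its own cluster.
#'
#' @param events rbind-ed event records.
#' @param clusters an `ortho_clusters` object.
#' @return data.frame `event_type`, `numerator`, `denominator`,
#'   `percentage`.
#' @export
event_frequency_table <- function(events, clusters) {
  m <- clusters$members
  n_all <- length(unique(m$cluster_id))
  n_multi <- sum(table(m$cluster_id) >= 2)
  types <- c("SINGLETON", "HGT_CANDIDATE", "DUPLICATION", "ORG_CHANGE",
             "ARCH_CHANGE", "FAMILY_CHANGE", "SIZE_CHANGE", "PSEUDOGENE",
             "RELOCATION")
  rows <- lapply(types, function(tp) {
    den <- if (tp %in% c("SINGLETON", "HGT_CANDIDATE")) n_all else n_multi
    ev <- events[events$event_type == tp, , drop = FALSE]
    num <- length(unique(ev$cluster_id[!is.na(ev$cluster_id)]))
    num <- min(num, den)
    data.frame(event_type = tp, numerator = num, denominator = den,
               percentage = if (den > 0) round_half_up(100 * num / den, 1)
               else 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
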