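#' Pipeline configuration
#'
#' @param bundle_dirs character vector of bundle directories (or NULL if
#'   `bundles` supplied directly).
#' @param bundles optional named list of `genome_bundle` objects.
#' @param out_dir output directory for report tables.
#' @param high,low clustering cut-offs; `size_threshold`, `min_segment`,
#'   `max_gap`, `k_bands`, `bootstrap_n` as in the stage functions.
#' @param seed RNG seed for the bootstrap.
#' @param reference optional labelled homolog table for HGT flagging.
#' @param focal_clade clade label treated as vertical descent.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(bundle_dirs = NULL, bundles = NULL,
                            out_dir = tempfile("tcs_report_"),
                            high = 0.90, low = 0.30, size_threshold = 100,
                            min_segment = 3, max_gap = 25, k_bands = 4,
                            bootstrap_n = 100, seed = 1,
                            reference = NULL, focal_clade = "focal") {
  structure(list(bundle_dirs = bundle_dirs, bundles = bundles,
                 out_dir = out_dir, high = high, low = low,
                 size_threshold = size_threshold,
                 min_segment = min_segment, max_gap = max_gap,
                 k_bands = k_bands, bootstrap_n = bootstrap_n, seed = seed,
                 reference = reference, focal_clade = focal_clade),
            class = "pipeline_config")
}

provenance_header <- function(cfg) {
  core <- cfg[setdiff(names(cfg),
                      c("bundles", "reference", "out_dir", "bundle_dirs"))]
  hash <- sum(utf8ToInt(paste(deparse(core), collapse = ""))) %% 1000003L
  sprintf("# tcsevo %s | config-hash %d | seed %d",
          as.character(utils::packageVersion("tcsevo")), hash, cfg$seed)
}

write_report_tsv <- function(df, path, header) {
  con <- file(path, "w")
  writeLines(header, con)
  close(con)
  suppressWarnings(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                append = TRUE))
  invisible(path)
}

#' Run the full comparative pipeline
#'
#' Stage sequence: classify -> foci -> per-genome and cohort statistics ->
#' two-tier orthologue clustering -> 16S distances/tree -> pairwise event
#' inference (first genome pair). Tables are written under
#' `cfg$out_dir` with a provenance header line; the full result set is
#' returned invisibly. Comparative stages need at least two genomes;
#' with one genome only the statistics stage runs.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress progress lines.
#' @return (invisibly) list with `bundles`, `tcs`, `foci`, `stats`,
#'   `clusters`, `events`, `freq`, `dotplot`, `distances`, `tree`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  bundles <- cfg$bundles
  if (is.null(bundles)) {
    if (is.null(cfg$bundle_dirs))
      abort("no-input", "supply bundle_dirs or bundles")
    bundles <- lapply(cfg$bundle_dirs, read_bundle)
  }
  names(bundles) <- vapply(bundles, `[[`, character(1), "genome_id")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(cfg)

  tcs <- lapply(bundles, classify_bundle)
  foci <- lapply(names(bundles),
                 function(g) build_foci(bundles[[g]], tcs[[g]]))
  names(foci) <- names(bundles)
  stats <- do.call(rbind, lapply(names(bundles), function(g)
    genome_summary(bundles[[g]], tcs[[g]], foci[[g]])))
  say("stats: %d genomes, %d TCS genes total", nrow(stats),
      sum(stats$n_tcs))
  stats_out <- stats
  if (nrow(stats) > 1) {
    mean_row <- cohort_summary(stats)
    mean_row$no_tcs <- NA
    stats_out <- rbind(stats, mean_row)
  }
  write_report_tsv(stats_out, file.path(cfg$out_dir, "table2.tsv"), hdr)
  foci_flat <- do.call(rbind, lapply(foci, function(f) {
    f$members <- vapply(f$members, paste, character(1), collapse = ";")
    f
  }))
  write_report_tsv(foci_flat, file.path(cfg$out_dir, "foci.tsv"), hdr)

  out <- list(bundles = bundles, tcs = tcs, foci = foci, stats = stats_out)
  if (length(bundles) < 2) {
    say("single genome: comparative stages skipped")
    return(invisible(out))
  }

  prot <- do.call(rbind, lapply(names(bundles), function(g)
    tcs_proteins(bundles[[g]], tcs[[g]])))
  clusters <- two_tier_cluster(prot, high = cfg$high, low = cfg$low)
  ann <- do.call(rbind, lapply(names(bundles), function(g)
    annotate_proteins(bundles[[g]], tcs[[g]], foci[[g]])))
  clusters <- flag_clusters(clusters, ann,
                            size_threshold = cfg$size_threshold)
  say("cluster: %d proteins -> %d clusters", nrow(clusters$members),
      length(unique(clusters$members$cluster_id)))
  cl_out <- clusters$members
  if (nrow(clusters$flags)) {
    cl_out <- merge(cl_out,
                    stats::aggregate(flag ~ cluster_id, clusters$flags,
                                     paste, collapse = ","),
                    by = "cluster_id", all.x = TRUE)
  } else cl_out$flag <- NA_character_
  write_report_tsv(cl_out, file.path(cfg$out_dir, "clusters.tsv"), hdr)

  ssu <- Filter(Negate(is.null), lapply(bundles, `[[`, "ssu"))
  distances <- NULL
  tree <- NULL
  if (length(ssu) >= 2 && length(unique(nchar(unlist(ssu)))) == 1) {
    aln <- unlist(ssu)
    distances <- p_distance_matrix(aln)
    if (length(ssu) >= 3) {
      tree <- nj_tree(distances)
      ape::write.tree(tree, file.path(cfg$out_dir, "tree.nwk"))
    }
    dd <- as.data.frame(as.table(distances), stringsAsFactors = FALSE)
    names(dd) <- c("a", "b", "distance")
    dd <- dd[dd$a < dd$b, , drop = FALSE]
    write_report_tsv(dd, file.path(cfg$out_dir, "distances.tsv"), hdr)
  }

  gA <- names(bundles)[1]
  gB <- names(bundles)[2]
  pair_members <- clusters$members[
    clusters$members$genome_id %in% c(gA, gB), , drop = FALSE]
  pair <- clusters
  pair$members <- pair_members
  sing <- detect_singletons(pair, gA, gB)
  dups <- detect_duplications(pair, ann)
  chg <- detect_changes(pair, ann, size_threshold = cfg$size_threshold)
  hgts <- if (!is.null(cfg$reference))
    flag_hgt(sing, do.call(rbind, lapply(bundles[c(gA, gB)],
                                         `[[`, "proteins")),
             cfg$reference, cfg$focal_clade)
  else empty_events()
  pts <- dotplot_points(pair, bundles[[gA]], bundles[[gB]],
                        min_segment = cfg$min_segment,
                        max_gap = cfg$max_gap)
  rel <- detect_relocations(pts, cfg$min_segment, cfg$max_gap)
  events <- rbind(sing, dups, chg, hgts, rel)
  freq <- event_frequency_table(events, pair)
  say("events (%s vs %s): %d records", gA, gB, nrow(events))
  write_report_tsv(events, file.path(cfg$out_dir, "events.tsv"), hdr)
  write_report_tsv(freq, file.path(cfg$out_dir, "freq.tsv"), hdr)
  write_report_tsv(pts, file.path(cfg$out_dir, "dotplot.tsv"), hdr)

  out$clusters <- clusters
  out$ann <- ann
  out$events <- events
  out$freq <- freq
  out$dotplot <- pts
  out$distances <- distances
  out$tree <- tree
  invisible(out)
}
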