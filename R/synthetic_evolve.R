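# Evolution of a genome state along a tree, with a truth log.
#
# The state is a list(genes = list(...), ssu = chr); each gene carries its
# ancestral origin, origin group (shared by duplication copies), provenance
# (ancestral / duplication / hgt), sequence, domain table, strand, focus
# tag, pseudogene flag and per-gene rate factor.

sample1 <- function(x) if (length(x) <= 1L) x else sample(x, 1L)

is_core_kind <- function(kind)
  kind %in% c("receiver", "transmitter", "phosphoacceptor")

tcs_idx <- function(genes) which(vapply(genes, `[[`, logical(1), "is_tcs"))

# ---- individual event applications (mutate environment E) ------------------

ev_gene_loss <- function(E) {
  idx <- tcs_idx(E$genes)
  if (!length(idx)) return(invisible())
  i <- sample1(idx)
  E$add("gene_loss", E$genes[[i]]$origin, n_genes = 1L,
        detail = E$genes[[i]]$focus %||% "")
  E$genes[[i]] <- NULL
}

ev_focus_loss <- function(E) {
  idx <- tcs_idx(E$genes)
  foci <- unique(stats::na.omit(
    vapply(E$genes[idx], `[[`, character(1), "focus")))
  if (!length(foci)) return(invisible())
  f <- sample1(foci)
  hit <- idx[vapply(E$genes[idx], function(g)
    identical(g$focus, f), logical(1))]
  E$add("focus_loss",
        paste(vapply(E$genes[hit], `[[`, character(1), "origin"),
              collapse = ";"),
        n_genes = length(hit), detail = f)
  E$genes[hit] <- NULL
}

ev_duplication <- function(E, cfg) {
  idx <- tcs_idx(E$genes)
  if (!length(idx)) return(invisible())
  i <- sample1(idx)
  src <- E$genes[[i]]
  E$dup_n <- E$dup_n + 1L
  copy <- src
  copy$origin <- sprintf("%s+d%d", src$origin, E$dup_n)
  copy$via <- "duplication"
  copy$pseudogene <- FALSE
  local <- runif(1) < cfg$local_dup_prob
  if (local) {
    pos <- i            # insert right after the source (tandem)
  } else {
    pos <- sample1(setdiff(0:length(E$genes), c(i - 1L, i)))
    copy$focus <- NA_character_
    copy$strand <- sample(c("+", "-"), 1)
  }
  E$genes <- append(E$genes, list(copy), after = pos)
  E$add("duplication", src$origin, n_genes = 1L,
        detail = if (local) "local" else "distal")
}

ev_hgt <- function(E, cfg) {
  if (E$foreign_used >= length(E$pool)) return(invisible())
  E$foreign_used <- E$foreign_used + 1L
  p <- E$pool[[E$foreign_used]]
  g <- new_gene(p$id, p$sequence, p$domains, sample(c("+", "-"), 1),
                is_tcs = TRUE, via = "hgt", origin_group = p$id)
  pos <- sample1(0:length(E$genes))
  E$genes <- append(E$genes, list(g), after = pos)
  E$add("hgt_insertion", p$id, n_genes = 1L, detail = "foreign-pool")
}

ev_domain_gain <- function(E) {
  idx <- tcs_idx(E$genes)
  if (!length(idx)) return(invisible())
  i <- sample1(idx)
  g <- E$genes[[i]]
  kind <- sample(c("receiver", "transmitter", "input", "output"), 1,
                 prob = c(0.35, 0.25, 0.2, 0.2))
  subtype <- switch(kind, input = sample(SENSOR_SUBTYPES, 1),
                    output = sample(RR_FAMILIES, 1), NA_character_)
  len <- DOMAIN_LEN[[kind]]
  block <- random_protein(len)
  linker <- random_protein(LINKER_LEN)
  at_n <- runif(1) < 0.5
  if (at_n) {
    g$sequence <- paste0(block, linker, g$sequence)
    if (nrow(g$domains)) {
      g$domains$start <- g$domains$start + len + LINKER_LEN
      g$domains$end <- g$domains$end + len + LINKER_LEN
    }
    hit <- data.frame(kind = kind, subtype = subtype, start = 1L,
                      end = len, stringsAsFactors = FALSE)
  } else {
    old_len <- nchar(g$sequence)
    g$sequence <- paste0(g$sequence, linker, block)
    hit <- data.frame(kind = kind, subtype = subtype,
                      start = old_len + LINKER_LEN + 1L,
                      end = old_len + LINKER_LEN + len,
                      stringsAsFactors = FALSE)
  }
  g$domains <- rbind(g$domains, hit)
  g$domains <- g$domains[order(g$domains$start), , drop = FALSE]
  E$genes[[i]] <- g
  E$add("domain_gain", g$origin, detail = paste0(kind, ":",
                                                 if (at_n) "N" else "C"))
}

# a domain may be removed only if the gene keeps at least one core
# (R/T/H) domain: total functional loss is modelled by gene_loss instead,
# which keeps the truth-log arithmetic exact
ev_domain_loss <- function(E) {
  idx <- tcs_idx(E$genes)
  cand <- Filter(function(i) {
    d <- E$genes[[i]]$domains
    n_core <- sum(is_core_kind(d$kind))
    any(!is_core_kind(d$kind)) || n_core >= 2
  }, idx)
  if (!length(cand)) return(invisible())
  i <- sample1(cand)
  g <- E$genes[[i]]
  d <- g$domains
  n_core <- sum(is_core_kind(d$kind))
  removable <- which(!is_core_kind(d$kind) | n_core >= 2)
  r <- sample1(removable)
  span <- d$end[r] - d$start[r] + 1L
  g$sequence <- paste0(substr(g$sequence, 1, d$start[r] - 1L),
                       substr(g$sequence, d$end[r] + 1L, nchar(g$sequence)))
  kind <- d$kind[r]
  after <- d$start > d$end[r]
  d$start[after] <- d$start[after] - span
  d$end[after] <- d$end[after] - span
  g$domains <- d[-r, , drop = FALSE]
  E$genes[[i]] <- g
  E$add("domain_loss", g$origin, detail = kind)
}

ev_size_indel <- function(E, cfg) {
  idx <- tcs_idx(E$genes)
  if (!length(idx)) return(invisible())
  i <- sample1(idx)
  g <- E$genes[[i]]
  len <- nchar(g$sequence)
  L <- 1L + rpois(1, max(cfg$size_indel_mean - 1, 0))
  inside <- function(p) {
    d <- g$domains
    nrow(d) > 0 && any(d$start <= p & p <= d$end - 1L)
  }
  pts <- Filter(function(p) !inside(p), 0:len)
  if (runif(1) < 0.5) {        # insertion
    p <- sample1(pts)
    g$sequence <- paste0(substr(g$sequence, 1, p), random_protein(L),
                         substr(g$sequence, p + 1L, len))
    after <- g$domains$start > p
    g$domains$start[after] <- g$domains$start[after] + L
    g$domains$end[after] <- g$domains$end[after] + L
    E$add("size_indel", g$origin, detail = sprintf("+%d", L))
  } else {                     # deletion from a domain-free run
    covered <- rep(FALSE, len)
    for (r in seq_len(nrow(g$domains)))
      covered[g$domains$start[r]:g$domains$end[r]] <- TRUE
    free <- which(!covered)
    if (!length(free)) return(invisible())
    runs <- split(free, cumsum(c(1L, diff(free) != 1L)))
    run <- runs[[sample1(seq_along(runs))]]
    dL <- min(L, length(run))
    s <- run[1]
    g$sequence <- paste0(substr(g$sequence, 1, s - 1L),
                         substr(g$sequence, s + dL, len))
    shift <- g$domains$start >= s
    g$domains$start[shift] <- g$domains$start[shift] - dL
    g$domains$end[shift] <- g$domains$end[shift] - dL
    E$add("size_indel", g$origin, detail = sprintf("-%d", dL))
  }
  E$genes[[i]] <- g
}

# frameshift: truncates after a uniformly chosen point downstream of the
# first core domain (so the gene stays recognisably TCS), drops lost
# domains and flags the gene as a pseudogene
ev_frameshift <- function(E) {
  idx <- tcs_idx(E$genes)
  cand <- Filter(function(i) {
    g <- E$genes[[i]]
    !g$pseudogene && any(is_core_kind(g$domains$kind)) &&
      nchar(g$sequence) > min(g$domains$end[is_core_kind(g$domains$kind)])
  }, idx)
  if (!length(cand)) return(invisible())
  i <- sample1(cand)
  g <- E$genes[[i]]
  lo <- min(g$domains$end[is_core_kind(g$domains$kind)])
  cut <- sample1(lo:nchar(g$sequence))
  g$sequence <- substr(g$sequence, 1, cut)
  g$domains <- g$domains[g$domains$end <= cut, , drop = FALSE]
  g$pseudogene <- TRUE
  E$genes[[i]] <- g
  E$add("frameshift", g$origin, detail = sprintf("cut=%d", cut))
}

ev_relocation <- function(E) {
  idx <- tcs_idx(E$genes)
  if (!length(idx)) return(invisible())
  i <- sample1(idx)
  g <- E$genes[[i]]
  n <- length(E$genes)
  min_move <- min(30L, max(1L, n %/% 3L))
  targets <- Filter(function(p) abs(p - (i - 1L)) >= min_move, 0:(n - 1L))
  if (!length(targets)) return(invisible())
  p <- sample1(targets)
  g$focus <- NA_character_
  E$genes[[i]] <- NULL
  E$genes <- append(E$genes, list(g), after = p)
  E$add("relocation", g$origin, detail = sprintf("to=%d", p))
}

ev_inversion <- function(E) {
  n <- length(E$genes)
  if (n < 6) return(invisible())
  center <- round(n * runif(1, 0.45, 0.55))
  half <- round(n * runif(1, 0.15, 0.30))
  lo <- max(1L, center - half)
  hi <- min(n, center + half)
  block <- rev(E$genes[lo:hi])
  block <- lapply(block, function(g) {
    g$strand <- if (g$strand == "+") "-" else "+"
    g
  })
  E$genes[lo:hi] <- block
  E$add("inversion", NA_character_, n_genes = hi - lo + 1L,
        detail = sprintf("block=%d-%d", lo, hi))
}

# ---- branch application ----------------------------------------------------

apply_branch <- function(state, t, cfg, label, add_truth, foreign) {
  E <- new.env(parent = emptyenv())
  E$genes <- state$genes
  E$pool <- foreign$pool
  E$foreign_used <- foreign$used
  E$dup_n <- foreign$dup_n
  E$add <- function(event_type, origin, n_genes = 1L, detail = "")
    add_truth(label, event_type, origin, n_genes, detail)
  r <- cfg$rates
  n_t <- length(tcs_idx(E$genes))
  n_f <- length(unique(stats::na.omit(vapply(
    E$genes[tcs_idx(E$genes)], `[[`, character(1), "focus"))))
  draw <- function(rate, n) rpois(1, rate * t * n)
  for (k in seq_len(draw(r$focus_loss, n_f))) ev_focus_loss(E)
  for (k in seq_len(draw(r$gene_loss, n_t))) ev_gene_loss(E)
  for (k in seq_len(draw(r$duplication, n_t))) ev_duplication(E, cfg)
  for (k in seq_len(draw(r$hgt_insertion, 1))) ev_hgt(E, cfg)
  for (k in seq_len(draw(r$domain_gain, n_t))) ev_domain_gain(E)
  for (k in seq_len(draw(r$domain_loss, n_t))) ev_domain_loss(E)
  for (k in seq_len(draw(r$size_indel, n_t))) ev_size_indel(E, cfg)
  for (k in seq_len(draw(r$frameshift, n_t))) ev_frameshift(E)
  for (k in seq_len(draw(r$relocation, n_t))) ev_relocation(E)
  if (runif(1) < cfg$inversion_prob) ev_inversion(E)
  # sequence divergence: proteins at the scaled rate, 16S at branch rate
  E$genes <- lapply(E$genes, function(g) {
    p <- t * cfg$protein_rate_scaling * g$rate_factor
    g$sequence <- mutate_seq(g$sequence, p)
    g
  })
  foreign$used <- E$foreign_used
  foreign$dup_n <- E$dup_n
  list(genes = E$genes, ssu = mutate_seq(state$ssu, t, DNA_ALPHABET))
}

# ---- tree traversal --------------------------------------------------------

make_foreign_pool <- function(cfg) {
  set.seed(cfg$seed + 104729L)
  lapply(seq_len(cfg$n_foreign_pool), function(i) {
    arch <- sample(c("R", "T", "RT"), 1, prob = c(0.4, 0.35, 0.25))
    g <- gene_from_arch(arch)
    list(id = sprintf("hgt%03d", i), sequence = g$sequence,
         domains = g$domains)
  })
}

evolve_state <- function(anc_state, cfg, pool) {
  tree <- ape::read.tree(text = cfg$tree)
  if (is.null(tree$edge.length))
    abort("tree-without-branch-lengths", "the tree needs branch lengths")
  # per-gene rate factors (gamma, mean 1) for protein divergence
  anc_state$genes <- lapply(anc_state$genes, function(g) {
    g$rate_factor <- if (is.finite(cfg$gene_rate_shape))
      rgamma(1, shape = cfg$gene_rate_shape, rate = cfg$gene_rate_shape)
    else 1
    g
  })
  truth_rows <- list()
  add_truth <- function(branch, event_type, origin, n_genes, detail) {
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      branch = branch, event_type = event_type,
      origin = origin %||% NA_character_, n_genes = n_genes,
      detail = detail, stringsAsFactors = FALSE)
  }
  foreign <- new.env(parent = emptyenv())
  foreign$pool <- pool
  foreign$used <- 0L
  foreign$dup_n <- 0L
  tips <- list()
  paths <- list()
  ntip <- length(tree$tip.label)
  walk <- function(node, state, path) {
    kids <- which(tree$edge[, 1] == node)
    if (!length(kids)) {
      lab <- tree$tip.label[node]
      tips[[lab]] <<- state
      paths[[lab]] <<- path
      return(invisible())
    }
    for (k in kids) {
      child <- tree$edge[k, 2]
      lab <- if (child <= ntip) tree$tip.label[child] else
        paste0("n", child)
      st2 <- apply_branch(state, tree$edge.length[k], cfg, lab,
                          add_truth, foreign)
      walk(child, st2, c(path, lab))
    }
  }
  walk(ntip + 1L, anc_state, character(0))
  events <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(branch = character(), event_type = character(),
               origin = character(), n_genes = integer(),
               detail = character(), stringsAsFactors = FALSE)
  list(tips = tips, paths = paths, events = events)
}

# rebuild a simulator state from a bundle (classification + foci supply
# the TCS and focus tags)
state_from_bundle <- function(b) {
  tcs <- classify_bundle(b)
  foci <- build_foci(b, tcs)
  focus_of <- list()
  for (i in seq_len(nrow(foci)))
    for (tag in foci$members[[i]]) focus_of[[tag]] <- foci$focus_id[i]
  cls <- setNames(tcs$tcs_class, tcs$protein_id)
  g <- b$genes[order(b$genes$rank), , drop = FALSE]
  genes <- lapply(seq_len(nrow(g)), function(i) {
    pid <- g$protein_id[i]
    d <- protein_domains(b, pid)
    d$protein_id <- NULL
    new_gene(g$locus_tag[i],
             b$proteins$sequence[match(pid, b$proteins$protein_id)],
             d, g$strand[i],
             is_tcs = !is.na(pid) && cls[[pid]] != "NONE",
             focus = focus_of[[g$locus_tag[i]]] %||% NA_character_,
             pseudogene = g$pseudogene[i])
  })
  list(genes = genes, ssu = b$ssu)
}

#' Evolve an annotated genome along a tree
#'
#' Samples evolutionary events (whole-gene and whole-focus losses,
#' duplications, horizontal insertions, domain gains/losses, in-frame
#' indels, frameshift pseudogenisations, relocations, inversions) as
#' Poisson processes with rate x branch-length expectations, mutates
#' sequences per site, and records every applied event in the truth log.
#'
#' @param ancestor a `genome_bundle` (e.g. from [simulate_ancestor()]).
#' @param cfg a [sim_config()]; the tree tips name the output genomes.
#' @return list: `tips` (named list of `genome_bundle`s), `truth` (list
#'   with `events`, per-tip `orthology` maps and root-to-tip `paths`).
#' @export
evolve_along_tree <- function(ancestor, cfg) {
  pool <- make_foreign_pool(cfg)
  state <- state_from_bundle(ancestor)
  set.seed(cfg$seed + 1L)
  res <- evolve_state(state, cfg, pool)
  finish_simulation(res, cfg)
}

finish_simulation <- function(res, cfg) {
  tips <- lapply(names(res$tips), function(lab)
    state_to_bundle(res$tips[[lab]], lab))
  names(tips) <- names(res$tips)
  orthology <- lapply(names(res$tips), function(lab)
    state_orthology(res$tips[[lab]], lab))
  names(orthology) <- names(res$tips)
  list(tips = tips,
       truth = list(events = res$events, orthology = orthology,
                    paths = res$paths))
}

#' Run a full simulation: ancestor, evolution, truth log, reference set
#'
#' @param cfg a [sim_config()].
#' @return list of class `tcs_simulation`: `config`, `ancestor` (bundle),
#'   `tips` (named list of bundles), `truth` (events + orthology maps +
#'   root-to-tip branch paths), `reference` (labelled homolog set:
#'   `ref_id`, `label`, `sequence` -- mutated copies of the ancestral TCS
#'   proteins labelled with the focal clade, plus the foreign pool
#'   labelled `other-order`).
#' @export
simulate_genomes <- function(cfg) {
  pool <- make_foreign_pool(cfg)
  set.seed(cfg$seed)
  anc_state <- simulate_ancestor_state(cfg)
  res <- evolve_state(anc_state, cfg, pool)
  out <- finish_simulation(res, cfg)
  anc_bundle <- state_to_bundle(anc_state, "ancestor")
  focal <- lapply(anc_state$genes[tcs_idx(anc_state$genes)], function(g)
    data.frame(ref_id = paste0("ref_", g$origin), label = cfg$focal_clade,
               sequence = mutate_seq(g$sequence, 0.08),
               stringsAsFactors = FALSE))
  foreign <- lapply(pool, function(p)
    data.frame(ref_id = p$id, label = "other-order", sequence = p$sequence,
               stringsAsFactors = FALSE))
  reference <- do.call(rbind, c(focal, foreign))
  structure(list(config = cfg, ancestor = anc_bundle, tips = out$tips,
                 truth = out$truth, reference = reference),
            class = "tcs_simulation")
}

#' @export
print.tcs_simulation <- function(x, ...) {
  cat(sprintf("tcs_simulation: %d tips (%s), %d truth events, seed %d\n",
              length(x$tips), paste(names(x$tips), collapse = ", "),
              nrow(x$truth$events), x$config$seed))
  invisible(x)
}

#' Four distance regimes emulating the observed 16S distance bands
#'
#' Returns four configurations whose expected pairwise 16S p-distances
#' fall in disjoint increasing ranges corresponding to the within-genus,
#' within-family, within-sub-order and within-order comparisons. Gamma
#' rate heterogeneity across genes is enabled so orthologue
#' detectability decays smoothly with distance.
#'
#' @param template a [sim_config()] supplying everything except the tree.
#' @param distances strictly increasing expected 16S p-distances, one per
#'   regime.
#' @return named list of four [sim_config()]s.
#' @export
make_distance_regimes <- function(template,
                                  distances = c(genus = 0.016,
                                                family = 0.05,
                                                `sub-order` = 0.10,
                                                order = 0.19)) {
  if (any(diff(distances) <= 0) || any(distances <= 0))
    abort("degenerate-regimes",
          "expected distances must be positive and strictly increasing")
  out <- lapply(seq_along(distances), function(i) {
    cfg <- template
    cfg$tree <- sprintf("(A:%g,B:%g);", distances[i] / 2, distances[i] / 2)
    cfg$seed <- template$seed + 13L * i
    if (!is.finite(cfg$gene_rate_shape)) cfg$gene_rate_shape <- 1.5
    cfg
  })
  names(out) <- names(distances) %||% paste0("band", seq_along(distances))
  out
}

# reorder a bundle's genes to a new permutation (of rank order),
# recomputing ranks and sequential coordinates
reorder_bundle_genes <- function(b, perm, flip = logical(length(perm))) {
  g <- b$genes[order(b$genes$rank), , drop = FALSE][perm, , drop = FALSE]
  fl <- flip
  g$strand <- ifelse(fl, ifelse(g$strand == "+", "-", "+"), g$strand)
  nt <- g$end - g$start + 1L
  g$start <- cumsum(c(1L, head(nt, -1) + 120L))
  g$end <- g$start + nt - 1L
  g$rank <- seq_len(nrow(g)) - 1L
  genome_bundle(b$genome_id, g, b$proteins, b$domains, ssu = b$ssu,
                complete = b$complete)
}

#' Plant a chromosomal inversion into a bundle
#'
#' Reverses the gene order of the block between positions `lo` and `hi`
#' (1-based indices into the rank order; default: the middle third,
#' emulating a replichore-symmetric inversion) and flips the strands of
#' the inverted genes. Ranks and coordinates are recomputed.
#'
#' @param b a `genome_bundle`.
#' @param lo,hi block bounds (1-based gene positions).
#' @return the modified `genome_bundle`.
#' @export
plant_inversion <- function(b, lo = NULL, hi = NULL) {
  n <- nrow(b$genes)
  lo <- lo %||% max(1L, round(n / 3))
  hi <- hi %||% min(n, round(2 * n / 3))
  stopifnot(lo >= 1, hi <= n, lo < hi)
  perm <- seq_len(n)
  perm[lo:hi] <- rev(perm[lo:hi])
  flip <- logical(n)
  flip[lo:hi] <- TRUE
  reorder_bundle_genes(b, perm, flip)
}

#' Plant a single-gene relocation into a bundle
#'
#' Moves the gene at position `from` (1-based rank order) to position
#' `to`, recomputing ranks and coordinates; emulates the relocation of an
#' individual TCS focus around the chromosome.
#'
#' @param b a `genome_bundle`.
#' @param from,to 1-based gene positions.
#' @return the modified `genome_bundle`.
#' @export
plant_relocation <- function(b, from, to) {
  n <- nrow(b$genes)
  stopifnot(from >= 1, from <= n, to >= 1, to <= n, from != to)
  perm <- setdiff(seq_len(n), from)
  perm <- append(perm, from, after = to - 1L)
  reorder_bundle_genes(b, perm)
}

#' Events expected from the truth log for a two-genome comparison
#'
#' The acceptance oracle: derives, from the simulator's true orthology
#' map and the realised tip annotations, the canonical event keys that a
#' perfect clustering-based detector should report -- `SINGLETON:` /
#' `HGT:` per protein, `DUP:` per genome and copy set, `ORG:` per
#' orthologue group whose members differ in focus category or notation.
#'
#' @param sim a `tcs_simulation`.
#' @param tipA,tipB tip names.
#' @return data.frame `type`, `key`.
#' @export
truth_expected_events <- function(sim, tipA, tipB) {
  per_tip <- lapply(c(tipA, tipB), function(tp) {
    b <- sim$tips[[tp]]
    tcs <- classify_bundle(b)
    foci <- build_foci(b, tcs)
    ann <- annotate_proteins(b, tcs, foci)
    o <- sim$truth$orthology[[tp]]
    o <- o[o$protein_id %in% ann$protein_id, , drop = FALSE]
    merge(o, ann[c("protein_id", "category", "notation")],
          by = "protein_id")
  })
  names(per_tip) <- c(tipA, tipB)
  A <- per_tip[[tipA]]
  B <- per_tip[[tipB]]
  rows <- list()
  add <- function(type, key)
    rows[[length(rows) + 1L]] <<- data.frame(type = type, key = key,
                                             stringsAsFactors = FALSE)
  for (grp in union(A$origin_group, B$origin_group)) {
    a <- A[A$origin_group == grp, , drop = FALSE]
    b <- B[B$origin_group == grp, , drop = FALSE]
    if (nrow(a) == 0 || nrow(b) == 0) {
      solo <- if (nrow(a)) a else b
      for (i in seq_len(nrow(solo))) {
        add("SINGLETON", paste0("SINGLETON:", solo$protein_id[i]))
        if (solo$via[i] == "hgt")
          add("HGT", paste0("HGT:", solo$protein_id[i]))
      }
    }
    counts <- c(nrow(a), nrow(b))
    if (sum(counts >= 2) == 1) {
      multi <- if (nrow(a) >= 2) a else b
      g <- if (nrow(a) >= 2) tipA else tipB
      add("DUP", paste0("DUP:", g, ":",
                        paste(sort(multi$protein_id), collapse = ";")))
    }
    all_m <- rbind(a, b)
    if (nrow(all_m) >= 2 &&
        length(unique(paste(all_m$category, all_m$notation))) > 1)
      add("ORG", paste0("ORG:",
                        paste(sort(all_m$protein_id), collapse = ";")))
  }
  if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(type = character(), key = character(),
               stringsAsFactors = FALSE)
}

#' Canonical keys for detected events, comparable to the truth oracle
#'
#' @param singletons,duplications,changes,hgts event tables from
#'   [detect_singletons()], [detect_duplications()], [detect_changes()]
#'   and [flag_hgt()] (any may be empty).
#' @return data.frame `type`, `key` in the same key syntax as
#'   [truth_expected_events()].
#' @export
detected_event_keys <- function(singletons, duplications, changes, hgts) {
  rows <- list()
  add <- function(type, key) if (length(key))
    rows[[length(rows) + 1L]] <<- data.frame(type = type, key = key,
                                             stringsAsFactors = FALSE)
  if (nrow(singletons))
    add("SINGLETON", paste0("SINGLETON:", singletons$protein_id))
  if (nrow(hgts)) add("HGT", paste0("HGT:", hgts$protein_id))
  if (nrow(duplications))
    add("DUP", paste0("DUP:", duplications$genome_id, ":",
                      duplications$protein_id))
  org <- changes[changes$event_type == "ORG_CHANGE", , drop = FALSE]
  if (nrow(org)) add("ORG", paste0("ORG:", org$protein_id))
  if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(type = character(), key = character(),
               stringsAsFactors = FALSE)
}
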