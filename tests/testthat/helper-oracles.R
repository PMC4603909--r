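# Independent oracles and fixture builders used across the suite.

# --- pure-R Gotoh aligner: lexicographic (score, identities) -----------------
# Written independently of the C++ implementation; same specification:
# global alignment, gap of length L costs open + ext*L, and among all
# optimal-score alignments the identity count is maximised.
oracle_align_matches <- function(a, b, match = 2, mismatch = -1,
                                 open = 10, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  S <- array(NEG, c(n + 1, m + 1, 3))   # scores: 1=M, 2=gap-in-b, 3=gap-in-a
  Mt <- array(0L, c(n + 1, m + 1, 3))   # identity counts
  S[1, 1, 1] <- 0
  for (i in seq_len(n)) S[i + 1, 1, 2] <- -(open + ext * i)
  for (j in seq_len(m)) S[1, j + 1, 3] <- -(open + ext * j)
  pickmax <- function(scores, mats) {
    best <- which(scores == max(scores))
    k <- best[which.max(mats[best])]
    c(scores[k], mats[k])
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      eq <- av[i] == bv[j]
      p <- pickmax(S[i, j, ], Mt[i, j, ])
      if (p[1] > NEG / 2) {
        S[i + 1, j + 1, 1] <- p[1] + if (eq) match else mismatch
        Mt[i + 1, j + 1, 1] <- p[2] + as.integer(eq)
      }
      sx <- c(S[i, j + 1, 1] - open - ext, S[i, j + 1, 2] - ext,
              S[i, j + 1, 3] - open - ext)
      mx <- Mt[i, j + 1, ]
      px <- pickmax(sx, mx)
      S[i + 1, j + 1, 2] <- px[1]
      Mt[i + 1, j + 1, 2] <- px[2]
      sy <- c(S[i + 1, j, 1] - open - ext, S[i + 1, j, 2] - open - ext,
              S[i + 1, j, 3] - ext)
      my <- Mt[i + 1, j, c(1, 2, 3)]
      py <- pickmax(sy, my)
      S[i + 1, j + 1, 3] <- py[1]
      Mt[i + 1, j + 1, 3] <- py[2]
    }
  }
  fin <- pickmax(S[n + 1, m + 1, ], Mt[n + 1, m + 1, ])
  c(score = fin[1], matches = fin[2])
}

oracle_similarity <- function(a, b, ...) {
  unname(oracle_align_matches(a, b, ...)["matches"]) / min(nchar(a), nchar(b))
}

# --- random sequences --------------------------------------------------------
AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
rand_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
rand_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                              collapse = "")

# substitute a fraction p of positions (always to a different letter)
perturb <- function(s, p, alphabet = AA20) {
  ch <- strsplit(s, "")[[1]]
  k <- max(0L, round(length(ch) * p))
  if (k == 0) return(s)
  pos <- sample(seq_along(ch), k)
  for (i in pos) ch[i] <- sample(setdiff(alphabet, ch[i]), 1)
  paste(ch, collapse = "")
}

# --- toy bundle builder ------------------------------------------------------
# spec: list of gene descriptors list(arch = "RT" or NA for background,
# strand = "+"). Domain blocks are 100 aa with 10 aa spacers, so coords
# are valid; lone-"R" genes get an output domain with the given family.
toy_bundle <- function(spec, genome_id = "toy", ssu = NULL,
                       complete = TRUE) {
  genes <- list()
  prots <- list()
  doms <- list()
  for (i in seq_along(spec)) {
    g <- spec[[i]]
    tag <- sprintf("%s_%03d", genome_id, i)
    pid <- paste0(tag, "_p")
    arch <- g$arch
    if (is.null(arch) || is.na(arch)) {
      seqlen <- 200L
      dd <- NULL
    } else {
      letters_v <- strsplit(arch, "")[[1]]
      kinds <- c(R = "receiver", T = "transmitter",
                 H = "phosphoacceptor")[letters_v]
      if (identical(letters_v, "R") && !is.null(g$family))
        kinds <- c(kinds, output = "output")
      if (isTRUE(g$tm)) kinds <- c(TM = "TM", kinds)
      starts <- 10L + 110L * (seq_along(kinds) - 1L)
      dd <- data.frame(protein_id = pid, kind = unname(kinds),
                       subtype = ifelse(kinds == "output",
                                        g$family %||% NA_character_,
                                        NA_character_),
                       start = starts, end = starts + 99L,
                       stringsAsFactors = FALSE)
      seqlen <- max(dd$end) + 10L
    }
    seq <- if (!is.null(g$seq)) g$seq else rand_aa(seqlen)
    genes[[i]] <- data.frame(
      locus_tag = tag, contig = g$contig %||% "chr", rank = 0L,
      strand = g$strand %||% "+", start = 0L, end = 0L,
      pseudogene = isTRUE(g$pseudogene), protein_id = pid,
      stringsAsFactors = FALSE)
    prots[[i]] <- data.frame(protein_id = pid, sequence = seq,
                             stringsAsFactors = FALSE)
    if (!is.null(dd)) doms[[i]] <- dd
  }
  gdf <- do.call(rbind, genes)
  nt <- 3L * nchar(do.call(rbind, prots)$sequence) + 3L
  gdf$start <- cumsum(c(1L, head(nt, -1) + 100L))
  gdf$end <- gdf$start + nt - 1L
  gdf <- assign_ranks(gdf)
  dom_df <- if (length(doms)) do.call(rbind, doms) else
    data.frame(protein_id = character(), kind = character(),
               subtype = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  genome_bundle(genome_id, gdf, do.call(rbind, prots), dom_df,
                ssu = ssu, complete = complete)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small fast simulation config for tests
quick_cfg <- function(seed, ...) {
  sim_config(seed = seed, n_background_genes = 60, n_tcs_foci = 8,
             ssu_length = 600, ...)
}

zero_rates <- function() {
  list(gene_loss = 0, focus_loss = 0, duplication = 0, hgt_insertion = 0,
       domain_gain = 0, domain_loss = 0, frameshift = 0, size_indel = 0,
       relocation = 0)
}

# run the comparative detection stack on a simulated pair, returning
# detected canonical keys plus intermediate objects
run_pair_detection <- function(sim, gA = "A", gB = "B") {
  bA <- sim$tips[[gA]]
  bB <- sim$tips[[gB]]
  tcsA <- classify_bundle(bA)
  tcsB <- classify_bundle(bB)
  fA <- build_foci(bA, tcsA)
  fB <- build_foci(bB, tcsB)
  prot <- rbind(tcs_proteins(bA, tcsA), tcs_proteins(bB, tcsB))
  cl <- two_tier_cluster(prot)
  ann <- rbind(annotate_proteins(bA, tcsA, fA),
               annotate_proteins(bB, tcsB, fB))
  sing <- detect_singletons(cl, gA, gB)
  dup <- detect_duplications(cl, ann)
  chg <- detect_changes(cl, ann)
  hgt <- flag_hgt(sing, rbind(bA$proteins, bB$proteins), sim$reference,
                  focal_clade = sim$config$focal_clade)
  list(clusters = cl, ann = ann, singletons = sing, duplications = dup,
       changes = chg, hgts = hgt,
       detected = detected_event_keys(sing, dup, chg, hgt),
       expected = truth_expected_events(sim, gA, gB))
}

precision_recall <- function(detected, expected) {
  if (!nrow(detected) && !nrow(expected)) return(c(precision = 1, recall = 1))
  tp <- sum(detected$key %in% expected$key)
  c(precision = if (nrow(detected)) tp / nrow(detected) else 1,
    recall = if (nrow(expected)) sum(expected$key %in% detected$key) /
      nrow(expected) else 1)
}
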