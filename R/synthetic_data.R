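AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V")
AA_FREQS <- c(0.083,0.055,0.040,0.054,0.014,0.039,0.067,0.072,0.022,0.059,
              0.096,0.058,0.024,0.038,0.047,0.066,0.053,0.011,0.029,0.068)
DNA_ALPHABET <- c("A","C","G","T")
RR_FAMILIES <- c("NtrC", "OmpR", "NarL", "LytTR", "PleD")
SENSOR_SUBTYPES <- c("PAS", "GAF", "Cache")

DOMAIN_LEN <- c(receiver = 115L, transmitter = 210L, phosphoacceptor = 95L,
                output = 105L, input = 85L, TM = 20L)
LINKER_LEN <- 8L
LEADER_LEN <- 12L

random_protein <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE, prob = AA_FREQS),
        collapse = "")
}

random_dna <- function(n) {
  paste(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
}

# mutate a sequence: each position substituted with probability p,
# always to a different letter
mutate_seq <- function(s, p, alphabet = AA_ALPHABET) {
  n <- nchar(s)
  if (n == 0 || p <= 0) return(s)
  k <- rbinom(1, n, min(p, 0.95))
  if (k == 0) return(s)
  pos <- sample.int(n, k)
  ch <- strsplit(s, "")[[1]]
  for (i in pos) ch[i] <- sample(setdiff(alphabet, ch[i]), 1)
  paste(ch, collapse = "")
}

#' Simulation configuration
#'
#' Event rates are per TCS gene (or per focus for `focus_loss`, per genome
#' for `hgt_insertion`) per unit branch length, where branch lengths are
#' in 16S substitutions per site; an event's expected count on a branch is
#' rate x branch length x number of targets. Protein sequences diverge at
#' `protein_rate_scaling` times the 16S rate, optionally with per-gene
#' gamma rate heterogeneity (`gene_rate_shape`; `Inf` = homogeneous). The
#' defaults describe a within-genus comparison: a two-tip tree at 16S
#' p-distance ~0.016 with event rates chosen so that roughly 10% of genes
#' are gained/lost per pairwise comparison, duplications are much rarer
#' than losses, and horizontal acquisitions account for a minority of
#' singletons, mirroring reported within-genus frequencies.
#'
#' @param seed mandatory RNG seed.
#' @param tree Newick string with branch lengths (16S substitutions/site).
#' @param n_background_genes non-TCS genes in the ancestor.
#' @param n_tcs_foci TCS foci in the ancestor.
#' @param focus_mix fractions of orphan/paired/complex/intricate foci
#'   (must sum to 1).
#' @param rates named list of event rates (>= 0): `gene_loss`,
#'   `focus_loss`, `duplication`, `hgt_insertion`, `domain_gain`,
#'   `domain_loss`, `frameshift`, `size_indel`, `relocation`.
#' @param local_dup_prob probability a duplication inserts adjacent to its
#'   source (tandem) rather than at a random distal position.
#' @param size_indel_mean mean residue length of small in-frame indels.
#' @param inversion_prob per-branch probability of one large chromosomal
#'   inversion centred near the replichore midpoint.
#' @param protein_rate_scaling protein vs 16S substitution rate ratio.
#' @param gene_rate_shape gamma shape for per-gene rate factors
#'   (mean 1; `Inf` disables heterogeneity).
#' @param ssu_length 16S rRNA gene length.
#' @param n_foreign_pool size of the separately seeded foreign sequence
#'   pool feeding HGT insertions and the labelled reference set.
#' @param focal_clade clade label given to vertical-descent reference
#'   entries; foreign entries are labelled `"other-order"`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       tree = "(A:0.008,B:0.008);",
                       n_background_genes = 140,
                       n_tcs_foci = 16,
                       focus_mix = c(orphan = 0.35, paired = 0.35,
                                     complex = 0.22, intricate = 0.08),
                       rates = list(),
                       local_dup_prob = 0.7,
                       size_indel_mean = 120,
                       inversion_prob = 0,
                       protein_rate_scaling = 3,
                       gene_rate_shape = Inf,
                       ssu_length = 1500,
                       n_foreign_pool = 12,
                       focal_clade = "focal") {
  if (missing(seed)) abort("seed-required", "sim_config needs a seed")
  default_rates <- list(gene_loss = 6, focus_loss = 1.2, duplication = 0.35,
                        hgt_insertion = 110, domain_gain = 0.5,
                        domain_loss = 0.8, frameshift = 0.5,
                        size_indel = 1.2, relocation = 0)
  rates <- utils::modifyList(default_rates, rates)
  if (any(unlist(rates) < 0)) abort("bad-rates", "rates must be >= 0")
  if (abs(sum(focus_mix) - 1) > 1e-8)
    abort("bad-focus-mix", "focus_mix fractions must sum to 1")
  structure(list(seed = as.integer(seed), tree = tree,
                 n_background_genes = n_background_genes,
                 n_tcs_foci = n_tcs_foci, focus_mix = focus_mix,
                 rates = rates, local_dup_prob = local_dup_prob,
                 size_indel_mean = size_indel_mean,
                 inversion_prob = inversion_prob,
                 protein_rate_scaling = protein_rate_scaling,
                 gene_rate_shape = gene_rate_shape,
                 ssu_length = ssu_length, n_foreign_pool = n_foreign_pool,
                 focal_clade = focal_clade),
            class = "sim_config")
}

# ---- gene construction -----------------------------------------------------

# build one gene's sequence + domain table from an architecture string
# ("RT", "T", "H", "TRTR", ...). Kinase genes may get an N-terminal TM
# helix and sensor (input) domain; lone-receiver genes usually carry an
# output (effector) domain that defines their RR family.
gene_from_arch <- function(arch) {
  kinds <- character(0)
  subtypes <- character(0)
  letters <- strsplit(arch, "")[[1]]
  has_T <- "T" %in% letters
  if (has_T && runif(1) < 0.45) {
    kinds <- c(kinds, "TM"); subtypes <- c(subtypes, NA_character_)
  }
  if (has_T && runif(1) < 0.5 && letters[1] == "T") {
    kinds <- c(kinds, "input")
    subtypes <- c(subtypes, sample(SENSOR_SUBTYPES, 1))
  }
  map <- c(R = "receiver", T = "transmitter", H = "phosphoacceptor")
  kinds <- c(kinds, unname(map[letters]))
  subtypes <- c(subtypes, rep(NA_character_, length(letters)))
  if (identical(letters, "R") && runif(1) < 0.85) {
    kinds <- c(kinds, "output")
    subtypes <- c(subtypes, sample(RR_FAMILIES, 1))
  }
  seq_parts <- random_protein(LEADER_LEN)
  pos <- LEADER_LEN
  dom <- list()
  for (i in seq_along(kinds)) {
    len <- DOMAIN_LEN[[kinds[i]]]
    dom[[i]] <- data.frame(kind = kinds[i], subtype = subtypes[i],
                           start = pos + 1L, end = pos + len,
                           stringsAsFactors = FALSE)
    seq_parts <- c(seq_parts, random_protein(len), random_protein(LINKER_LEN))
    pos <- pos + len + LINKER_LEN
  }
  list(sequence = paste(seq_parts, collapse = ""),
       domains = do.call(rbind, dom))
}

new_gene <- function(origin, sequence, domains, strand, is_tcs,
                     focus = NA_character_, via = "ancestral",
                     origin_group = origin, pseudogene = FALSE,
                     rate_factor = 1) {
  list(origin = origin, origin_group = origin_group, via = via,
       sequence = sequence, domains = domains, strand = strand,
       is_tcs = is_tcs, focus = focus, pseudogene = pseudogene,
       rate_factor = rate_factor)
}

empty_gene_domains <- function() {
  data.frame(kind = character(), subtype = character(), start = integer(),
             end = integer(), stringsAsFactors = FALSE)
}

background_gene <- function(origin) {
  new_gene(origin, random_protein(sample(150:450, 1)), empty_gene_domains(),
           sample(c("+", "-"), 1), is_tcs = FALSE)
}

# architecture patterns per focus category; each pattern is a character
# vector of per-gene architecture strings
focus_patterns <- function(category) {
  switch(category,
    orphan = sample(c("R", "T", "H"), 1, prob = c(0.55, 0.30, 0.15)),
    paired = if (runif(1) < 0.4) "RT" else c("T", "R"),
    complex = sample(list(c("T", "R", "R"), c("RT", "R"), c("R", "T", "R"),
                          c("T", "R", "H")), 1)[[1]],
    intricate = sample(list("TRTR", c("TR", "TR"), c("T", "R", "T", "R"),
                            c("TRT", "R")), 1)[[1]])
}

# ---- ancestor --------------------------------------------------------------

simulate_ancestor_state <- function(cfg) {
  n_bg <- cfg$n_background_genes
  n_foci <- cfg$n_tcs_foci
  counts <- floor(cfg$focus_mix * n_foci)
  rem <- n_foci - sum(counts)
  if (rem > 0) {
    frac <- cfg$focus_mix * n_foci - counts
    bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[bump] <- counts[bump] + 1
  }
  cats <- rep(names(counts), counts)
  gap <- if (n_foci > 0) floor(n_bg / (n_foci + 1)) else n_bg
  if (n_foci > 0 && gap < 2)
    abort("too-few-background-genes",
          "need >= 2 background genes between foci")
  genes <- list()
  gid <- 0L
  next_origin <- function() {
    gid <<- gid + 1L
    sprintf("g%04d", gid)
  }
  bg_left <- n_bg
  add_bg <- function(k) {
    for (i in seq_len(k)) genes[[length(genes) + 1L]] <<-
        background_gene(next_origin())
    bg_left <<- bg_left - k
  }
  for (fi in seq_along(cats)) {
    add_bg(gap)
    pat <- focus_patterns(cats[fi])
    strand <- sample(c("+", "-"), 1)
    focus <- sprintf("F%03d", fi)
    archs <- if (strand == "-") rev(pat) else pat
    for (ai in seq_along(archs)) {
      g <- gene_from_arch(archs[[ai]])
      genes[[length(genes) + 1L]] <- new_gene(
        next_origin(), g$sequence, g$domains, strand, is_tcs = TRUE,
        focus = focus)
      # optionally one intervening non-TCS gene inside multi-gene foci
      if (ai < length(archs) && runif(1) < 0.2) add_bg(1)
    }
  }
  if (bg_left > 0) add_bg(bg_left)
  list(genes = genes, ssu = random_dna(cfg$ssu_length))
}

state_to_bundle <- function(state, genome_id, complete = TRUE) {
  n <- length(state$genes)
  if (n == 0) {
    return(genome_bundle(genome_id, empty_genes(),
                         data.frame(protein_id = character(),
                                    sequence = character(),
                                    stringsAsFactors = FALSE),
                         ssu = state$ssu, complete = complete))
  }
  locus <- sprintf("%s_%05d", genome_id, 5L * seq_len(n))
  pid <- sprintf("%s_P%05d", genome_id, 5L * seq_len(n))
  lens <- vapply(state$genes, function(g) nchar(g$sequence), integer(1))
  nt <- 3L * lens + 3L
  start <- cumsum(c(1L, head(nt, -1) + 120L))
  genes <- data.frame(
    locus_tag = locus, contig = "chr", rank = seq_len(n) - 1L,
    strand = vapply(state$genes, `[[`, character(1), "strand"),
    start = start, end = start + nt - 1L,
    pseudogene = vapply(state$genes, `[[`, logical(1), "pseudogene"),
    protein_id = pid, stringsAsFactors = FALSE)
  proteins <- data.frame(
    protein_id = pid,
    sequence = vapply(state$genes, `[[`, character(1), "sequence"),
    stringsAsFactors = FALSE)
  doms <- lapply(seq_len(n), function(i) {
    d <- state$genes[[i]]$domains
    if (!nrow(d)) return(NULL)
    cbind(data.frame(protein_id = pid[i], stringsAsFactors = FALSE), d)
  })
  doms <- do.call(rbind, doms)
  if (is.null(doms)) doms <- empty_domains()
  genome_bundle(genome_id, genes, proteins, doms, ssu = state$ssu,
                complete = complete)
}

state_orthology <- function(state, genome_id) {
  n <- length(state$genes)
  data.frame(
    origin = vapply(state$genes, `[[`, character(1), "origin"),
    origin_group = vapply(state$genes, `[[`, character(1), "origin_group"),
    via = vapply(state$genes, `[[`, character(1), "via"),
    is_tcs = vapply(state$genes, `[[`, logical(1), "is_tcs"),
    locus_tag = sprintf("%s_%05d", genome_id, 5L * seq_len(n)),
    protein_id = sprintf("%s_P%05d", genome_id, 5L * seq_len(n)),
    stringsAsFactors = FALSE)
}

#' Simulate the ancestral genome
#'
#' Single-contig genome with `n_background_genes` non-TCS genes and
#' `n_tcs_foci` TCS foci drawn from `focus_mix`, each with consistent
#' domain annotations and random sequences. Deterministic given the seed.
#'
#' @param cfg a [sim_config()].
#' @return a `genome_bundle` (genome id `"ancestor"`).
#' @export
simulate_ancestor <- function(cfg) {
  set.seed(cfg$seed)
  state_to_bundle(simulate_ancestor_state(cfg), "ancestor")
}
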