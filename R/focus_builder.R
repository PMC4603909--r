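#' Group TCS genes into genomic foci
#'
#' A focus is a maximal run of same-strand TCS genes in which consecutive
#' TCS genes are separated by at most one non-TCS gene. A strand change,
#' two or more consecutive non-TCS genes, or a contig end terminates the
#' focus. Every TCS gene belongs to exactly one focus. Intervening genes
#' are counted irrespective of their own strand.
#'
#' @param b a `genome_bundle`.
#' @param tcs classification table from [classify_bundle()].
#' @param max_intervening maximum number of non-TCS genes allowed between
#'   consecutive members (default 1).
#' @return data.frame with one row per focus: `focus_id`, `genome_id`,
#'   `contig`, `strand`, `members` (list-column of locus tags in genomic
#'   order), `n_genes`, `notation`, `category`, `intricate`.
#' @export
build_foci <- function(b, tcs, max_intervening = 1) {
  cls <- setNames(tcs$tcs_class, tcs$protein_id)
  arch <- setNames(tcs$architecture, tcs$protein_id)
  g <- b$genes[order(b$genes$contig, b$genes$rank), , drop = FALSE]
  pid <- g$protein_id
  is_tcs <- !is.na(pid) & pid %in% names(cls) & cls[pid] != "NONE"
  foci <- list()
  cur <- NULL   # list(contig, strand, idx of member rows)
  close_focus <- function() {
    if (!is.null(cur)) foci[[length(foci) + 1L]] <<- cur
    cur <<- NULL
  }
  gap <- 0L
  last_contig <- NA_character_
  for (i in seq_len(nrow(g))) {
    if (!identical(g$contig[i], last_contig)) {
      close_focus()
      gap <- 0L
      last_contig <- g$contig[i]
    }
    if (!is_tcs[i]) {
      gap <- gap + 1L
      if (gap > max_intervening) close_focus()
      next
    }
    if (!is.null(cur) && g$strand[i] != cur$strand) close_focus()
    if (is.null(cur)) {
      cur <- list(contig = g$contig[i], strand = g$strand[i], idx = i)
    } else {
      cur$idx <- c(cur$idx, i)
    }
    gap <- 0L
  }
  close_focus()
  if (!length(foci)) {
    return(data.frame(focus_id = character(), genome_id = character(),
                      contig = character(), strand = character(),
                      members = I(list()), n_genes = integer(),
                      notation = character(), category = character(),
                      intricate = logical(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(foci), function(k) {
    f <- foci[[k]]
    tags <- g$locus_tag[f$idx]
    nota <- focus_notation(unname(arch[g$protein_id[f$idx]]), f$strand)
    data.frame(focus_id = sprintf("%s_F%03d", b$genome_id, k),
               genome_id = b$genome_id, contig = f$contig,
               strand = f$strand, members = I(list(tags)),
               n_genes = length(tags), notation = nota,
               category = classify_focus(nota),
               intricate = detect_intricate(nota),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Focus notation string
#'
#' Joins the member architecture strings with commas, members in genomic
#' order. For minus-strand foci the member order is reversed so that the
#' string follows the transcription direction; within-protein domain order
#' is already N-to-C and needs no flip. Intervening non-TCS genes are not
#' represented.
#'
#' @param architectures character vector of member architecture strings in
#'   genomic (rank) order.
#' @param strand `"+"` or `"-"`.
#' @return notation string such as `"RT,R"`.
#' @export
focus_notation <- function(architectures, strand = "+") {
  if (strand == "-") architectures <- rev(architectures)
  paste(architectures, collapse = ",")
}

# internal: count R/T/H symbols in a notation string
notation_counts <- function(notation) {
  ch <- strsplit(gsub(",", "", notation), "")[[1]]
  c(R = sum(ch == "R"), T = sum(ch == "T"), H = sum(ch == "H"))
}

#' Focus organisation category
#'
#' `ORPHAN`: a single gene carrying exactly one TCS domain (R, T or H).
#' `PAIRED`: the focus's TCS-domain multiset is exactly one T plus one R -
#' either a single hybrid-kinase gene (`RT`/`TR`) or an HK/RR gene pair
#' (`T,R`/`R,T`), i.e. the focus encodes one complete two-component
#' system. `COMPLEX`: anything else.
#'
#' @param notation focus notation string over `{R,T,H}` with commas
#'   separating genes, e.g. `"RT,R"`.
#' @return one of `"ORPHAN"`, `"PAIRED"`, `"COMPLEX"`.
#' @export
classify_focus <- function(notation) {
  n <- notation_counts(notation)
  n_genes <- length(strsplit(notation, ",", fixed = TRUE)[[1]])
  if (n_genes == 1L && sum(n) == 1L) return("ORPHAN")
  if (n[["T"]] == 1L && n[["R"]] == 1L && n[["H"]] == 0L) return("PAIRED")
  "COMPLEX"
}

#' Intricate focus test
#'
#' A focus (or single protein) is intricate when at least two receiver and
#' at least two transmitter domains occur within it.
#'
#' @param notation focus notation string (a single protein's architecture
#'   qualifies on its own).
#' @return logical.
#' @export
detect_intricate <- function(notation) {
  n <- notation_counts(notation)
  n[["R"]] >= 2L && n[["T"]] >= 2L
}

#' Build a per-genome statistics row from counts
#'
#' Derived percentages are computed from the counts unless explicitly
#' supplied (printed tables sometimes carry percentages that are inputs in
#' their own right). Percentages use one-decimal rounding, half away from
#' zero. The hybrid percentage uses all HK-type proteins (non-hybrid +
#' hybrid) as denominator, as does the TM percentage.
#'
#' @param genome_id genome label.
#' @param n_hk,n_hybrid,n_pp,n_rr class counts.
#' @param pct_tm_hk,pct_orphan,pct_paired,pct_complex,n_intricate_foci
#'   optional values (NA when unavailable, e.g. incomplete genomes).
#' @param pct_hybrid optional override; computed from counts when NULL.
#' @param n_tcs optional override; computed as the class-count sum when
#'   NULL.
#' @return one-row data.frame (a `GenomeStats` row).
#' @export
genome_stats <- function(genome_id, n_hk, n_hybrid, n_pp, n_rr,
                         pct_tm_hk = NA_real_, pct_orphan = NA_real_,
                         pct_paired = NA_real_, pct_complex = NA_real_,
                         n_intricate_foci = NA_real_,
                         pct_hybrid = NULL, n_tcs = NULL) {
  n_tcs <- n_tcs %||% (n_hk + n_hybrid + n_pp + n_rr)
  if (is.null(pct_hybrid)) {
    pct_hybrid <- if (n_hk + n_hybrid > 0)
      round_half_up(100 * n_hybrid / (n_hk + n_hybrid), 1) else 0
  }
  data.frame(genome_id = genome_id, n_tcs = n_tcs, n_hk = n_hk,
             n_hybrid = n_hybrid, n_pp = n_pp, n_rr = n_rr,
             pct_hybrid = pct_hybrid, pct_tm_hk = pct_tm_hk,
             pct_orphan = pct_orphan, pct_paired = pct_paired,
             pct_complex = pct_complex,
             n_intricate_foci = n_intricate_foci, stringsAsFactors = FALSE)
}

#' Summarise one genome's TCS gene set
#'
#' Computes the class counts, hybrid and TM percentages, gene-weighted
#' organisation percentages (fraction of TCS genes residing in foci of
#' each category) and the intricate-focus count. Organisation percentages
#' and the intricate count are reported as NA for incomplete genomes.
#'
#' @param b a `genome_bundle`.
#' @param tcs classification table from [classify_bundle()].
#' @param foci focus table from [build_foci()].
#' @return one-row data.frame (see [genome_stats()]), with an extra
#'   logical column `no_tcs` flagging genomes without any TCS gene.
#' @export
genome_summary <- function(b, tcs, foci) {
  cc <- table(factor(tcs$tcs_class,
                     levels = c("HK", "HYBRID_HK", "PP", "RR", "NONE")))
  hkish <- tcs$tcs_class %in% c("HK", "HYBRID_HK")
  pct_tm <- if (any(hkish))
    round_half_up(100 * sum(tcs$has_tm[hkish]) / sum(hkish), 1) else 0
  if (b$complete && nrow(foci)) {
    w <- tapply(foci$n_genes, factor(foci$category,
                                     levels = c("ORPHAN", "PAIRED", "COMPLEX")),
                sum, default = 0L)
    tot <- sum(w)
    pct <- round_half_up(100 * w / tot, 1)
    n_int <- sum(foci$intricate)
  } else if (b$complete) {
    pct <- c(ORPHAN = 0, PAIRED = 0, COMPLEX = 0)
    n_int <- 0L
  } else {
    pct <- c(ORPHAN = NA_real_, PAIRED = NA_real_, COMPLEX = NA_real_)
    n_int <- NA_integer_
  }
  out <- genome_stats(b$genome_id,
                      n_hk = unname(cc[["HK"]]),
                      n_hybrid = unname(cc[["HYBRID_HK"]]),
                      n_pp = unname(cc[["PP"]]), n_rr = unname(cc[["RR"]]),
                      pct_tm_hk = pct_tm,
                      pct_orphan = unname(pct[["ORPHAN"]]),
                      pct_paired = unname(pct[["PAIRED"]]),
                      pct_complex = unname(pct[["COMPLEX"]]),
                      n_intricate_foci = n_int)
  out$no_tcs <- out$n_tcs == 0L
  out
}

#' Published per-genome TCS summary statistics
#'
#' The printed summary table for twelve myxobacterial genomes plus
#' *Bdellovibrio bacteriovorus* (genome `Bb`): per-genome class counts,
#' hybrid/TM percentages, organisation percentages and intricate-focus
#' counts. Organisation columns are NA for the two incomplete genomes.
#' Note that the printed `pct_hybrid` cells for `AdC` and `AF` are not
#' internally consistent with their printed counts (presumed typos in the
#' source table); the values here are the printed ones.
#'
#' @return data.frame with one row per genome (see [genome_stats()]).
#' @export
myxo_table2 <- function() {
  path <- system.file("extdata", "myxo_table2.tsv", package = "tcsevo")
  df <- tsv_read(path, ints = c("n_tcs", "n_hk", "n_hybrid", "n_pp",
                                "n_rr", "n_intricate_foci"),
                 logicals = "complete")
  for (cl in c("pct_hybrid", "pct_tm_hk", "pct_orphan", "pct_paired",
               "pct_complex"))
    df[[cl]] <- as.numeric(df[[cl]])
  df$n_intricate_foci <- as.numeric(df$n_intricate_foci)
  df
}

#' Cohort mean row over genome statistics
#'
#' Arithmetic column means over a set of [genome_stats()] rows, skipping
#' not-available entries, rounded to one decimal (half away from zero).
#'
#' @param stats data.frame of stats rows (rbind of [genome_stats()] /
#'   [genome_summary()] output).
#' @return one-row data.frame with `genome_id = "mean"`.
#' @export
cohort_summary <- function(stats) {
  if (!nrow(stats)) abort("empty-input", "no genome statistics supplied")
  num <- vapply(stats, is.numeric, logical(1))
  means <- lapply(names(stats)[num], function(cl)
    round_half_up(mean(stats[[cl]], na.rm = TRUE), 1))
  out <- c(list(genome_id = "mean"), setNames(means, names(stats)[num]))
  as.data.frame(out, stringsAsFactors = FALSE)
}
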