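#' Merge split kinase-core annotations into transmitter hits
#'
#' A transmitter (T) is the histidine-kinase core: a phosphoacceptor
#' (HisKA-like) region followed by an ATPase region. Annotation sources may
#' deliver the core either pre-merged (`kind = "transmitter"`) or as split
#' parts; this normalisation merges each phosphoacceptor hit that is
#' immediately followed by an ATPase-flavoured `input` hit (within
#' `max_gap` residues) into a single transmitter hit. Unpaired
#' phosphoacceptors stay as they are (they count as H, e.g. Hpt proteins).
#' Idempotent.
#'
#' @param domains domain-hit data.frame for one protein (columns
#'   `protein_id`, `kind`, `subtype`, `start`, `end`).
#' @param max_gap maximum residue gap between the phosphoacceptor end and
#'   the ATPase start (default 200).
#' @return the normalised domain table, sorted by start.
#' @export
transmitter_from_parts <- function(domains, max_gap = 200) {
  d <- domains[order(domains$start), , drop = FALSE]
  if (!nrow(d)) return(d)
  is_atp <- d$kind == "input" & !is.na(d$subtype) &
    grepl("atpase", d$subtype, ignore.case = TRUE)
  drop <- logical(nrow(d))
  for (i in which(d$kind == "phosphoacceptor")) {
    js <- which(is_atp & !drop & d$start > d$end[i] &
                  d$start - d$end[i] - 1L <= max_gap)
    if (!length(js)) next
    j <- js[which.min(d$start[js])]
    d$kind[i] <- "transmitter"
    d$subtype[i] <- NA_character_
    d$end[i] <- d$end[j]
    drop[j] <- TRUE
  }
  d <- d[!drop, , drop = FALSE]
  d[order(d$start), , drop = FALSE]
}

#' Classify one protein from its domain content
#'
#' Classes follow the standard TCS taxonomy: `HK` (>=1 transmitter, no
#' receiver), `HYBRID_HK` (>=1 transmitter and >=1 receiver in one
#' protein), `RR` (>=1 receiver, no transmitter), `PP` (phosphoacceptor
#' domains only, i.e. phosphotransfer proteins), `NONE` (no TCS domain).
#' The architecture string lists R/T/H symbols in N-to-C order.
#'
#' @param protein_id id recorded in the result.
#' @param length protein length in residues.
#' @param domains domain-hit data.frame for this protein.
#' @param merge_parts apply [transmitter_from_parts()] first (default TRUE).
#' @param max_gap passed to [transmitter_from_parts()].
#' @return one-row data.frame: `protein_id`, `tcs_class`, `architecture`,
#'   `n_receiver`, `n_transmitter`, `n_phosphoacceptor`, `rr_family`
#'   (subtype of the first output-domain hit, only for receiver-bearing
#'   proteins), `has_tm`, `length`.
#' @export
classify_protein <- function(protein_id, length, domains,
                             merge_parts = TRUE, max_gap = 200) {
  d <- if (merge_parts) transmitter_from_parts(domains, max_gap) else
    domains[order(domains$start), , drop = FALSE]
  nR <- sum(d$kind == "receiver")
  nT <- sum(d$kind == "transmitter")
  nH <- sum(d$kind == "phosphoacceptor")
  cls <- if (nT >= 1 && nR >= 1) "HYBRID_HK"
  else if (nT >= 1) "HK"
  else if (nR >= 1) "RR"
  else if (nH >= 1) "PP"
  else "NONE"
  sym <- c(receiver = "R", transmitter = "T", phosphoacceptor = "H")
  core <- d$kind %in% names(sym)
  arch <- paste(sym[d$kind[core]], collapse = "")
  fam <- NA_character_
  if (nR >= 1) {
    out <- which(d$kind == "output")
    if (length(out)) fam <- d$subtype[out[1]]
  }
  data.frame(protein_id = protein_id, tcs_class = cls, architecture = arch,
             n_receiver = nR, n_transmitter = nT, n_phosphoacceptor = nH,
             rr_family = fam, has_tm = any(d$kind == "TM"),
             length = length, stringsAsFactors = FALSE)
}

#' Classify every protein in a bundle
#'
#' @param b a `genome_bundle`.
#' @param merge_parts,max_gap see [classify_protein()].
#' @return data.frame, one row per protein (all proteins, including
#'   `NONE`), plus columns `genome_id`, `locus_tag` and `pseudogene` joined
#'   from the gene table.
#' @export
classify_bundle <- function(b, merge_parts = TRUE, max_gap = 200) {
  rows <- lapply(seq_len(nrow(b$proteins)), function(i) {
    pid <- b$proteins$protein_id[i]
    classify_protein(pid, b$proteins$length[i], protein_domains(b, pid),
                     merge_parts = merge_parts, max_gap = max_gap)
  })
  tcs <- if (length(rows)) do.call(rbind, rows) else
    classify_protein(character(0), integer(0), empty_domains())[0, ]
  tcs$genome_id <- b$genome_id
  g <- b$genes[!is.na(b$genes$protein_id),
               c("protein_id", "locus_tag", "pseudogene")]
  tcs <- merge(tcs, g, by = "protein_id", all.x = TRUE, sort = FALSE)
  tcs[order(tcs$protein_id), , drop = FALSE]
}

#' Domain-composition matrix of classified TCS proteins
#'
#' Counts TCS proteins (class != NONE) by banded transmitter count
#' (0/1/2+) and receiver count (0/1/2/3/4+). The (0T, 0R) cell holds the
#' phosphoacceptor-only (PP) proteins.
#'
#' @param tcs classification table from [classify_bundle()] (or several
#'   rbind-ed together).
#' @return 3 x 5 integer matrix with dimnames `c("0T","1T","2+T")` x
#'   `c("0R","1R","2R","3R","4+R")`.
#' @export
composition_matrix <- function(tcs) {
  m <- matrix(0L, nrow = 3, ncol = 5,
              dimnames = list(c("0T", "1T", "2+T"),
                              c("0R", "1R", "2R", "3R", "4+R")))
  keep <- tcs$tcs_class != "NONE"
  tb <- pmin(tcs$n_transmitter[keep], 2L) + 1L
  rb <- pmin(tcs$n_receiver[keep], 4L) + 1L
  for (i in seq_along(tb)) m[tb[i], rb[i]] <- m[tb[i], rb[i]] + 1L
  m
}
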