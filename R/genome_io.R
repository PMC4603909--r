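#' Construct a genome annotation bundle
#'
#' A bundle is the unit of input for all downstream analysis: an ordered
#' gene table, the encoded protein sequences, their domain annotations, and
#' (optionally) a 16S rRNA gene sequence.
#'
#' @param genome_id single string identifying the genome.
#' @param genes data.frame with columns `locus_tag`, `contig`, `rank`
#'   (0-based gene-order index within contig), `strand` (`+`/`-`), `start`,
#'   `end` (1-based inclusive nucleotide coordinates), `pseudogene`
#'   (logical), `protein_id` (NA when the gene encodes no protein).
#' @param proteins data.frame with columns `protein_id`, `sequence`
#'   (amino-acid string).
#' @param domains data.frame with columns `protein_id`, `kind` (one of
#'   [DOMAIN_KINDS]), `subtype` (free string, NA allowed), `start`, `end`
#'   (1-based inclusive residue coordinates).
#' @param ssu 16S rRNA gene sequence (nucleotide string) or NULL.
#' @param complete logical; incomplete genomes have their gene-organisation
#'   percentages suppressed in summaries.
#' @return object of class `genome_bundle`.
#' @seealso [read_bundle()], [write_bundle()], [validate_bundle()]
#' @export
genome_bundle <- function(genome_id, genes, proteins,
                          domains = empty_domains(), ssu = NULL,
                          complete = TRUE) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  domains <- as.data.frame(domains, stringsAsFactors = FALSE)
  need_g <- c("locus_tag", "contig", "rank", "strand", "start", "end",
              "pseudogene", "protein_id")
  if (!all(need_g %in% names(genes)))
    abort("bad-genes-table", "missing columns: ",
          paste(setdiff(need_g, names(genes)), collapse = ", "))
  if (!all(c("protein_id", "sequence") %in% names(proteins)))
    abort("bad-proteins-table", "need protein_id and sequence columns")
  need_d <- c("protein_id", "kind", "subtype", "start", "end")
  if (!all(need_d %in% names(domains)))
    abort("bad-domains-table", "missing columns: ",
          paste(setdiff(need_d, names(domains)), collapse = ", "))
  genes <- genes[order(genes$contig, genes$rank), , drop = FALSE]
  rownames(genes) <- NULL
  proteins$length <- nchar(proteins$sequence)
  domains <- domains[order(domains$protein_id, domains$start), , drop = FALSE]
  rownames(domains) <- NULL
  structure(list(genome_id = as.character(genome_id), genes = genes,
                 proteins = proteins, domains = domains,
                 ssu = ssu, complete = isTRUE(complete)),
            class = "genome_bundle")
}

empty_genes <- function() {
  data.frame(locus_tag = character(), contig = character(),
             rank = integer(), strand = character(), start = integer(),
             end = integer(), pseudogene = logical(),
             protein_id = character(), stringsAsFactors = FALSE)
}

empty_domains <- function() {
  data.frame(protein_id = character(), kind = character(),
             subtype = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat(sprintf("genome_bundle '%s': %d genes, %d proteins, %d domain hits%s%s\n",
              x$genome_id, nrow(x$genes), nrow(x$proteins), nrow(x$domains),
              if (is.null(x$ssu)) "" else ", 16S present",
              if (x$complete) "" else " [incomplete genome]"))
  invisible(x)
}

#' Assign gene-order ranks from coordinates
#'
#' Ranks are 0-based per contig, ascending by start coordinate; ties are
#' broken by locus tag (the generalisable stand-in for consecutive
#' locus-tag numbering).
#'
#' @param genes a gene table (see [genome_bundle()]).
#' @return the table ordered by (contig, rank) with `rank` recomputed.
#' @export
assign_ranks <- function(genes) {
  genes <- genes[order(genes$contig, genes$start, genes$locus_tag), ,
                 drop = FALSE]
  genes$rank <- stats::ave(seq_len(nrow(genes)), genes$contig,
                           FUN = seq_along) - 1L
  rownames(genes) <- NULL
  genes
}

#' Validate a genome bundle
#'
#' Checks every structural invariant of the bundle and returns a
#' machine-readable issue table rather than stopping, so callers can decide
#' what is fatal.
#'
#' @param b a `genome_bundle`.
#' @return data.frame with columns `code` and `where`; zero rows iff the
#'   bundle satisfies all invariants.
#' @export
validate_bundle <- function(b) {
  issues <- list()
  add <- function(code, where) {
    issues[[length(issues) + 1L]] <<- data.frame(
      code = code, where = where, stringsAsFactors = FALSE)
  }
  g <- b$genes
  dup <- unique(g$locus_tag[duplicated(g$locus_tag)])
  for (d in dup) add("duplicate-locus-tag", d)
  bad <- g$locus_tag[!is.na(g$start) & !is.na(g$end) & g$start > g$end]
  for (d in bad) add("start-after-end", d)
  bad <- g$locus_tag[!g$strand %in% c("+", "-")]
  for (d in bad) add("bad-strand", d)
  for (ct in unique(g$contig)) {
    r <- sort(g$rank[g$contig == ct])
    if (length(r) && !identical(as.integer(r), seq(0L, length(r) - 1L)))
      add("rank-not-consecutive", ct)
  }
  dangling <- setdiff(stats::na.omit(g$protein_id), b$proteins$protein_id)
  for (d in dangling) add("dangling-protein-id", d)
  dupp <- unique(b$proteins$protein_id[duplicated(b$proteins$protein_id)])
  for (d in dupp) add("duplicate-protein-id", d)
  dm <- b$domains
  bad <- !dm$kind %in% DOMAIN_KINDS
  for (i in which(bad)) add("unknown-domain-kind",
                            paste0(dm$protein_id[i], ":", dm$kind[i]))
  plen <- setNames(b$proteins$length, b$proteins$protein_id)
  known <- dm$protein_id %in% names(plen)
  for (i in which(!known)) add("domain-orphan-protein", dm$protein_id[i])
  for (i in which(known)) {
    if (dm$start[i] > dm$end[i] || dm$start[i] < 1 ||
        dm$end[i] > plen[[dm$protein_id[i]]])
      add("domain-out-of-range",
          paste0(dm$protein_id[i], ":", dm$start[i], "-", dm$end[i]))
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(code = character(), where = character(),
                  stringsAsFactors = FALSE)
}

write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    if (nchar(s) == 0) next
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) return(setNames(character(0), character(0)))
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  body <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  out <- setNames(character(length(ids)), ids)
  out[as.integer(names(body))] <- unname(body)
  out
}

tsv_write <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.logical(v)) v <- ifelse(v, "TRUE", "FALSE")
    v <- as.character(v)
    v[is.na(v)] <- "."
    out[[j]] <- v
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

tsv_read <- function(path, ints = character(), logicals = character()) {
  df <- read.delim(path, sep = "\t", na.strings = ".",
                   colClasses = "character", check.names = FALSE)
  for (cl in intersect(ints, names(df))) df[[cl]] <- as.integer(df[[cl]])
  for (cl in intersect(logicals, names(df))) df[[cl]] <- df[[cl]] == "TRUE"
  df
}

#' Write a genome bundle to a directory
#'
#' Emits `proteins.faa` (60-column FASTA), `genes.tsv`, `domains.tsv`,
#' optional `ssu.fna`, and `bundle.json` (genome id and completeness flag).
#' `read_bundle(write_bundle(b, d))` is the identity.
#'
#' @param b a `genome_bundle`.
#' @param dir_path output directory (created if needed).
#' @return `dir_path`, invisibly.
#' @export
write_bundle <- function(b, dir_path) {
  stopifnot(inherits(b, "genome_bundle"))
  ok <- dir.exists(dir_path) || dir.create(dir_path, recursive = TRUE)
  if (!ok) abort("io-error", "cannot create directory ", dir_path)
  write_fasta(setNames(as.list(b$proteins$sequence), b$proteins$protein_id),
              file.path(dir_path, "proteins.faa"))
  tsv_write(b$genes[c("locus_tag", "contig", "rank", "strand", "start",
                      "end", "pseudogene", "protein_id")],
            file.path(dir_path, "genes.tsv"))
  tsv_write(b$domains[c("protein_id", "kind", "subtype", "start", "end")],
            file.path(dir_path, "domains.tsv"))
  if (!is.null(b$ssu))
    write_fasta(setNames(list(b$ssu), paste0(b$genome_id, "_16S")),
                file.path(dir_path, "ssu.fna"))
  jsonlite::write_json(list(genome_id = b$genome_id, complete = b$complete),
                       file.path(dir_path, "bundle.json"), auto_unbox = TRUE)
  invisible(dir_path)
}

#' Read a genome bundle from a directory
#'
#' Counterpart of [write_bundle()]. Fatal inconsistencies (duplicate locus
#' tags, dangling protein ids, unknown domain kinds) raise an error listing
#' the offenders; everything else is left to [validate_bundle()].
#'
#' @param dir_path directory holding `proteins.faa`, `genes.tsv`,
#'   `domains.tsv` and optionally `ssu.fna` / `bundle.json`.
#' @return a `genome_bundle`.
#' @export
read_bundle <- function(dir_path) {
  for (f in c("proteins.faa", "genes.tsv", "domains.tsv")) {
    if (!file.exists(file.path(dir_path, f)))
      abort("load-error", "missing file ", f, " in ", dir_path)
  }
  prot <- read_fasta(file.path(dir_path, "proteins.faa"))
  genes <- tsv_read(file.path(dir_path, "genes.tsv"),
                    ints = c("rank", "start", "end"),
                    logicals = "pseudogene")
  domains <- tsv_read(file.path(dir_path, "domains.tsv"),
                      ints = c("start", "end"))
  meta <- list(genome_id = basename(normalizePath(dir_path)), complete = TRUE)
  mj <- file.path(dir_path, "bundle.json")
  if (file.exists(mj)) meta <- utils::modifyList(meta, jsonlite::read_json(mj))
  ssu <- NULL
  sf <- file.path(dir_path, "ssu.fna")
  if (file.exists(sf)) {
    s <- read_fasta(sf)
    if (length(s)) ssu <- unname(s[[1]])
  }
  b <- genome_bundle(meta$genome_id, genes,
                     data.frame(protein_id = names(prot),
                                sequence = unname(prot),
                                stringsAsFactors = FALSE),
                     domains, ssu = ssu, complete = isTRUE(meta$complete))
  iss <- validate_bundle(b)
  fatal <- iss[iss$code %in% c("duplicate-locus-tag", "dangling-protein-id",
                               "unknown-domain-kind"), , drop = FALSE]
  if (nrow(fatal))
    abort("validation-error",
          paste(paste0(fatal$code, " [", fatal$where, "]"), collapse = "; "))
  b
}

# internal: domain hits for one protein, sorted by start
protein_domains <- function(b, protein_id) {
  d <- b$domains[b$domains$protein_id == protein_id, , drop = FALSE]
  d[order(d$start), , drop = FALSE]
}
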