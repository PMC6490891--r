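#' @importFrom methods as
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table head tail
NULL

ALPHABETS <- list(
  aa  = c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*"),
  dna = c("A", "C", "G", "T", "N"),
  any = NULL
)

# Accepts a file path or literal text (anything containing a newline or
# starting with ">" / "#" is treated as text).
.as_lines <- function(input) {
  if (length(input) == 1 && !grepl("[\n>#\t]", input) && file.exists(input)) {
    return(readLines(input, warn = FALSE))
  }
  unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
}

#' Parse FASTA text into a sequence table
#'
#' Reads FASTA from a file path or a literal character string and returns a
#' data frame with one row per record (columns `id`, `desc`, `seq`).
#' Sequence lines wrapped across multiple lines are concatenated; record
#' order is preserved.
#'
#' @param input File path or FASTA text.
#' @param alphabet One of `"aa"`, `"dna"`, `"any"`. Under `strict = TRUE`,
#'   residues outside the alphabet (after upper-casing) are an error that
#'   names the record and offending position.
#' @param strict Logical; strict mode also makes duplicate ids an error.
#'   In lax mode duplicates are disambiguated by suffixing `_2`, `_3`, ...
#' @return `data.frame(id, desc, seq)` with attribute `alphabet`.
#' @export
parse_fasta <- function(input, alphabet = c("any", "aa", "dna"), strict = TRUE) {
  alphabet <- match.arg(alphabet)
  lines <- .as_lines(input)
  lines <- lines[!grepl("^\\s*$", lines) | FALSE]
  if (length(lines) == 0) stop("empty FASTA input")
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) stop("FASTA sequence line before any header")
  rec_idx <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- vapply(seq_along(headers), function(i) {
    paste(lines[!is_hdr & rec_idx == i], collapse = "")
  }, character(1))
  seqs <- toupper(gsub("\\s", "", seqs))
  if (any(ids == "")) stop("FASTA record with empty id")
  empty <- which(nchar(seqs) == 0)
  if (length(empty)) {
    stop("FASTA record '", ids[empty[1]], "' has an empty sequence")
  }
  dup <- duplicated(ids)
  if (any(dup)) {
    if (strict) stop("duplicate FASTA id: '", ids[which(dup)[1]], "'")
    for (id in unique(ids[dup])) {
      k <- which(ids == id)
      ids[k[-1]] <- paste0(id, "_", seq_along(k[-1]) + 1L)
    }
  }
  if (strict && !is.null(ALPHABETS[[alphabet]])) {
    ok <- ALPHABETS[[alphabet]]
    for (i in seq_along(seqs)) {
      res <- strsplit(seqs[i], "")[[1]]
      bad <- which(!res %in% ok)
      if (length(bad)) {
        stop("illegal residue '", res[bad[1]], "' at position ", bad[1],
             " of record '", ids[i], "'")
      }
    }
  }
  out <- data.frame(id = ids, desc = descs, seq = seqs,
                    stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  out
}

#' Write a sequence table as FASTA
#'
#' @param seqs `data.frame(id, desc, seq)` as returned by [parse_fasta()].
#' @param path Output path, or `NULL` to return the FASTA text invisibly.
#' @param width Line-wrap width (default 60).
#' @export
write_fasta <- function(seqs, path = NULL, width = 60) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  desc <- if ("desc" %in% names(seqs)) seqs$desc else rep("", nrow(seqs))
  out <- unlist(lapply(seq_len(nrow(seqs)), function(i) {
    hdr <- if (nzchar(desc[i])) paste(seqs$id[i], desc[i]) else seqs$id[i]
    body <- gsub(sprintf("(.{1,%d})", width), "\\1\n", seqs$seq[i])
    c(paste0(">", hdr), strsplit(body, "\n")[[1]])
  }))
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(path)) return(invisible(txt))
  writeLines(out, path)
  invisible(txt)
}

#' Parse GFF3 gene models
#'
#' Retains only rows of type `gene`; `gene_id` is taken from the `ID`
#' attribute. Coordinates are 1-based inclusive throughout the package.
#'
#' @param input File path or GFF3 text.
#' @return `data.frame(gene_id, seq_id, start, end, strand)`.
#' @export
parse_gff3 <- function(input) {
  lines <- .as_lines(input)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  empty <- data.frame(gene_id = character(), seq_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    stop("GFF3 line ", which(nf < 9)[1], " has fewer than 9 columns")
  }
  keep <- vapply(fields, function(f) f[3] == "gene", logical(1))
  fields <- fields[keep]
  lineno <- which(keep)
  if (length(fields) == 0) return(empty)
  start <- as.integer(vapply(fields, `[`, character(1), 4))
  end <- as.integer(vapply(fields, `[`, character(1), 5))
  strand <- vapply(fields, `[`, character(1), 7)
  attrs <- vapply(fields, `[`, character(1), 9)
  ids <- rep(NA_character_, length(attrs))
  m <- regmatches(attrs, regexpr("(?:^|;)\\s*ID=[^;]+", attrs))
  has_id <- grepl("(?:^|;)\\s*ID=", attrs)
  ids[has_id] <- sub("^.*ID=", "", m)
  if (any(!has_id)) {
    stop("GFF3 gene row at line ", lineno[!has_id][1], " lacks an ID attribute")
  }
  bad <- which(is.na(start) | is.na(end) | start > end | start < 1)
  if (length(bad)) {
    stop("invalid coordinates at GFF3 line ", lineno[bad[1]],
         " (require 1 <= start <= end)")
  }
  if (any(!strand %in% c("+", "-"))) {
    stop("invalid strand at GFF3 line ", lineno[which(!strand %in% c("+", "-"))[1]])
  }
  data.frame(gene_id = ids, seq_id = vapply(fields, `[`, character(1), 1),
             start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Write gene models as GFF3
#' @param genes data frame from [parse_gff3()].
#' @param path Output path or `NULL` for text.
#' @export
write_gff3 <- function(genes, path = NULL) {
  rows <- sprintf("%s\tfamscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  genes$seq_id, genes$start, genes$end, genes$strand,
                  genes$gene_id)
  out <- c("##gff-version 3", rows)
  if (is.null(path)) return(invisible(paste0(paste(out, collapse = "\n"), "\n")))
  writeLines(out, path)
  invisible(NULL)
}

#' Export gene models as BED (0-based half-open)
#' @param genes data frame of gene models (1-based inclusive).
#' @param path Output path or `NULL` for text.
#' @export
write_bed <- function(genes, path = NULL) {
  rows <- sprintf("%s\t%d\t%d\t%s\t0\t%s", genes$seq_id, genes$start - 1L,
                  genes$end, genes$gene_id, genes$strand)
  if (is.null(path)) return(invisible(paste0(paste(rows, collapse = "\n"), "\n")))
  writeLines(rows, path)
  invisible(NULL)
}

#' Default Pfam accession to domain-type map
#'
#' Maps the family's diagnostic Pfam accessions to topology tokens:
#' PF00005 (ABC transporter, nucleotide-binding) and PF01061 (ABC-2 type)
#' to `NBD`, PF00664 (ABC transporter transmembrane region) to `TMD`.
#' Packaged as a TSV so users can extend it.
#'
#' @return `data.frame(accession, domain)`.
#' @export
default_domain_map <- function() {
  read.delim(system.file("extdata", "pfam_domain_map.tsv", package = "famscan"),
             stringsAsFactors = FALSE)
}

#' Parse a HMMER3 domtblout-like domain-hit table
#'
#' Accepts either genuine HMMER3 `--domtblout` geometry (>= 19
#' whitespace-separated columns: target in column 1, query accession in
#' column 5, per-domain i-Evalue in column 13, alignment coordinates in
#' columns 18-19) or a compact five-column form
#' `(protein_id, accession, evalue, ali_start, ali_end)`. Pfam accession
#' version suffixes (`PF00005.27`) are stripped before mapping. Rows whose
#' accession is absent from `accession_map` are dropped (a count is
#' reported via `message`).
#'
#' @param input File path or table text; `#` comment lines are skipped.
#' @param accession_map `data.frame(accession, domain)`; defaults to
#'   [default_domain_map()].
#' @return `data.frame(protein_id, domain_name, evalue, ali_start, ali_end)`
#'   with `domain_name` in `{NBD, TMD}`.
#' @export
parse_domtblout <- function(input, accession_map = default_domain_map()) {
  lines <- .as_lines(input)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  empty <- data.frame(protein_id = character(), domain_name = character(),
                      evalue = numeric(), ali_start = integer(),
                      ali_end = integer(), stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  fields <- strsplit(trimws(lines), "\\s+")
  pick <- function(f, i) {
    nf <- length(f)
    if (nf >= 19) f[c(1, 5, 13, 18, 19)][i]
    else if (nf >= 5) f[1:5][i]
    else stop("domain-table row with ", nf, " fields (need 5 or >= 19)")
  }
  prot <- vapply(fields, pick, character(1), i = 1)
  acc <- sub("\\.\\d+$", "", vapply(fields, pick, character(1), i = 2))
  ev_chr <- vapply(fields, pick, character(1), i = 3)
  ev <- suppressWarnings(as.numeric(ev_chr))
  if (anyNA(ev)) {
    stop("non-numeric E-value '", ev_chr[is.na(ev)][1], "' at line ",
         lineno[is.na(ev)][1])
  }
  a1 <- suppressWarnings(as.integer(vapply(fields, pick, character(1), i = 4)))
  a2 <- suppressWarnings(as.integer(vapply(fields, pick, character(1), i = 5)))
  if (anyNA(a1) || anyNA(a2)) {
    stop("non-numeric alignment coordinate at line ",
         lineno[which(is.na(a1) | is.na(a2))[1]])
  }
  if (any(ev < 0)) stop("negative E-value at line ", lineno[which(ev < 0)[1]])
  if (any(a1 > a2)) {
    stop("ali_start > ali_end at line ", lineno[which(a1 > a2)[1]])
  }
  mapped <- match(acc, accession_map$accession)
  if (anyNA(mapped)) {
    message(sum(is.na(mapped)), " domain-table row(s) with unmapped accession dropped")
  }
  ok <- !is.na(mapped)
  data.frame(protein_id = prot[ok],
             domain_name = accession_map$domain[mapped[ok]],
             evalue = ev[ok], ali_start = a1[ok], ali_end = a2[ok],
             stringsAsFactors = FALSE)
}

#' Read a TSV with a header row into a data frame
#' @param input File path or text.
#' @export
read_tsv_table <- function(input) {
  if (length(input) == 1 && grepl("\n", input)) {
    read.delim(text = input, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    read.delim(input, stringsAsFactors = FALSE, check.names = FALSE)
  }
}

#' Packaged syntenic paralog-pair reference table
#'
#' A transcription of a published 14-pair survey of syntenic Capsicum ABC
#' transporter paralogs (columns: pair, s_sites, n_sites, ka, ks, omega,
#' selection, t_mya), used as the default input for [summarize_pairs()]
#' demonstrations and tests.
#' @return data frame with 14 rows.
#' @export
paralog_pair_fixture <- function() {
  read.delim(system.file("extdata", "syntenic_paralog_pairs.tsv",
                         package = "famscan"), stringsAsFactors = FALSE)
}

#' Packaged cis-element catalog
#'
#' The 23-entry catalog of common plant promoter cis-regulatory elements
#' (PLACE-style names, IUPAC signal sequences, SITE accessions and
#' expression-pattern annotations) that is the default scanning catalog.
#' @return `data.frame(name, signal, site_id, annotation)`, 23 rows.
#' @export
cis_element_catalog <- function() {
  read.delim(system.file("extdata", "cis_element_catalog.tsv",
                         package = "famscan"), stringsAsFactors = FALSE)
}
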