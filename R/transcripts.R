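#' Normalize a nucleotide sequence to clean uppercase RNA
#'
#' Strips every non-letter character (including zero-width separators that
#' survive copy-paste from typeset tables), uppercases, and maps T to U.
#' The result is validated against the A/C/G/U/N alphabet.
#'
#' @param x Character vector of raw sequences.
#' @return Character vector of normalized RNA sequences.
#' @examples
#' clean_sequence("acgt")  # "ACGU"
#' @export
clean_sequence <- function(x) {
  x <- gsub("[^A-Za-z]", "", x)
  x <- chartr("t", "u", toupper(x))
  x <- chartr("T", "U", x)
  for (s in x) base_index(s)
  x
}

#' Read a FASTA file of RNA or DNA sequences
#'
#' Sequences are normalized with [clean_sequence()] (uppercase, T to U).
#' Record order is preserved. Duplicate ids are kept but suffixed
#' (".2", ".3", ...) with a warning.
#'
#' @param path FASTA file path.
#' @return Named character vector of RNA sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  raw <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(raw)))
  if (length(nonempty) == 0L) stop("FASTA file '", path, "' is empty")
  if (!startsWith(trimws(raw[nonempty[1]]), ">"))
    stop("malformed FASTA: line ", nonempty[1], " of '", path,
         "' does not start a header")
  set <- Biostrings::readBStringSet(path)
  seqs <- clean_sequence(as.character(set))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids in '", path, "'; suffixing duplicates")
    ids <- make.unique(ids, sep = ".")
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of RNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::RNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read miRNAs from FASTA, caching the perfect-complement energy
#'
#' @param path FASTA file path.
#' @param model An [energy_model()].
#' @return Data frame with columns `id`, `seq`, `dGm`.
#' @export
read_mirnas <- function(path, model = energy_model()) {
  seqs <- read_fasta(path)
  data.frame(id = names(seqs), seq = unname(seqs),
             dGm = vapply(seqs, perfect_energy, 0, model = model),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Construct a transcript with region annotation
#'
#' A transcript partitions into 5'UTR (positions 1..utr5_end), CDS
#' (utr5_end+1..cds_end) and 3'UTR (cds_end+1..length), all 1-based
#' inclusive. `utr5_end = 0` means no 5'UTR. Missing annotation
#' (`cds_end = NA`) is allowed; such transcripts are scanned but their
#' sites get region `"unknown"`.
#'
#' @param id Transcript identifier.
#' @param seq RNA sequence (normalized with [clean_sequence()]).
#' @param utr5_end 1-based last position of the 5'UTR (0 if none).
#' @param cds_end 1-based last position of the CDS.
#' @param gene Gene symbol (defaults to `id`).
#' @return An object of class `transcript`.
#' @export
transcript <- function(id, seq, utr5_end = NA, cds_end = NA, gene = id) {
  seq <- clean_sequence(seq)
  len <- nchar(seq)
  annotated <- !is.na(utr5_end) && !is.na(cds_end)
  if (annotated) {
    utr5_end <- as.integer(utr5_end); cds_end <- as.integer(cds_end)
    if (utr5_end < 0 || utr5_end >= cds_end || cds_end > len)
      stop("transcript '", id, "': invalid region boundaries (need 0 <= utr5_end < cds_end <= length; got ",
           utr5_end, ", ", cds_end, ", length ", len, ")")
    cds_partial <- (cds_end - utr5_end) %% 3L != 0L
  } else {
    utr5_end <- cds_end <- NA_integer_
    cds_partial <- NA
  }
  structure(list(id = id, gene = gene, seq = seq, length = len,
                 utr5_end = utr5_end, cds_end = cds_end,
                 cds_partial = cds_partial),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("Transcript %s (gene %s), %d nt\n", x$id, x$gene, x$length))
  if (!is.na(x$cds_end))
    cat(sprintf("  5'UTR 1-%d | CDS %d-%d | 3'UTR %d-%d%s\n",
                x$utr5_end, x$utr5_end + 1L, x$cds_end,
                x$cds_end + 1L, x$length,
                if (isTRUE(x$cds_partial)) " (CDS length not a multiple of 3)" else ""))
  else cat("  no region annotation\n")
  invisible(x)
}

#' Region of a transcript position
#'
#' A binding site is assigned the region containing its start position.
#'
#' @param tx A [transcript()].
#' @param position 1-based positions (vectorized).
#' @return Character vector over `"5UTR"`, `"CDS"`, `"3UTR"`, `"unknown"`.
#' @examples
#' tx <- transcript("t", strrep("A", 100), utr5_end = 20, cds_end = 80)
#' region_of(tx, c(20, 21, 81))  # "5UTR" "CDS" "3UTR"
#' @export
region_of <- function(tx, position) {
  stopifnot(inherits(tx, "transcript"))
  position <- as.integer(position)
  if (any(position < 1L | position > tx$length))
    stop("position out of range 1..", tx$length, " for transcript '", tx$id, "'")
  if (is.na(tx$cds_end)) return(rep("unknown", length(position)))
  ifelse(position <= tx$utr5_end, "5UTR",
         ifelse(position <= tx$cds_end, "CDS", "3UTR"))
}

#' Read a region-annotation table
#'
#' Accepts either a TSV with columns `transcript_id`, `utr5_end`,
#' `cds_end` (1-based inclusive last positions), or a GFF3 file carrying
#' `five_prime_UTR` and `CDS` features in transcript coordinates
#' (seqid = transcript id). For GFF3, `utr5_end` is the largest
#' five_prime_UTR end (0 if absent) and `cds_end` the largest CDS end.
#'
#' @param path Annotation file; GFF3 is detected by extension
#'   (`.gff`/`.gff3`) or a `##gff-version` first line.
#' @return Data frame with columns `transcript_id`, `utr5_end`, `cds_end`.
#' @export
read_annotation <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE) ||
    startsWith(first, "##gff-version")
  if (is_gff) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 annotation requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    df <- as.data.frame(gr)
    ids <- unique(as.character(df$seqnames))
    ann <- do.call(rbind, lapply(ids, function(id) {
      sub <- df[df$seqnames == id, ]
      utr <- sub[sub$type == "five_prime_UTR", ]
      cds <- sub[sub$type == "CDS", ]
      if (nrow(cds) == 0L)
        stop("GFF3 annotation for '", id, "' lacks a CDS feature")
      data.frame(transcript_id = id,
                 utr5_end = if (nrow(utr)) max(utr$end) else 0L,
                 cds_end = max(cds$end), stringsAsFactors = FALSE)
    }))
    return(ann)
  }
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "utr5_end", "cds_end")
  if (!all(need %in% names(ann)))
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  ann[need]
}

#' Read transcripts from FASTA plus annotation
#'
#' Joins sequences with region boundaries and validates each transcript.
#' Transcripts absent from the annotation are kept unannotated (their
#' sites will report region `"unknown"`).
#'
#' @param fasta_path Transcript FASTA.
#' @param annotation_path Optional annotation file (see
#'   [read_annotation()]).
#' @param genes Optional named character vector mapping transcript id to
#'   gene symbol.
#' @return Named list of [transcript()] objects, in FASTA order.
#' @export
read_transcripts <- function(fasta_path, annotation_path = NULL, genes = NULL) {
  seqs <- read_fasta(fasta_path)
  ann <- if (!is.null(annotation_path)) read_annotation(annotation_path) else NULL
  if (!is.null(ann)) {
    bad <- setdiff(ann$transcript_id, names(seqs))
    if (length(bad))
      warning("annotation rows without sequence: ", paste(bad, collapse = ", "))
  }
  out <- lapply(names(seqs), function(id) {
    u <- ce <- NA
    if (!is.null(ann) && id %in% ann$transcript_id) {
      row <- ann[match(id, ann$transcript_id), ]
      u <- row$utr5_end; ce <- row$cds_end
    }
    g <- if (!is.null(genes) && id %in% names(genes)) genes[[id]] else id
    transcript(id, seqs[[id]], utr5_end = u, cds_end = ce, gene = g)
  })
  names(out) <- names(seqs)
  out
}

# md5 checksums of the packaged fixture tables (integrity guard)
.fixture_md5 <- c(
  table1.tsv = "e741a1b47b2f7e3660e4bdd490d050a2",
  table2.tsv = "5bf7cc3e60c2a68479a1f83bb543d4fc",
  table3.tsv = "f2aa9ba85be93762d006cc29e5da1e25",
  table4.tsv = "5c15580e03a4cf1fedc71186dd237a19"
)

#' Load the packaged published-table fixtures
#'
#' Four TSV tables transcribed from the published report accompany the
#' package: cluster characteristics of the repeated-site miRNA on 28
#' genes (`table1`), high-complementarity sites with start, region, dG
#' and ratio (`table2`), GCC-repeat binding-site sequences in CDS with
#' encoded peptides (`table3`) and in 5'UTR (`table4`). Sequence fields
#' are printed with mixed T/U; `seq_rna` columns carry the
#' [clean_sequence()]-normalized form.
#'
#' @param check_integrity Verify md5 checksums of the packaged files
#'   (default TRUE).
#' @return Named list of data frames `table1` .. `table4`.
#' @export
load_fixtures <- function(check_integrity = TRUE) {
  dir <- system.file("extdata", package = "xenoscan")
  files <- paste0("table", 1:4, ".tsv")
  paths <- file.path(dir, files)
  if (check_integrity) {
    sums <- tools::md5sum(paths)
    names(sums) <- files
    bad <- files[sums != .fixture_md5[files]]
    if (length(bad))
      stop("packaged fixture integrity check failed for: ",
           paste(bad, collapse = ", "))
  }
  out <- lapply(paths, utils::read.delim, stringsAsFactors = FALSE,
                colClasses = "character")
  names(out) <- paste0("table", 1:4)
  for (col in c("first_start", "last_start", "site_count", "dg_low",
                "dg_high", "ratio_min", "ratio_max"))
    out$table1[[col]] <- as.numeric(out$table1[[col]])
  for (col in c("start", "dg", "ratio", "length_nt", "identical_human", "milk"))
    out$table2[[col]] <- as.numeric(out$table2[[col]])
  out$table3$seq_rna <- clean_sequence(out$table3$sequence)
  out$table4$seq_rna <- clean_sequence(out$table4$sequence)
  out
}
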