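#' Group binding sites into clusters of overlapping/abutting sites
#'
#' Sites on one transcript are merged into maximal groups in which each
#' member is within `gap` nucleotides of the interval covered so far
#' (intervals are `[start, end)` with end = start + length). With the
#' default `gap = 0`, members must overlap or abut, which matches
#' tandem-repeat site runs. Singleton clusters are allowed.
#'
#' @param sites Site table for one transcript (any miRNAs), as from
#'   [scan_sites()].
#' @param gap Maximum tolerated gap between a site and the running
#'   cluster interval, nt (default 0).
#' @return Data frame with one row per cluster: `transcript_id`, `gene`,
#'   `first_start`, `last_start`, `last_end`, `span`
#'   (= last_end - first_start), `n_sites`, `total_site_length`,
#'   `compaction`, `dg_low`, `dg_high` (least/most negative member dG)
#'   plus list columns `members` (row indices into `sites`),
#'   `spacings` (successive start differences) and `site_count`
#'   (named per-miRNA counts).
#' @examples
#' tx <- transcript("t", strrep("A", 200))
#' s <- data.frame(mirna_id = "m", transcript_id = "t", gene = "t",
#'                 start = c(100, 102, 104), length = 20,
#'                 end = c(120, 122, 124), dG = -100, dGm = -110,
#'                 ratio = 91, region = "unknown")
#' cluster_sites(s)$span  # 24
#' @export
cluster_sites <- function(sites, gap = 0) {
  if (nrow(sites) == 0L)
    return(data.frame(transcript_id = character(), gene = character(),
                      first_start = integer(), last_start = integer(),
                      last_end = integer(), span = integer(),
                      n_sites = integer(), total_site_length = integer(),
                      compaction = numeric(), dg_low = numeric(),
                      dg_high = numeric()))
  if (length(unique(sites$transcript_id)) > 1L)
    stop("cluster_sites() operates on sites of a single transcript")
  o <- order(sites$start, sites$end)
  s <- sites[o, ]
  cl <- integer(nrow(s)); cl[1] <- 1L
  reach <- s$end[1]
  for (i in seq_len(nrow(s))[-1]) {
    if (s$start[i] - reach <= gap) cl[i] <- cl[i - 1L]
    else cl[i] <- cl[i - 1L] + 1L
    reach <- max(reach, s$end[i])
  }
  rows <- lapply(split(seq_len(nrow(s)), cl), function(ii) {
    m <- s[ii, ]
    span <- max(m$end) - min(m$start)
    tot <- sum(m$length)
    data.frame(transcript_id = m$transcript_id[1], gene = m$gene[1],
               first_start = min(m$start), last_start = max(m$start),
               last_end = max(m$end), span = span,
               n_sites = nrow(m), total_site_length = tot,
               compaction = compaction(tot, span),
               dg_low = max(m$dG), dg_high = min(m$dG),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  idx <- split(o, cl)
  out$members <- I(unname(idx))
  out$spacings <- I(unname(lapply(split(s$start, cl), function(st) diff(st))))
  out$site_count <- I(unname(lapply(split(s$mirna_id, cl),
                                    function(id) table(id))))
  rownames(out) <- NULL
  out
}

#' Degree of compaction of a site cluster
#'
#' Total summed site length divided by the cluster span; a measure of
#' how densely the repeated sites overlap (1 for a singleton, ~10 for a
#' heavily overlapping tandem run). Stored unrounded; reports round to
#' the nearest integer.
#'
#' @param total_site_length Sum of member site lengths, nt.
#' @param span Cluster span (last end - first start), nt.
#' @return Real-valued quotient.
#' @examples
#' compaction(281, 28)  # 10.04
#' @export
compaction <- function(total_site_length, span) {
  if (any(span <= 0)) stop("cluster span must be positive")
  total_site_length / span
}

#' Successive start spacings within a cluster
#'
#' Differences between consecutive site starts in 5'->3' order (e.g. a
#' run of sites "through three nucleotides" yields spacings of 3).
#'
#' @param starts Integer vector of member site starts, or a one-row
#'   cluster data frame from [cluster_sites()].
#' @return Integer vector of successive differences (empty for a
#'   singleton).
#' @export
start_spacings <- function(starts) {
  if (is.data.frame(starts)) {
    stopifnot(nrow(starts) == 1L, !is.null(starts$spacings))
    return(starts$spacings[[1]])
  }
  diff(sort(as.integer(starts)))
}

gcc_starts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n < 3L) return(integer())
  which(ch[seq_len(n - 2L)] == "G" &
        ch[seq_len(n - 2L) + 1L] == "C" &
        ch[seq_len(n - 2L) + 2L] == "C")
}

#' Maximal exact GCC-repeat run in a sequence
#'
#' Finds the largest k such that (GCC)^k occurs as a contiguous
#' substring, taking the leftmost occurrence on ties. k = 0 (no GCC
#' unit) is allowed.
#'
#' @param seq RNA sequence text.
#' @return Object of class `repeat_run`: list with `start` (1-based, NA
#'   when k = 0), `k`, `run_length` (= 3k), `length_class` (see
#'   [classify_run()]) and `mismatched_triplets` (0 for exact runs).
#' @examples
#' find_gcc_run("GCCGCC")$run_length  # 6
#' find_gcc_run("GCGCGC")$k           # 0
#' @export
find_gcc_run <- function(seq) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("sequence must be non-empty")
  st <- gcc_starts(seq)
  if (length(st) == 0L) return(repeat_run(NA_integer_, 0L, 0L))
  # chain GCC units 3 nt apart, right to left
  kmap <- integer(nchar(seq) + 3L)
  for (p in rev(st)) kmap[p] <- 1L + if (p + 3L <= nchar(seq)) kmap[p + 3L] else 0L
  k <- max(kmap[st])
  start <- st[which(kmap[st] == k)[1]]
  repeat_run(start, k, 0L)
}

repeat_run <- function(start, k, mismatched) {
  structure(list(start = start, k = as.integer(k),
                 run_length = 3L * as.integer(k),
                 length_class = classify_run(3L * as.integer(k)),
                 mismatched_triplets = as.integer(mismatched)),
            class = "repeat_run")
}

#' @export
print.repeat_run <- function(x, ...) {
  if (x$k == 0L) cat("No GCC repeat run\n")
  else cat(sprintf("GCC run: start %d, %d units (%d nt, class %s)%s\n",
                   x$start, x$k, x$run_length, x$length_class,
                   if (x$mismatched_triplets)
                     sprintf(", %d mismatched triplet(s)", x$mismatched_triplets)
                   else ""))
  invisible(x)
}

#' Maximal GCC-phase run tolerating interrupting triplets
#'
#' Like [find_gcc_run()] but allows up to `max_bad_triplets` non-GCC
#' triplets inside the run (never at either end). Useful for
#' interrupted repeats in printed site sequences. With
#' `max_bad_triplets = 0` this reduces to the exact detector.
#'
#' @param seq RNA sequence text.
#' @param max_bad_triplets Maximum interior non-GCC triplets allowed.
#' @return A `repeat_run`; `run_length` counts all triplets (3 x total),
#'   `mismatched_triplets` the tolerated interruptions.
#' @export
find_tolerant_run <- function(seq, max_bad_triplets = 0) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("sequence must be non-empty")
  stopifnot(max_bad_triplets >= 0)
  st <- gcc_starts(seq)
  if (length(st) == 0L) return(repeat_run(NA_integer_, 0L, 0L))
  best <- c(k = 0L, start = NA_integer_, bad = 0L)
  for (p in st) {
    ends <- st[st >= p & (st - p) %% 3L == 0L]
    for (q in ends) {
      ntrip <- (q - p) %/% 3L + 1L
      ingcc <- sum((st - p) %% 3L == 0L & st >= p & st <= q)
      bad <- ntrip - ingcc
      if (bad <= max_bad_triplets && ntrip > best["k"]) {
        best <- c(k = ntrip, start = p, bad = bad)
        }
    }
  }
  repeat_run(best[["start"]], best[["k"]], best[["bad"]])
}

#' Classify a GCC run by its printed length class
#'
#' Run lengths 18, 21 and 24 nt form their own classes; 27 nt and longer
#' are pooled as `"27plus"`; anything below 18 nt is `"none"`.
#'
#' @param run_length Run length in nt (must be a multiple of 3).
#' @return One of `"18"`, `"21"`, `"24"`, `"27plus"`, `"none"`.
#' @export
classify_run <- function(run_length) {
  run_length <- as.integer(run_length)
  if (any(run_length %% 3L != 0L))
    stop("run length must be a multiple of 3, got ", run_length)
  out <- character(length(run_length))
  out[run_length < 18L] <- "none"
  out[run_length == 18L] <- "18"
  out[run_length == 21L] <- "21"
  out[run_length == 24L] <- "24"
  out[run_length >= 27L] <- "27plus"
  out
}

#' Homopolymer peptide encoded by a CDS GCC run
#'
#' A (GCC)^k run inside a coding sequence encodes a homopolymer whose
#' residue depends on the reading-frame offset of the run start relative
#' to the CDS start: offset 0 reads GCC codons (polyA, alanine), offset
#' 1 reads CCG (polyP, proline), offset 2 reads CGC (polyR, arginine).
#'
#' @param run A `repeat_run` (or integer k).
#' @param frame_offset `(run start - CDS start) mod 3`: 0, 1 or 2.
#' @param region Region containing the run; must be `"CDS"`.
#' @return Character string of length k over A/P/R.
#' @examples
#' translate_repeat(7, frame_offset = 2)  # "RRRRRRR"
#' @export
translate_repeat <- function(run, frame_offset, region = "CDS") {
  if (!identical(region, "CDS"))
    stop("GCC runs encode peptides only inside a CDS (got region '",
         region, "')")
  k <- if (inherits(run, "repeat_run")) run$k else as.integer(run)
  stopifnot(k >= 1L, frame_offset %in% 0:2)
  aa <- c("A", "P", "R")[frame_offset + 1L]
  strrep(aa, k)
}

#' Position frequency matrix of aligned site sequences
#'
#' Numeric counterpart of a sequence logo: per-position base frequencies
#' of a set of equal-length sequences. Columns are normalized over the
#' A/C/G/U counts observed at that position, so each column sums to 1.
#'
#' @param seqs Character vector of equal-length RNA sequences.
#' @return 4 x L numeric matrix, rows A, C, G, U.
#' @export
position_frequency_matrix <- function(seqs) {
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences must be aligned to equal length (got lengths ",
         paste(unique(lens), collapse = ", "), ")")
  mat <- do.call(rbind, strsplit(seqs, ""))
  bases <- c("A", "C", "G", "U")
  counts <- vapply(seq_len(ncol(mat)), function(j)
    tabulate(match(mat[, j], bases), 4L), integer(4))
  rownames(counts) <- bases
  sweep(counts, 2, colSums(counts), "/")
}
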