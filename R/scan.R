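#' Scan one transcript for binding sites of one miRNA
#'
#' Slides the miRNA along the transcript one nucleotide at a time,
#' starting from the first nucleotide, scoring every window over the
#' full miRNA length with [duplex_energy()]. Windows whose unrounded
#' complementarity ratio reaches `threshold` are reported as binding
#' sites, each localized to the region containing its start. Windows
#' with more than `max_n_frac` ambiguous (N) bases are skipped.
#'
#' @param mirna_id miRNA identifier.
#' @param mirna_seq miRNA sequence, 5'->3' RNA text.
#' @param tx A [transcript()].
#' @param model An [energy_model()].
#' @param threshold Minimum complementarity ratio, percent, in (0, 100].
#' @param max_n_frac Maximum tolerated fraction of N per window.
#' @return Data frame of binding sites with columns `mirna_id`,
#'   `transcript_id`, `gene`, `start` (1-based), `length`, `end`
#'   (= start + length), `dG`, `dGm`, `ratio` (unrounded), `region`;
#'   sorted by start. `end` follows the span convention
#'   end = start + length used by the cluster metrics.
#' @examples
#' tx <- transcript("t1", "AAAAGCAUAAAA")
#' scan_sites("m", "AUGC", tx, threshold = 90)
#' @export
scan_sites <- function(mirna_id, mirna_seq, tx, model = energy_model(),
                       threshold = 90, max_n_frac = 0.1) {
  stopifnot(inherits(tx, "transcript"))
  if (threshold <= 0 || threshold > 100)
    stop("threshold must be in (0, 100], got ", threshold)
  mirna_seq <- clean_sequence(mirna_seq)
  lm <- nchar(mirna_seq)
  if (lm > tx$length) {
    warning("miRNA '", mirna_id, "' (", lm, " nt) longer than transcript '",
            tx$id, "' (", tx$length, " nt); no windows to scan")
    return(empty_sites())
  }
  txi <- base_index(tx$seq, "transcript")
  mi <- base_index(mirna_seq, "miRNA")
  w <- tx$length - lm + 1L
  # additive energy per window, vectorized over starts for each miRNA
  # position; accumulation follows miRNA order (site position lm+1-k pairs
  # miRNA position k) so perfect windows reproduce dGm's sum exactly
  e <- numeric(w)
  starts <- 0:(w - 1L)
  comp <- c(4L, 3L, 2L, 1L, 5L)
  dgm_mag <- 0  # accumulated with the same arithmetic as e, so a perfect
                # window gives ratio exactly 100
  for (k in seq_len(lm)) {
    e <- e + model$energy[cbind(txi[starts + lm + 1L - k], mi[k])]
    dgm_mag <- dgm_mag + model$energy[mi[k], comp[mi[k]]]
  }
  dGm <- -dgm_mag
  ratio <- 100 * (e / dgm_mag)
  # skip N-heavy windows
  is_n <- as.integer(txi == 5L)
  ncum <- c(0L, cumsum(is_n))
  nfrac <- (ncum[starts + lm + 1L] - ncum[starts + 1L]) / lm
  keep <- which(ratio >= threshold - 1e-9 & nfrac <= max_n_frac)
  if (length(keep) == 0L) return(empty_sites())
  data.frame(
    mirna_id = mirna_id, transcript_id = tx$id, gene = tx$gene,
    start = keep, length = lm, end = keep + lm,
    dG = -e[keep], dGm = dGm, ratio = ratio[keep],
    region = region_of(tx, keep),
    stringsAsFactors = FALSE
  )
}

empty_sites <- function() {
  data.frame(mirna_id = character(), transcript_id = character(),
             gene = character(), start = integer(), length = integer(),
             end = integer(), dG = numeric(), dGm = numeric(),
             ratio = numeric(), region = character(),
             stringsAsFactors = FALSE)
}

#' Scan all miRNAs against all transcripts
#'
#' @param mirnas Data frame with columns `id`, `seq` (see
#'   [read_mirnas()]).
#' @param transcripts List of [transcript()] objects.
#' @param model An [energy_model()].
#' @param threshold Minimum complementarity ratio, percent.
#' @param verbose Log per-transcript site counts.
#' @return Site table as in [scan_sites()], ordered deterministically by
#'   transcript id, start, miRNA id.
#' @export
scan_all <- function(mirnas, transcripts, model = energy_model(),
                     threshold = 90, verbose = FALSE) {
  stopifnot(is.data.frame(mirnas), all(c("id", "seq") %in% names(mirnas)))
  pieces <- list()
  for (tx in transcripts) {
    for (k in seq_len(nrow(mirnas))) {
      s <- withCallingHandlers(
        scan_sites(mirnas$id[k], mirnas$seq[k], tx, model, threshold),
        warning = function(w) {
          if (verbose) message(conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      if (nrow(s)) pieces[[length(pieces) + 1L]] <- s
    }
    if (verbose)
      message("scanned ", tx$id, ": ",
              sum(vapply(pieces, function(p) sum(p$transcript_id == tx$id), 0L)),
              " site(s)")
  }
  out <- if (length(pieces)) do.call(rbind, pieces) else empty_sites()
  out[order(out$transcript_id, out$start, out$mirna_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Resolve overlapping sites of different miRNAs
#'
#' When binding sites of two different miRNAs partly coincide on a
#' transcript, the site with the greater free binding energy (larger
#' |dG|) is preferred. The rule is applied transitively over overlap
#' chains by iteratively removing the weakest site that overlaps a
#' different-miRNA site. Overlapping sites of the *same* miRNA (tandem
#' repeats) are always kept. Ties on |dG| keep the 5'-most start, then
#' the lexicographically smallest miRNA id, so the result is a pure
#' function of the input set.
#'
#' @param sites Site table for one transcript (as from [scan_sites()]).
#' @return Filtered site table, original ordering preserved.
#' @export
resolve_overlaps <- function(sites) {
  if (nrow(sites) < 2L) return(sites)
  if (length(unique(sites$transcript_id)) > 1L)
    stop("resolve_overlaps() operates on sites of a single transcript")
  keep <- rep(TRUE, nrow(sites))
  repeat {
    idx <- which(keep)
    if (length(idx) < 2L) break
    s <- sites[idx, ]
    # sites involved in at least one cross-miRNA overlap
    involved <- rep(FALSE, length(idx))
    for (a in seq_along(idx)) {
      ov <- s$start[a] < s$end & s$start < s$end[a] & s$mirna_id != s$mirna_id[a]
      if (any(ov)) involved[a] <- TRUE
    }
    if (!any(involved)) break
    cand <- which(involved)
    # weakest = smallest |dG|; ties: larger start goes, then larger miRNA id
    o <- order(abs(s$dG[cand]), -s$start[cand],
               -xtfrm(s$mirna_id[cand]))
    keep[idx[cand[o[1]]]] <- FALSE
  }
  sites[keep, , drop = FALSE]
}
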