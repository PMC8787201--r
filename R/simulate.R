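#' Reverse complement of an RNA sequence
#'
#' @param x RNA sequence text.
#' @return The canonical reverse complement, 5'->3'.
#' @export
rna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))
}

# evaluate code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# derive an independent stream seed from (seed, key), < 2^31
sub_seed <- function(seed, key) {
  as.integer((as.numeric(seed) %% 44488 * 48271 + key * 16807) %% 2147483647 + 1)
}

#' Generate a random background transcript
#'
#' Bases are i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(U) = (1-gc)/2.
#' Region boundaries follow the configured geometry: the 5'UTR covers
#' the first `utr5_frac` of the transcript and the CDS the next
#' `cds_frac` (CDS length snapped down to a multiple of 3).
#'
#' @param length Transcript length, nt (>= 50).
#' @param gc_fraction GC fraction in (0, 1), exclusive.
#' @param seed Integer seed; identical arguments give identical output.
#' @param id,gene Identifiers.
#' @param utr5_frac,cds_frac Region geometry as fractions of length.
#' @return A [transcript()].
#' @export
random_transcript <- function(length, gc_fraction = 0.5, seed = 1,
                              id = "tx1", gene = id,
                              utr5_frac = 0.15, cds_frac = 0.55) {
  if (length < 50) stop("transcript length must be >= 50")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must be strictly inside (0, 1)")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, U = (1 - gc_fraction) / 2)
  seq <- with_seed(seed, paste(
    sample(names(p), length, replace = TRUE, prob = p), collapse = ""))
  utr5_end <- floor(length * utr5_frac)
  cds_len <- (floor(length * cds_frac) %/% 3L) * 3L
  tx <- transcript(id, seq, utr5_end = utr5_end,
                   cds_end = utr5_end + cds_len, gene = gene)
  attr(tx, "planted") <- data.frame(start = integer(), end = integer())
  tx
}

# register a planted interval [start, end) with a flank guard; error on clash
reserve_interval <- function(tx, start, end, guard = 3L, what = "feature") {
  if (start < 1L || end - 1L > tx$length)
    stop("planted ", what, " [", start, ", ", end, ") falls outside transcript '",
         tx$id, "'")
  occ <- attr(tx, "planted")
  if (is.null(occ)) occ <- data.frame(start = integer(), end = integer())
  clash <- occ$start < end + guard & start - guard < occ$end
  if (any(clash))
    stop("placement error: ", what, " [", start, ", ", end,
         ") overlaps a previously planted feature on '", tx$id, "'")
  attr(tx, "planted") <- rbind(occ, data.frame(start = start, end = end))
  tx
}

write_at <- function(seq, start, text) {
  substr(seq, start, start + nchar(text) - 1L) <- text
  seq
}

truth_row <- function(tx, feature, mirna_id, start, length, ratio,
                      class = NA, peptide = NA) {
  data.frame(transcript_id = tx$id, feature = feature, mirna_id = mirna_id,
             start = as.integer(start), length = as.integer(length),
             expected_ratio = ratio,
             expected_region = region_of(tx, start),
             expected_class = class, expected_peptide = peptide,
             stringsAsFactors = FALSE)
}

#' Plant one miRNA binding site in a transcript
#'
#' Writes the canonical reverse complement of the miRNA at `start`, then
#' substitutes `n_wobbles` positions on the mRNA side with the wobble
#' partner (C -> U opposite a miRNA G, U -> C opposite a miRNA A),
#' chosen without replacement under `seed`. The returned truth record
#' carries the analytic expected complementarity ratio
#' 100 * (|dGm| - sum of per-substitution losses) / |dGm|.
#'
#' @param tx A [transcript()] from [random_transcript()].
#' @param mirna_seq miRNA sequence, 5'->3'.
#' @param start 1-based start of the site window.
#' @param n_wobbles Number of wobble substitutions (0 to miRNA length).
#' @param seed Integer seed for the substitution choice.
#' @param mirna_id Identifier recorded in the truth table.
#' @param model An [energy_model()].
#' @return List with the modified `tx` and a one-row `truth` data frame.
#' @export
plant_site <- function(tx, mirna_seq, start, n_wobbles = 0, seed = 1,
                       mirna_id = "mir", model = energy_model()) {
  mirna_seq <- clean_sequence(mirna_seq)
  lm <- nchar(mirna_seq)
  stopifnot(n_wobbles <= lm)
  tx <- reserve_interval(tx, start, start + lm, what = "site")
  site <- rna_revcomp(mirna_seq)
  ch <- strsplit(site, "")[[1]]
  # site position i faces miRNA base complement(ch[i]); wobble-eligible where
  # the site base is C (miRNA G -> G.U wobble) or U (miRNA A -> A.C wobble)
  eligible <- which(ch %in% c("C", "U"))
  if (n_wobbles > length(eligible))
    stop("only ", length(eligible), " wobble-eligible positions for this miRNA")
  loss <- 0
  if (n_wobbles > 0) {
    pos <- with_seed(seed, sample(eligible, n_wobbles))
    gc_loss <- model$energy["G", "C"] - model$energy["G", "U"]
    au_loss <- model$energy["A", "U"] - model$energy["A", "C"]
    for (p in pos) {
      loss <- loss + if (ch[p] == "C") gc_loss else au_loss
      ch[p] <- if (ch[p] == "C") "U" else "C"
    }
  }
  site <- paste(ch, collapse = "")
  tx$seq <- write_at(tx$seq, start, site)
  dgm <- abs(perfect_energy(mirna_seq, model))
  list(tx = tx,
       truth = truth_row(tx, "site", mirna_id, start, lm,
                         100 * (dgm - loss) / dgm))
}

#' Plant a tandem run of overlapping sites of one miRNA
#'
#' Writes `n` exact-complement sites at starts `start`, `start +
#' spacing`, ... . Overlapping writes are only self-consistent when the
#' miRNA's reverse complement is periodic with period `spacing`
#' (otherwise the overlapped letters would have to take two values);
#' inconsistent requests are refused, naming the first conflicting
#' position. Flanking guard bases break the periodicity so the scan
#' recovers exactly the planted starts at ratio 100.
#'
#' @inheritParams plant_site
#' @param n Number of tandem copies (>= 2).
#' @param spacing Start-to-start offset, nt (>= 1).
#' @return List with modified `tx` and an `n`-row `truth` data frame.
#' @export
plant_tandem_sites <- function(tx, mirna_seq, start, n, spacing,
                               mirna_id = "mir", model = energy_model()) {
  stopifnot(n >= 2, spacing >= 1)
  mirna_seq <- clean_sequence(mirna_seq)
  lm <- nchar(mirna_seq)
  rc <- strsplit(rna_revcomp(mirna_seq), "")[[1]]
  if (spacing < lm) {
    mism <- which(rc[seq_len(lm - spacing)] != rc[seq_len(lm - spacing) + spacing])
    if (length(mism))
      stop("placement error: overlapped tandem writes conflict at site position ",
           mism[1], " (reverse complement is not periodic with period ",
           spacing, ")")
  }
  total <- lm + spacing * (n - 1L)
  tx <- reserve_interval(tx, start, start + total, what = "tandem site run")
  stretch <- substr(strrep(paste(rc[seq_len(min(spacing, lm))], collapse = ""),
                           ceiling(total / spacing)), 1L, total)
  if (spacing >= lm)
    stretch <- paste(vapply(seq_len(n) - 1L, function(t)
      paste(rc, collapse = ""), ""), collapse = strrep("A", spacing - lm))
  tx$seq <- write_at(tx$seq, start, stretch)
  # 3-nt guard flanks: replace the periodic continuation with bases that
  # form no bond with the miRNA base that would face them, so windows
  # hanging over the run edge lose whole pairs and fall below threshold
  anti <- function(b) chartr("ACGU", "CAUG", b)  # zero-energy replacement
  per <- function(pos) {                         # continuation of the pattern
    idx <- ((pos - start) %% spacing) + 1L
    if (idx <= lm) rc[idx] else "A"              # gap filler when spacing > lm
  }
  for (d in 1:3) {
    if (start - d >= 1L)
      tx$seq <- write_at(tx$seq, start - d, anti(per(start - d)))
    if (start + total - 1L + d <= tx$length)
      tx$seq <- write_at(tx$seq, start + total - 1L + d,
                         anti(per(start + total - 1L + d)))
  }
  truth <- do.call(rbind, lapply(seq_len(n) - 1L, function(t)
    truth_row(tx, "site", mirna_id, start + t * spacing, lm, 100)))
  list(tx = tx, truth = truth)
}

#' Plant a GCC trinucleotide repeat cluster
#'
#' Writes (GCC)^k at a position inside the requested region. For CDS
#' placements the start is chosen with the requested reading-frame
#' offset relative to the CDS start, so the encoded homopolymer (polyA,
#' polyP or polyR) is known by construction. Guard bases flanking the
#' run ensure the detector reports exactly k units.
#'
#' @inheritParams plant_site
#' @param k_units Number of GCC units (6 to 16).
#' @param region `"5UTR"` or `"CDS"`.
#' @param frame_offset For CDS: (start - CDS start) mod 3, in 0:2.
#' @param start Optional explicit start; `NULL` picks a random admissible
#'   position under `seed`.
#' @return List with modified `tx` and a one-row `truth` data frame.
#' @export
plant_gcc_cluster <- function(tx, k_units, region = c("5UTR", "CDS"),
                              frame_offset = 0, seed = 1, start = NULL) {
  region <- match.arg(region)
  stopifnot(k_units >= 6, k_units <= 16, frame_offset %in% 0:2)
  if (is.na(tx$cds_end)) stop("transcript '", tx$id, "' lacks region annotation")
  run_len <- 3L * k_units
  lo <- if (region == "5UTR") 1L else tx$utr5_end + 1L
  hi <- if (region == "5UTR") tx$utr5_end else tx$cds_end
  # 3-nt guards on both sides must stay inside the region
  lo <- lo + 3L
  hi_start <- hi - run_len + 1L - 3L
  if (hi_start < lo)
    stop("placement error: region ", region, " of '", tx$id,
         "' too short for a ", run_len, "-nt run")
  if (region == "CDS") {
    cds_start <- tx$utr5_end + 1L
    first <- cds_start + frame_offset
    while (first < lo) first <- first + 3L
    if (first > hi_start)
      stop("placement error: region CDS of '", tx$id,
           "' too short for a ", run_len, "-nt run")
    admissible <- seq(first, hi_start, by = 3L)
  } else admissible <- seq.int(lo, hi_start)
  if (is.null(start)) {
    occ <- attr(tx, "planted")
    free <- admissible[vapply(admissible, function(s)
      !any(occ$start < s + run_len + 6L & s - 6L < occ$end), TRUE)]
    if (length(free) == 0L)
      stop("placement error: no free position for the run in ", region,
           " of '", tx$id, "'")
    start <- with_seed(seed, free[sample.int(length(free), 1L)])
  }
  tx <- reserve_interval(tx, start, start + run_len, what = "GCC run")
  tx$seq <- write_at(tx$seq, start - 3L, paste0("AAU", strrep("GCC", k_units), "UAA"))
  peptide <- if (region == "CDS")
    translate_repeat(k_units, frame_offset, "CDS") else NA
  list(tx = tx,
       truth = truth_row(tx, "repeat", NA, start, run_len, NA,
                         class = classify_run(run_len), peptide = peptide))
}

#' Simulation configuration
#'
#' Bundles the generator parameters: the seed, transcript geometry and
#' the planted-feature specifications. Feature specs are data frames:
#' `site_specs` (columns `tx`, `mirna`, `n_wobbles`), `tandem_specs`
#' (`tx`, `mirna`, `n`, `spacing`) and `repeat_specs` (`tx`, `k`,
#' `region`, `frame_offset`). `tx` is the transcript index, `mirna` the
#' miRNA index. Identical configurations with identical seeds produce
#' byte-identical studies.
#'
#' @param seed Master integer seed.
#' @param n_transcripts Number of background transcripts.
#' @param length_range Min/max transcript length, nt.
#' @param gc_fraction Background GC fraction in (0, 1).
#' @param utr5_frac,cds_frac Region geometry.
#' @param mirnas Data frame with columns `id`, `seq`, or `NULL` for none.
#' @param site_specs,tandem_specs,repeat_specs Planted features (may be
#'   `NULL`).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 42, n_transcripts = 20,
                              length_range = c(1500, 3000),
                              gc_fraction = 0.5,
                              utr5_frac = 0.15, cds_frac = 0.55,
                              mirnas = NULL, site_specs = NULL,
                              tandem_specs = NULL, repeat_specs = NULL) {
  stopifnot(n_transcripts >= 0, length_range[1] >= 50,
            length_range[2] >= length_range[1],
            gc_fraction > 0, gc_fraction < 1)
  for (spec in list(site_specs, tandem_specs, repeat_specs))
    if (!is.null(spec) && nrow(spec) && any(spec$tx > n_transcripts))
      stop("feature spec references a transcript index beyond n_transcripts")
  structure(list(seed = as.integer(seed), n_transcripts = n_transcripts,
                 length_range = length_range, gc_fraction = gc_fraction,
                 utr5_frac = utr5_frac, cds_frac = cds_frac,
                 mirnas = mirnas, site_specs = site_specs,
                 tandem_specs = tandem_specs, repeat_specs = repeat_specs),
            class = "simulation_config")
}

#' Demonstration study configuration
#'
#' Twenty transcripts, five miRNAs and thirty planted features: fifteen
#' single sites with 0-2 wobbles, five tandem site runs (spacing 2 and
#' 3, mirroring sites located "through" one to three nucleotides), and
#' ten GCC repeat clusters (five in 5'UTR, five in CDS across all three
#' reading-frame offsets). Every feature is recoverable by the pipeline
#' at a 90% ratio threshold.
#'
#' @param seed Master seed (default 42).
#' @return A [simulation_config()].
#' @export
demo_config <- function(seed = 42) {
  mirnas <- data.frame(
    id = paste0("syn-mir-", 1:5),
    seq = c(random_mirna(22, sub_seed(seed, 1)),
            random_mirna(22, sub_seed(seed, 2)),
            random_mirna(24, sub_seed(seed, 3)),
            strrep("UG", 9),     # period-2 reverse complement, spacing-2 tandems
            strrep("UGG", 7)),   # period-3 reverse complement, spacing-3 tandems
    stringsAsFactors = FALSE)
  simulation_config(
    seed = seed,
    mirnas = mirnas,
    site_specs = data.frame(tx = 1:15, mirna = rep(1:3, 5),
                            n_wobbles = rep(0:2, each = 5)),
    tandem_specs = data.frame(tx = 16:20,
                              mirna = c(4, 5, 4, 5, 4),
                              n = c(14, 5, 8, 4, 6),
                              spacing = c(2, 3, 2, 3, 2)),
    repeat_specs = data.frame(tx = c(1:5, 6:10),
                              k = c(6, 7, 8, 9, 10, 6, 7, 8, 6, 7),
                              region = rep(c("5UTR", "CDS"), each = 5),
                              frame_offset = c(rep(0, 5), 0, 1, 2, 0, 1))
  )
}

random_mirna <- function(len, seed) {
  with_seed(seed, paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
                        collapse = ""))
}

#' Generate a complete synthetic study
#'
#' Builds the configured miRNAs and background transcripts, plants every
#' specified feature, and (optionally) writes `transcripts.fasta`,
#' `mirnas.fasta`, `annotation.tsv` and `truth.tsv` to `out_dir`. All
#' randomness derives from per-transcript streams seeded by
#' (config seed, transcript index), so adding a feature to one
#' transcript never changes another.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return Invisibly, a list with `mirnas` (data frame), `transcripts`
#'   (list of [transcript()]), `truth` (data frame) and `paths` (named
#'   character vector when `out_dir` is given).
#' @export
generate_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  lens <- with_seed(sub_seed(config$seed, 0),
                    sample(config$length_range[1]:config$length_range[2],
                           config$n_transcripts, replace = TRUE))
  txs <- lapply(seq_len(config$n_transcripts), function(i)
    random_transcript(lens[i], config$gc_fraction,
                      seed = sub_seed(config$seed, 100 + i),
                      id = sprintf("tx%02d", i),
                      utr5_frac = config$utr5_frac, cds_frac = config$cds_frac))
  names(txs) <- vapply(txs, `[[`, "", "id")
  truth <- list()
  counter <- integer(config$n_transcripts)  # per-transcript draw counter
  next_seed <- function(i) {
    counter[i] <<- counter[i] + 1L
    sub_seed(config$seed, i * 1000L + counter[i])
  }
  place_randomly <- function(i, need, plant_fun) {
    # rejection-sample a start from the transcript's own stream
    for (try in 1:200) {
      s <- with_seed(next_seed(i),
                     sample.int(txs[[i]]$length - need - 6L, 1L) + 3L)
      res <- tryCatch(plant_fun(s), error = function(e) e)
      if (!inherits(res, "error")) return(res)
      if (!grepl("placement error", conditionMessage(res))) stop(res)
    }
    stop("could not place a ", need, "-nt feature on ", txs[[i]]$id,
         " after 200 attempts (seed ", config$seed, ")")
  }
  specs <- config$repeat_specs  # repeats first: they have region constraints
  if (!is.null(specs)) for (r in seq_len(nrow(specs))) {
    i <- specs$tx[r]
    res <- plant_gcc_cluster(txs[[i]], specs$k[r], specs$region[r],
                             specs$frame_offset[r], seed = next_seed(i))
    txs[[i]] <- res$tx; truth[[length(truth) + 1L]] <- res$truth
  }
  specs <- config$site_specs
  if (!is.null(specs)) for (r in seq_len(nrow(specs))) {
    i <- specs$tx[r]
    m <- config$mirnas[specs$mirna[r], ]
    res <- place_randomly(i, nchar(m$seq), function(s)
      plant_site(txs[[i]], m$seq, s, specs$n_wobbles[r],
                 seed = next_seed(i), mirna_id = m$id))
    txs[[i]] <- res$tx; truth[[length(truth) + 1L]] <- res$truth
  }
  specs <- config$tandem_specs
  if (!is.null(specs)) for (r in seq_len(nrow(specs))) {
    i <- specs$tx[r]
    m <- config$mirnas[specs$mirna[r], ]
    need <- nchar(m$seq) + specs$spacing[r] * (specs$n[r] - 1L)
    res <- place_randomly(i, need, function(s)
      plant_tandem_sites(txs[[i]], m$seq, s, specs$n[r], specs$spacing[r],
                         mirna_id = m$id))
    txs[[i]] <- res$tx; truth[[length(truth) + 1L]] <- res$truth
  }
  truth <- if (length(truth)) do.call(rbind, truth)
           else truth_template()
  out <- list(mirnas = config$mirnas, transcripts = txs, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(transcripts = file.path(out_dir, "transcripts.fasta"),
               mirnas = file.path(out_dir, "mirnas.fasta"),
               annotation = file.path(out_dir, "annotation.tsv"),
               truth = file.path(out_dir, "truth.tsv"))
    seqs <- vapply(txs, `[[`, "", "seq")
    if (length(seqs)) write_fasta(seqs, paths["transcripts"])
    else writeLines(character(), paths["transcripts"])
    if (!is.null(config$mirnas) && nrow(config$mirnas)) {
      mseq <- config$mirnas$seq
      names(mseq) <- config$mirnas$id
      write_fasta(mseq, paths["mirnas"])
    } else writeLines(character(), paths["mirnas"])
    ann <- data.frame(
      transcript_id = names(txs),
      utr5_end = vapply(txs, `[[`, 0L, "utr5_end"),
      cds_end = vapply(txs, `[[`, 0L, "cds_end"))
    utils::write.table(ann, paths["annotation"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  invisible(out)
}

truth_template <- function() {
  data.frame(transcript_id = character(), feature = character(),
             mirna_id = character(), start = integer(), length = integer(),
             expected_ratio = numeric(), expected_region = character(),
             expected_class = character(), expected_peptide = character(),
             stringsAsFactors = FALSE)
}
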