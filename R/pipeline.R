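#' Pipeline configuration
#'
#' Validates and bundles the end-to-end scan parameters. Rounding
#' happens only at the report layer (dG and ratio to integers,
#' compaction to the nearest integer); all filtering uses unrounded
#' values.
#'
#' @param mirna_fasta,transcript_fasta Input FASTA paths.
#' @param annotation Region-annotation path (TSV or GFF3), or `NULL`.
#' @param out_dir Output directory for the report bundle.
#' @param threshold Complementarity-ratio threshold, percent, (0, 100].
#' @param overlap_resolution Drop the weaker of partly coinciding sites
#'   of different miRNAs (default FALSE, matching the published tables,
#'   which report both members of overlapping cross-miRNA pairs).
#' @param cluster_gap Maximum gap between cluster members, nt.
#' @param min_cluster_sites Minimum member count for a cluster to enter
#'   the cluster report (default 14, the published selection rule).
#' @param repeat_tolerance Interior non-GCC triplets tolerated by the
#'   repeat report.
#' @param model An [energy_model()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(mirna_fasta, transcript_fasta, annotation = NULL,
                            out_dir = tempfile("xenoscan"),
                            threshold = 90, overlap_resolution = FALSE,
                            cluster_gap = 0, min_cluster_sites = 14,
                            repeat_tolerance = 0, model = energy_model()) {
  if (threshold <= 0 || threshold > 100)
    stop("threshold must be in (0, 100], got ", threshold)
  stopifnot(cluster_gap >= 0, min_cluster_sites >= 1, repeat_tolerance >= 0)
  for (p in c(mirna_fasta, transcript_fasta, annotation))
    if (!file.exists(p)) stop("input file not found: ", p)
  structure(list(mirna_fasta = mirna_fasta,
                 transcript_fasta = transcript_fasta,
                 annotation = annotation, out_dir = out_dir,
                 threshold = threshold,
                 overlap_resolution = overlap_resolution,
                 cluster_gap = cluster_gap,
                 min_cluster_sites = min_cluster_sites,
                 repeat_tolerance = repeat_tolerance, model = model),
            class = "pipeline_config")
}

#' Run the full scan -> cluster -> repeat pipeline
#'
#' Scans every miRNA against every transcript, optionally resolves
#' cross-miRNA overlaps, groups sites into clusters, and characterizes
#' GCC repeat runs per region. Writes a deterministic report bundle:
#' `sites.tsv` (one row per site: gene, miRNA, start, region, dG, ratio,
#' length), `clusters.tsv` (clusters with at least `min_cluster_sites`
#' members: span, site count, dG range in min-to-max notation,
#' compaction), `repeats.tsv` (maximal GCC run per region per
#' transcript, kept when long enough to carry a length class, with the
#' encoded peptide for CDS runs), `pfm.tsv`
#' (per-miRNA position frequency matrix of its sites) and `config.tsv`
#' (parameter echo with input checksums). Identical inputs and
#' configuration yield byte-identical reports.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the unrounded `sites`, `clusters` and
#'   `repeats` tables and the output `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(config$out_dir,
                     c("sites.tsv", "clusters.tsv", "repeats.tsv",
                       "pfm.tsv", "config.tsv"))
  names(paths) <- c("sites", "clusters", "repeats", "pfm", "config")
  ok <- FALSE
  on.exit(if (!ok) unlink(paths))

  mirnas <- read_mirnas(config$mirna_fasta, config$model)
  txs <- read_transcripts(config$transcript_fasta, config$annotation)
  sites <- scan_all(mirnas, txs, config$model, config$threshold)
  if (config$overlap_resolution && nrow(sites)) {
    parts <- split(sites, sites$transcript_id)
    sites <- do.call(rbind, lapply(parts, resolve_overlaps))
    sites <- sites[order(sites$transcript_id, sites$start, sites$mirna_id), ]
    rownames(sites) <- NULL
  }

  cl_parts <- lapply(split(sites, sites$transcript_id), function(s)
    cluster_sites(s, gap = config$cluster_gap))
  clusters <- if (length(cl_parts)) do.call(rbind, unname(cl_parts))
              else cluster_sites(empty_sites())
  clusters <- clusters[clusters$n_sites >= config$min_cluster_sites, ,
                       drop = FALSE]

  repeats <- do.call(rbind, lapply(txs, function(tx) region_repeats(
    tx, config$repeat_tolerance)))
  rownames(repeats) <- NULL
  # report only runs long enough to carry a length class (>= 18 nt)
  repeats <- repeats[repeats$length_class != "none", , drop = FALSE]

  # report layer: integer rounding, range notation
  sites_rep <- data.frame(
    gene = sites$gene, mirna_id = sites$mirna_id, start = sites$start,
    region = sites$region, dG = round(sites$dG), ratio = round(sites$ratio),
    length = sites$length)
  cl_rep <- data.frame(
    gene = clusters$gene, transcript_id = clusters$transcript_id,
    first_start = clusters$first_start, last_start = clusters$last_start,
    span = clusters$span, n_sites = clusters$n_sites,
    dG_range = if (nrow(clusters)) paste0(round(clusters$dg_low), "÷",
                                          round(clusters$dg_high))
               else character(0),
    compaction = round(clusters$compaction))
  utils::write.table(sites_rep, paths["sites"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cl_rep, paths["clusters"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(repeats, paths["repeats"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_pfm(sites, paths["pfm"], txs)

  inputs <- c(config$mirna_fasta, config$transcript_fasta, config$annotation)
  echo <- data.frame(
    key = c("threshold", "overlap_resolution", "cluster_gap",
            "min_cluster_sites", "repeat_tolerance",
            paste0("md5:", basename(inputs))),
    value = c(config$threshold, config$overlap_resolution,
              config$cluster_gap, config$min_cluster_sites,
              config$repeat_tolerance, unname(tools::md5sum(inputs))))
  utils::write.table(echo, paths["config"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ok <- TRUE
  invisible(list(sites = sites, clusters = clusters, repeats = repeats,
                 paths = paths))
}

# maximal GCC run per annotated region of one transcript
region_repeats <- function(tx, tolerance = 0) {
  regions <- if (is.na(tx$cds_end)) {
    list(unknown = c(1L, tx$length))
  } else {
    list(`5UTR` = c(1L, tx$utr5_end),
         CDS = c(tx$utr5_end + 1L, tx$cds_end),
         `3UTR` = c(tx$cds_end + 1L, tx$length))
  }
  rows <- lapply(names(regions), function(rg) {
    b <- regions[[rg]]
    if (b[2] < b[1] + 2L) return(NULL)
    sub <- substr(tx$seq, b[1], b[2])
    run <- if (tolerance > 0) find_tolerant_run(sub, tolerance)
           else find_gcc_run(sub)
    if (run$k == 0L) return(NULL)
    start_tx <- b[1] + run$start - 1L
    pep <- if (rg == "CDS")
      translate_repeat(run, (start_tx - (tx$utr5_end + 1L)) %% 3L, "CDS")
    else NA
    data.frame(transcript_id = tx$id, gene = tx$gene, region = rg,
               run_start = start_tx, run_length = run$run_length,
               length_class = run$length_class,
               mismatched_triplets = run$mismatched_triplets,
               peptide = pep, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(transcript_id = character(), gene = character(),
                      region = character(), run_start = integer(),
                      run_length = integer(), length_class = character(),
                      mismatched_triplets = integer(), peptide = character(),
                      stringsAsFactors = FALSE)
  out
}

write_pfm <- function(sites, path, txs) {
  rows <- list()
  for (m in sort(unique(sites$mirna_id))) {
    s <- sites[sites$mirna_id == m, ]
    seqs <- vapply(seq_len(nrow(s)), function(i)
      substr(txs[[s$transcript_id[i]]]$seq, s$start[i],
             s$start[i] + s$length[i] - 1L), "")
    pfm <- position_frequency_matrix(seqs)
    for (b in rownames(pfm))
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = m, base = b, t(round(pfm[b, ], 4)))
  }
  if (length(rows)) {
    # pad to common width so one header serves all miRNA lengths
    w <- max(vapply(rows, ncol, 0L)) - 2L
    rows <- lapply(rows, function(r) {
      miss <- w - (ncol(r) - 2L)
      if (miss > 0) r[paste0("X", (w - miss + 1):w)] <- NA
      names(r)[-(1:2)] <- paste0("pos", seq_len(w))
      r
    })
    out <- do.call(rbind, rows)
  } else out <- data.frame(mirna_id = character(), base = character())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Recompute the published table-level counts from the packaged fixtures
#'
#' Checks, against the packaged tables, the counts the published report
#' states in its text: the 28 genes with clusters of 14 or more repeated
#' sites; the 13 distinct genes with fully complementary (100%) sites
#' and the distinct-gene region counts for 3'UTR (15) and CDS (10); the
#' 66 CDS and 52 5'UTR GCC-repeat site sequences; and the exact-run
#' length classification of all 52 5'UTR sequences (18 nt in 18 genes,
#' 21 nt in 11, 24 nt in 14, 27-48 nt in 9), recomputed from the printed
#' sequences with [find_gcc_run()].
#'
#' @return Object of class `fixture_check`: data frame with columns
#'   `check`, `expected`, `observed`, `pass`, and attribute `pass`
#'   (overall).
#' @export
check_fixtures <- function() {
  fx <- load_fixtures()
  cls <- vapply(fx$table4$seq_rna,
                function(s) find_gcc_run(s)$length_class, "")
  t2 <- fx$table2
  checks <- data.frame(
    check = c("table1: genes with >= 14 repeated sites",
              "table2: distinct genes with 100% sites",
              "table2: distinct genes with 3'UTR sites",
              "table2: distinct genes with CDS sites",
              "table3: CDS repeat-site sequences",
              "table4: 5'UTR repeat-site sequences",
              "table4: exact GCC run of 18 nt",
              "table4: exact GCC run of 21 nt",
              "table4: exact GCC run of 24 nt",
              "table4: exact GCC run of 27-48 nt"),
    expected = c(28, 13, 15, 10, 66, 52, 18, 11, 14, 9),
    observed = c(sum(fx$table1$site_count >= 14),
                 length(unique(t2$gene[t2$ratio == 100])),
                 length(unique(t2$gene[t2$region == "3UTR"])),
                 length(unique(t2$gene[t2$region == "CDS"])),
                 nrow(fx$table3), nrow(fx$table4),
                 sum(cls == "18"), sum(cls == "21"), sum(cls == "24"),
                 sum(cls == "27plus")))
  checks$pass <- checks$expected == checks$observed
  structure(checks, class = c("fixture_check", "data.frame"),
            pass = all(checks$pass))
}

#' @export
print.fixture_check <- function(x, ...) {
  cat("Fixture checks (", sum(x$pass), "/", nrow(x), " pass)\n", sep = "")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %-45s expected %3d observed %3d\n",
                if (x$pass[i]) "ok" else "FAIL", x$check[i],
                x$expected[i], x$observed[i]))
  invisible(x)
}
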