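#' Per-pair hybridization free-energy model
#'
#' The scoring model assigns every unordered RNA base pair a free-energy
#' magnitude (kJ/mol) and a hydrogen-bond count. The defaults cover the two
#' canonical Watson-Crick pairs and the two non-canonical (wobble) pairs:
#' G-C (6.37 kJ/mol, 3 bonds), A-U (4.25, 2), G-U (2.12, 1) and A-C
#' (2.12, 1). All other pairs form no bonds and contribute nothing. The
#' ambiguity base N never bonds.
#'
#' @param pairs Optional data frame overriding the default model, with
#'   columns `pair` (two-letter string such as `"GC"`), `energy` (kJ/mol,
#'   magnitude, >= 0) and `hbonds` (integer count). Pairs are unordered:
#'   `"GC"` and `"CG"` denote the same pair. Unlisted pairs get 0/0.
#' @return An object of class `energy_model`: a list with 5x5 matrices
#'   `energy`, `hbonds` and `pair_class` over the alphabet A, C, G, U, N,
#'   where `pair_class` labels each pair `"canonical"` (2 or 3 bonds),
#'   `"wobble"` (1 bond) or `"none"`.
#' @examples
#' mod <- energy_model()
#' mod$energy["G", "C"]   # 6.37
#' mod$hbonds["A", "C"]   # 1
#' @seealso [pair_energy()], [duplex_energy()], [read_energy_model()]
#' @export
energy_model <- function(pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- data.frame(
      pair   = c("GC", "AU", "GU", "AC"),
      energy = c(6.37, 4.25, 2.12, 2.12),
      hbonds = c(3L, 2L, 1L, 1L)
    )
  }
  stopifnot(is.data.frame(pairs), all(c("pair", "energy", "hbonds") %in% names(pairs)))
  ab <- c("A", "C", "G", "U", "N")
  energy <- matrix(0, 5, 5, dimnames = list(ab, ab))
  hbonds <- matrix(0L, 5, 5, dimnames = list(ab, ab))
  for (i in seq_len(nrow(pairs))) {
    p <- toupper(pairs$pair[i])
    if (nchar(p) != 2L || !all(strsplit(p, "")[[1]] %in% ab))
      stop("invalid pair specification: '", pairs$pair[i], "'")
    b <- strsplit(p, "")[[1]]
    energy[b[1], b[2]] <- energy[b[2], b[1]] <- pairs$energy[i]
    hbonds[b[1], b[2]] <- hbonds[b[2], b[1]] <- as.integer(pairs$hbonds[i])
  }
  # N never bonds
  energy["N", ] <- energy[, "N"] <- 0
  hbonds["N", ] <- hbonds[, "N"] <- 0L
  if (any(energy > 0 & hbonds < 1L))
    stop("every bonded pair (energy > 0) must have at least one hydrogen bond")
  if (any(energy == 0 & hbonds > 0L))
    stop("pairs with zero energy cannot carry hydrogen bonds")
  # energy must be ordered consistently with bond count
  ord <- order(energy[upper.tri(energy, diag = TRUE)])
  hb_ord <- hbonds[upper.tri(hbonds, diag = TRUE)][ord]
  if (is.unsorted(hb_ord))
    stop("pair energies must be ordered consistently with hydrogen-bond counts")
  pair_class <- matrix("none", 5, 5, dimnames = list(ab, ab))
  pair_class[hbonds >= 2L] <- "canonical"
  pair_class[hbonds == 1L] <- "wobble"
  structure(list(energy = energy, hbonds = hbonds, pair_class = pair_class),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("Hybridization energy model (kJ/mol magnitudes / hydrogen bonds)\n")
  ab <- c("A", "C", "G", "U")
  for (i in 1:3) for (j in (i + 1):4) {
    if (x$energy[ab[i], ab[j]] > 0)
      cat(sprintf("  %s-%s: %.2f kJ/mol, %d bond(s) [%s]\n", ab[i], ab[j],
                  x$energy[ab[i], ab[j]], x$hbonds[ab[i], ab[j]],
                  x$pair_class[ab[i], ab[j]]))
  }
  invisible(x)
}

#' Read an energy model from a flat key-value file
#'
#' The file is tab-separated with columns `pair`, `energy`, `hbonds`
#' (header required), one row per unordered base pair.
#'
#' @param path Path to the TSV file.
#' @return An [energy_model()] object.
#' @export
read_energy_model <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  energy_model(tab)
}

base_index <- function(seq, what = "sequence") {
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, c("A", "C", "G", "U", "N"))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("invalid ", what, " character '", chars[bad], "' at position ", bad,
         " (alphabet is A, C, G, U, N)")
  }
  idx
}

#' Free energy of a single base pair
#'
#' Looks up the energy magnitude (kJ/mol) of pairing an mRNA base with a
#' miRNA base. Symmetric in its arguments; any pair involving N scores 0.
#'
#' @param base_mrna,base_mirna Single RNA bases (A, C, G, U or N).
#' @param model An [energy_model()].
#' @return Energy magnitude in kJ/mol.
#' @examples
#' pair_energy("G", "C")  # 6.37
#' pair_energy("A", "A")  # 0
#' @export
pair_energy <- function(base_mrna, base_mirna, model = energy_model()) {
  i <- base_index(toupper(base_mrna), "base")
  j <- base_index(toupper(base_mirna), "base")
  unname(model$energy[cbind(i, j)])
}

#' Hydrogen-bond count of a single base pair
#'
#' @inheritParams pair_energy
#' @return Integer bond count (3 for G-C, 2 for A-U, 1 for the G-U and A-C
#'   wobbles, 0 otherwise).
#' @examples
#' hydrogen_bonds("G", "C")  # 3
#' hydrogen_bonds("C", "U")  # 0
#' @export
hydrogen_bonds <- function(base_mrna, base_mirna, model = energy_model()) {
  i <- base_index(toupper(base_mrna), "base")
  j <- base_index(toupper(base_mirna), "base")
  unname(model$hbonds[cbind(i, j)])
}

#' Free energy of a miRNA bound to its perfect complement
#'
#' dGm is the free energy of the duplex formed by the miRNA and its exact
#' canonical reverse complement. It depends only on base composition:
#' each G or C contributes the G-C energy, each A or U the A-U energy
#' (under the default model), and N contributes nothing.
#'
#' @param mirna miRNA sequence, 5'->3' RNA text.
#' @param model An [energy_model()].
#' @return dGm in kJ/mol (<= 0).
#' @examples
#' perfect_energy(strrep("G", 18))  # -114.66
#' perfect_energy("AUAU")           # -17
#' @export
perfect_energy <- function(mirna, model = energy_model()) {
  mirna <- toupper(mirna)
  if (!nzchar(mirna)) stop("miRNA sequence must be non-empty")
  idx <- base_index(mirna, "miRNA")
  comp <- c(4L, 3L, 2L, 1L, 5L)  # A<->U, C<->G, N<->N
  -sum(model$energy[cbind(idx, comp[idx])])
}

#' Score one miRNA:site duplex over the full miRNA length
#'
#' Pairs the candidate mRNA window against the miRNA antiparallel: site
#' position i (1-based, 5'->3') pairs miRNA position L + 1 - i. Each
#' position contributes its pair energy; non-bonding positions contribute
#' 0. The duplex carries dG (sum, negative), dGm (perfect-complement
#' energy of the miRNA) and the complementarity ratio 100 * dG/dGm.
#'
#' @param mirna miRNA sequence, 5'->3' RNA text.
#' @param site Candidate site sequence, 5'->3' RNA text, same length.
#' @param model An [energy_model()].
#' @return An object of class `duplex`: list with `mirna`, `site`,
#'   `pair_class` (character vector, `"canonical"`/`"wobble"`/`"none"` per
#'   site position), `dG`, `dGm`, `ratio`.
#' @examples
#' d <- duplex_energy("AUGC", "GCAU")
#' d$dG     # -21.24
#' d$ratio  # 100
#' @export
duplex_energy <- function(mirna, site, model = energy_model()) {
  mirna <- toupper(mirna); site <- toupper(site)
  if (nchar(mirna) != nchar(site))
    stop("miRNA and site lengths differ: ", nchar(mirna), " vs ", nchar(site))
  if (!nzchar(mirna)) stop("sequences must be non-empty")
  mi <- base_index(mirna, "miRNA")
  si <- base_index(site, "site")
  mi_rev <- rev(mi)  # miRNA base paired with site position i
  # summed in miRNA-position order so a perfect duplex reproduces dGm exactly
  dG <- -sum(model$energy[cbind(rev(si), mi)])
  dGm <- perfect_energy(mirna, model)
  structure(list(
    mirna = mirna, site = site,
    pair_class = model$pair_class[cbind(si, mi_rev)],
    dG = dG, dGm = dGm,
    ratio = complementarity_ratio(dG, dGm)
  ), class = "duplex")
}

#' Complementarity ratio of a duplex
#'
#' The site-quality statistic 100 * dG/dGm (percent). 100 means the site
#' is the exact canonical complement of the miRNA; smaller values reflect
#' wobbles and mismatches. Internally unrounded; reports round to the
#' nearest integer percent.
#'
#' @param dG Duplex free energy, kJ/mol (<= 0).
#' @param dGm Perfect-complement free energy, kJ/mol (< 0).
#' @return Percent in \[0, 100\].
#' @examples
#' complementarity_ratio(-19.09, -21.24)  # 89.88...
#' @export
complementarity_ratio <- function(dG, dGm) {
  if (any(dGm >= 0)) stop("dGm must be negative (degenerate miRNA?)")
  if (any(dG > 1e-9)) stop("dG must be <= 0")
  if (any(dG < dGm - 1e-9)) stop("|dG| cannot exceed |dGm|")
  100 * (dG / dGm)  # grouped so dG == dGm gives exactly 100
}

#' @export
print.duplex <- function(x, ...) {
  cat(render_scheme(x), "\n")
  cat(sprintf("dG = %.2f kJ/mol, dGm = %.2f kJ/mol, dG/dGm = %.1f%%\n",
              x$dG, x$dGm, x$ratio))
  invisible(x)
}

#' Render a duplex as a three-line pairing scheme
#'
#' Line 1 is the mRNA site 5'->3', line 2 the bond row (`|` canonical,
#' `:` wobble, space for no bond), line 3 the miRNA written 3'->5' so
#' paired bases align vertically. [parse_scheme()] inverts the rendering.
#'
#' @param duplex A [duplex_energy()] result.
#' @return A single string with embedded newlines.
#' @export
render_scheme <- function(duplex) {
  stopifnot(inherits(duplex, "duplex"))
  bonds <- chartr("cwn", "|: ", substr(duplex$pair_class, 1, 1))
  mirna_rev <- paste(rev(strsplit(duplex$mirna, "")[[1]]), collapse = "")
  paste0("5'-", duplex$site, "-3'\n",
         "   ", paste(bonds, collapse = ""), "   \n",
         "3'-", mirna_rev, "-5'")
}

#' Parse a rendered pairing scheme
#'
#' @param text Output of [render_scheme()].
#' @return List with `site`, `mirna` (both 5'->3') and `pair_class`.
#' @export
parse_scheme <- function(text) {
  ln <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(ln) != 3L) stop("a pairing scheme has exactly three lines")
  site <- sub("-3'$", "", sub("^5'-", "", ln[1]))
  mirna_rev <- sub("-5'$", "", sub("^3'-", "", ln[3]))
  bonds <- substr(ln[2], 4, 3 + nchar(site))
  cls <- c("|" = "canonical", ":" = "wobble", " " = "none")
  list(site = site,
       mirna = paste(rev(strsplit(mirna_rev, "")[[1]]), collapse = ""),
       pair_class = unname(cls[strsplit(bonds, "")[[1]]]))
}
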