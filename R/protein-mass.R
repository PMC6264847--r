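# Monoisotopic and average residue masses (Da) for the 20 canonical amino
# acids, plus the mass of water added once per chain.
.MONO <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
           V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
           I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
           K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
           F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
.AVG  <- c(G = 57.0513, A = 71.0779, S = 87.0773, P = 97.1152,
           V = 99.1311, T = 101.1039, C = 103.1429, L = 113.1576,
           I = 113.1576, N = 114.1026, D = 115.0874, Q = 128.1292,
           K = 128.1723, E = 129.1140, M = 131.1926, H = 137.1393,
           F = 147.1739, R = 156.1857, Y = 163.1733, W = 186.2099)
.WATER_MONO <- 18.01056
.WATER_AVG  <- 18.01528
.MET_MONO <- 131.04049
.MET_AVG  <- 131.19261
.PROTON <- 1.00728

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L)
    stop("sequence must be a non-empty string of canonical residues")
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!aa %in% names(.MONO))
  if (length(bad) > 0)
    stop(sprintf("non-canonical residue '%s' at position %d", aa[bad[1]],
                 bad[1]))
  aa
}

#' Monoisotopic and average mass of a protein sequence
#'
#' Sum of standard residue masses plus one water. Full precision is
#' retained; report tables round to 0.1 Da.
#'
#' @param sequence amino-acid string (20 canonical residues, case
#'   insensitive).
#' @return named numeric vector `c(mono, avg)` in Da.
#' @export
protein_masses <- function(sequence) {
  aa <- .check_sequence(sequence)
  c(mono = sum(.MONO[aa]) + .WATER_MONO,
    avg = sum(.AVG[aa]) + .WATER_AVG)
}

#' Masses after N-terminal methionine loss
#'
#' The initiator methionine is commonly excised co-translationally, shifting
#' the intact mass down by one Met residue (mono 131.04049 Da, average
#' 131.19261 Da). Variants are produced for every sequence starting with
#' Met; for other sequences the result is absent (`NULL`).
#'
#' @param mono_mass,avg_mass masses of the full sequence, Da.
#' @param sequence the sequence the masses belong to.
#' @return named vector `c(mono_noMet, avg_noMet)`, or `NULL` when the
#'   sequence does not start with methionine.
#' @export
met_loss_masses <- function(mono_mass, avg_mass, sequence) {
  aa <- .check_sequence(sequence)
  if (aa[1] != "M") return(NULL)
  c(mono_noMet = mono_mass - .MET_MONO, avg_noMet = avg_mass - .MET_AVG)
}

# Bjellqvist pKa values: side chains, C terminus, and residue-specific
# N-terminal values.
.PK_SIDE_NEG <- c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
.PK_SIDE_POS <- c(H = 5.98, K = 10.00, R = 12.00)
.PK_CTERM <- 3.55
.PK_NTERM <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
               V = 7.44, E = 7.70, G = 7.50)
.nterm_pk <- function(res) {
  if (res %in% names(.PK_NTERM)) .PK_NTERM[[res]] else 7.50
}

# Net charge of the Henderson-Hasselbalch model at a given pH.
.net_charge <- function(aa, ph) {
  pos <- 1 / (1 + 10^(ph - .nterm_pk(aa[1])))
  neg <- 1 / (1 + 10^(.PK_CTERM - ph))
  for (res in names(.PK_SIDE_POS)) {
    k <- sum(aa == res)
    if (k > 0) pos <- pos + k / (1 + 10^(ph - .PK_SIDE_POS[[res]]))
  }
  for (res in names(.PK_SIDE_NEG)) {
    k <- sum(aa == res)
    if (k > 0) neg <- neg + k / (1 + 10^(.PK_SIDE_NEG[[res]] - ph))
  }
  pos - neg
}

#' Isoelectric point of a protein sequence
#'
#' pH at which the modeled net charge (termini plus D, E, C, Y, K, R, H
#' side chains; Bjellqvist pKa set) crosses zero, found by bisection on
#' \[0, 14\].
#'
#' @param sequence amino-acid string.
#' @param precision bisection stopping width in pH units (default 1e-4;
#'   results are conventionally reported to 0.01).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence, precision = 1e-4) {
  aa <- .check_sequence(sequence)
  lo <- 0; hi <- 14
  # net charge is strictly decreasing in pH
  while (hi - lo > precision) {
    mid <- (lo + hi) / 2
    if (.net_charge(aa, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Build protein records from sequences
#'
#' Computes, for each sequence, the monoisotopic and average intact mass,
#' the methionine-loss variants (when the sequence starts with Met) and the
#' isoelectric point.
#'
#' @param sequences named character vector of amino-acid sequences, or the
#'   path to a FASTA file.
#' @return a data.frame with columns `accession`, `name`, `mono_mass`,
#'   `avg_mass`, `mono_mass_noMet`, `avg_mass_noMet` (NA when absent) and
#'   `pi`.
#' @export
protein_records <- function(sequences) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    aa <- Biostrings::readAAStringSet(sequences)
    seqs <- as.character(aa)
    hdr <- names(aa)
    acc <- sub("\\s.*$", "", hdr)
    nm <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), hdr)
    names(seqs) <- acc
  } else {
    seqs <- sequences
    acc <- names(seqs)
    if (is.null(acc)) acc <- paste0("seq", seq_along(seqs))
    nm <- acc
  }
  rows <- lapply(seq_along(seqs), function(i) {
    m <- protein_masses(seqs[[i]])
    nomet <- met_loss_masses(m[["mono"]], m[["avg"]], seqs[[i]])
    data.frame(accession = acc[i], name = nm[i],
               mono_mass = m[["mono"]], avg_mass = m[["avg"]],
               mono_mass_noMet = if (is.null(nomet)) NA_real_ else nomet[["mono_noMet"]],
               avg_mass_noMet = if (is.null(nomet)) NA_real_ else nomet[["avg_noMet"]],
               pi = round(isoelectric_point(seqs[[i]]), 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign candidate proteins to observed peaks by mass agreement
#'
#' For each protein the candidate (mass variant, peak) pair minimizing the
#' absolute mass difference over the enabled variants and all peaks is
#' selected, and reported when it falls within the tolerance. Each protein
#' yields at most one assignment; peaks may certify several proteins (more
#' than one protein can share a peak within tolerance).
#'
#' @param proteins data.frame as from [protein_records()], or any
#'   data.frame with `accession` and the mass columns named by `variants`.
#' @param peaks numeric vector of observed peak m/z values (sorted).
#' @param tol tolerance: Da when `tol_mode = "da"`, ppm when `"ppm"`.
#' @param variants subset of `c("mono", "avg", "mono_noMet", "avg_noMet")`
#'   to consider; default `c("avg", "avg_noMet")` since intact-protein
#'   MALDI peaks are unresolved isotopic envelopes tracking average mass.
#' @param tol_mode `"da"` (absolute) or `"ppm"`.
#' @param proton subtract one proton mass from the observed m/z before
#'   comparison (treat peaks as \[M+H\]+); default FALSE compares neutral
#'   masses directly.
#' @return list with `assignments` (data.frame: accession, name,
#'   matched_peak_mz, variant_used, mass_used, delta_da, delta_ppm; sorted
#'   by matched_peak_mz) and `unmatched` (data.frame of the rest).
#' @export
match_masses_to_peaks <- function(proteins, peaks, tol = 6,
                                  variants = c("avg", "avg_noMet"),
                                  tol_mode = c("da", "ppm"),
                                  proton = FALSE) {
  tol_mode <- match.arg(tol_mode)
  stopifnot(tol > 0)
  varcols <- c(mono = "mono_mass", avg = "avg_mass",
               mono_noMet = "mono_mass_noMet", avg_noMet = "avg_mass_noMet")
  variants <- match.arg(variants, names(varcols), several.ok = TRUE)
  peaks <- sort(as.numeric(peaks))
  neutral <- if (proton) peaks - .PROTON else peaks
  nm_col <- if ("name" %in% names(proteins)) proteins$name else proteins$accession

  res <- lapply(seq_len(nrow(proteins)), function(i) {
    best <- NULL
    for (v in variants) {
      mass <- proteins[[varcols[[v]]]][i]
      if (is.na(mass)) next
      if (length(peaks) == 0L) next
      d <- neutral - mass
      j <- which.min(abs(d))
      cand <- list(variant = v, peak = peaks[j], delta = d[j], mass = mass)
      if (is.null(best) || abs(cand$delta) < abs(best$delta)) best <- cand
    }
    ok <- FALSE
    if (!is.null(best)) {
      ok <- if (tol_mode == "da") abs(best$delta) <= tol
            else abs(best$delta) / best$mass * 1e6 <= tol
    }
    data.frame(accession = proteins$accession[i], name = nm_col[i],
               matched_peak_mz = if (ok) best$peak else NA_real_,
               variant_used = if (ok) best$variant else NA_character_,
               mass_used = if (ok) best$mass else NA_real_,
               delta_da = if (ok) best$delta else NA_real_,
               delta_ppm = if (ok) best$delta / best$mass * 1e6 else NA_real_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, res)
  matched <- df[!is.na(df$matched_peak_mz), , drop = FALSE]
  matched <- matched[order(matched$matched_peak_mz, matched$accession), ,
                     drop = FALSE]
  rownames(matched) <- NULL
  unmatched <- df[is.na(df$matched_peak_mz),
                  c("accession", "name"), drop = FALSE]
  rownames(unmatched) <- NULL
  list(assignments = matched, unmatched = unmatched)
}
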