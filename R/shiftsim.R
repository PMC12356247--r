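#' Random-coil backbone shift statistics
#'
#' Literature-typical random-coil means (ppm) for amide \eqn{^{15}}N,
#' \eqn{^1H^N}, \eqn{^{13}C^\alpha} and \eqn{^{13}C^\beta} of the 20
#' standard residues. Glycine has no \eqn{C^\beta}; proline has no amide
#' \eqn{H^N}/N entry. This built-in table is a modelling choice standing in
#' for database-derived shifts; the Gaussian dispersion added by
#' [generate_shift_table()] emulates the structure-dependent spread seen in
#' folded proteins.
#'
#' @return Data frame with columns `aa` (one-letter), `aa3`, `n_ppm`,
#'   `h_ppm`, `ca_ppm`, `cb_ppm`.
#' @export
random_coil_shifts <- function() {
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
aa aa3 n_ppm h_ppm ca_ppm cb_ppm
A ALA 123.8 8.24 52.5 19.1
R ARG 120.5 8.23 56.0 30.9
N ASN 118.7 8.40 53.1 38.9
D ASP 120.4 8.34 54.2 41.1
C CYS 118.8 8.32 58.2 28.0
Q GLN 119.8 8.32 55.7 29.4
E GLU 120.2 8.36 56.6 29.9
G GLY 108.8 8.33 45.1 NA
H HIS 118.2 8.42 55.0 29.0
I ILE 119.9 8.00 61.1 38.8
L LEU 121.8 8.16 55.1 42.4
K LYS 120.4 8.29 56.2 33.1
M MET 119.6 8.28 55.4 32.9
F PHE 120.3 8.30 57.7 39.6
P PRO NA NA 63.3 32.1
S SER 115.7 8.31 58.3 63.8
T THR 113.6 8.15 61.8 69.8
W TRP 121.3 8.25 57.5 29.6
Y TYR 120.3 8.12 57.9 38.8
V VAL 119.2 8.03 62.2 32.9")
  tab
}

#' Generate a synthetic backbone shift table
#'
#' Draws per-residue shifts as the residue type's random-coil mean plus a
#' Gaussian deviation, emulating the dispersion of folded-protein spectra.
#' Default standard deviations (ppm, scaled by `dispersion_scale`):
#' N 4.0, \eqn{H^N} 0.5, \eqn{C^\alpha} 1.5, \eqn{C^\beta} 1.5. Glycine
#' rows have no \eqn{C^\beta}; proline rows have no amide entries.
#'
#' @param sequence one-letter residue string over the 20 standard residues.
#' @param dispersion_scale multiplier on the default dispersion (0 gives
#'   identical shifts for same-type residues).
#' @param seed optional integer seed (deterministic output under it).
#' @param sd_ppm named numeric: base standard deviations for `n`, `h`,
#'   `ca`, `cb`.
#' @return An object of class `shift_table` (a data frame with columns
#'   `res`, `aa`, `n_ppm`, `h_ppm`, `ca_ppm`, `cb_ppm`).
#' @examples
#' generate_shift_table("MQIFVKTLTG", seed = 1)
#' @export
generate_shift_table <- function(sequence, dispersion_scale = 1, seed = NULL,
                                 sd_ppm = c(n = 4, h = 0.5, ca = 1.5,
                                            cb = 1.5)) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  rc <- random_coil_shifts()
  unknown <- setdiff(unique(aa), rc$aa)
  if (length(unknown))
    stop("unknown residue letter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  row <- match(aa, rc$aa)
  L <- length(aa)
  tab <- .with_seed(seed, {
    data.frame(
      res = seq_len(L), aa = aa,
      n_ppm = rc$n_ppm[row] +
        stats::rnorm(L, 0, sd_ppm[["n"]] * dispersion_scale),
      h_ppm = rc$h_ppm[row] +
        stats::rnorm(L, 0, sd_ppm[["h"]] * dispersion_scale),
      ca_ppm = rc$ca_ppm[row] +
        stats::rnorm(L, 0, sd_ppm[["ca"]] * dispersion_scale),
      cb_ppm = rc$cb_ppm[row] +
        stats::rnorm(L, 0, sd_ppm[["cb"]] * dispersion_scale))
  })
  tab$n_ppm[is.na(rc$n_ppm[row])] <- NA_real_
  tab$h_ppm[is.na(rc$h_ppm[row])] <- NA_real_
  tab$cb_ppm[is.na(rc$cb_ppm[row])] <- NA_real_
  class(tab) <- c("shift_table", "data.frame")
  tab
}

#' Concatenate domains into a multidomain shift table
#'
#' Joins member sequences with glycine linkers (default 10 residues) and
#' draws fresh shifts for the whole construct, emulating multidomain test
#' systems; total length is the member sum plus
#' `linker_length * (n_members - 1)`.
#'
#' @param sequences character vector of one-letter member sequences.
#' @param linker_length glycine-linker run length between members.
#' @inheritParams generate_shift_table
#' @return A `shift_table`.
#' @export
build_multidomain <- function(sequences, linker_length = 10,
                              dispersion_scale = 1, seed = NULL) {
  stopifnot(is.character(sequences), length(sequences) >= 1)
  full <- paste(sequences, collapse = strrep("G", linker_length))
  generate_shift_table(full, dispersion_scale = dispersion_scale, seed = seed)
}

# amide observability: residue 2..L, not proline, with amide shifts present
.observable_amides <- function(table) {
  obs <- table$res[table$res >= 2 & table$aa != "P" & !is.na(table$n_ppm)]
  obs
}

.is_sr_experiment <- function(experiment) startsWith(experiment, "SR-")

#' Default acquisition geometry per experiment type
#'
#' Complex time-domain points and sweep widths per dimension at a 700 MHz
#' field: 512 (\eqn{^1}H), 128 (\eqn{^{15}}N) and, in the carbon dimension,
#' 42 points for standard experiments (coupling-limited t1max of about
#' 8 ms at a 30 ppm sweep) versus 200 for SR experiments (about 38 ms).
#'
#' @param experiment experiment name (see [simulate_peaklist()]).
#' @return List with per-dimension points, sweep widths (Hz), derived
#'   maximal evolution times and the three Larmor frequencies (MHz).
#' @export
experiment_acq <- function(experiment) {
  sr <- .is_sr_experiment(experiment)
  freq <- c(h = 700, n = 70.95, c = 176.05)
  c_sw <- 30 * freq[["c"]]
  n_sw <- 35 * freq[["n"]]
  h_sw <- 17.9 * freq[["h"]]
  c_points <- if (sr) 200L else 42L
  list(h_points = 512L, n_points = 128L, c_points = c_points,
       h_sw_hz = h_sw, n_sw_hz = n_sw, c_sw_hz = c_sw,
       c_t1max_s = c_points / c_sw, n_t1max_s = 128 / n_sw,
       h_t1max_s = 512 / h_sw, freq_mhz = freq)
}

# apparent FWHM model: truncation-limited width 0.66/t1max plus, for
# standard experiments where the Ca-Cb doublet is unresolved, the splitting
.c_width_hz <- function(t1max_s, doublet_j_hz = 0) {
  0.66 / t1max_s + doublet_j_hz
}

#' Simulate a triple-resonance peak list
#'
#' Cross-peak generation rules per observable amide (residues 2..L,
#' non-proline):
#' \describe{
#'   \item{HSQC15N}{one amide peak.}
#'   \item{HNCA / SR-HNCA}{one intraresidual peak at \eqn{C^\alpha_i} and
#'     one sequential peak at \eqn{C^\alpha_{i-1}}, the latter scaled by
#'     `intra_seq_ratio`.}
#'   \item{HNcoCA / SR-HNcoCA}{the sequential peak only.}
#'   \item{CBCAcoNH}{\eqn{C^\alpha_{i-1}} and \eqn{C^\beta_{i-1}} (absent
#'     when a glycine precedes).}
#' }
#' SR and standard lists are coordinate-identical; they differ in the
#' carbon-dimension width (truncation-limited, 0.66/t1max, plus the 35 Hz
#' doublet contribution for standard carbon peaks) and in fine structure
#' (SR peaks are singlets, standard \eqn{C^\alpha}/\eqn{C^\beta} peaks are
#' 35 Hz doublets).
#'
#' @param table a `shift_table`.
#' @param experiment one of `"HSQC15N"`, `"HNCA"`, `"SR-HNCA"`,
#'   `"HNcoCA"`, `"SR-HNcoCA"`, `"CBCAcoNH"`.
#' @param acq acquisition geometry, see [experiment_acq()].
#' @param intra_seq_ratio sequential-to-intra intensity ratio in HNCA.
#' @return Data frame of peaks with columns `experiment`, `peak_type`
#'   (`"amide"`, `"intra"`, `"seq"`, `"seq_cb"`), `h_ppm`, `n_ppm`,
#'   `c_ppm`, `intensity`, `fwhm_h_hz`, `fwhm_n_hz`, `fwhm_c_hz`,
#'   `fine_structure`, `j_hz`, `res_amide`, `res_c`, `atom`.
#' @examples
#' tab <- generate_shift_table("MQIFVK", seed = 1)
#' simulate_peaklist(tab, "HNCA")
#' @export
simulate_peaklist <- function(table,
                              experiment = c("HSQC15N", "HNCA", "SR-HNCA",
                                             "HNcoCA", "SR-HNcoCA",
                                             "CBCAcoNH"),
                              acq = NULL, intra_seq_ratio = 0.5) {
  stopifnot(inherits(table, "shift_table"))
  experiment <- match.arg(experiment)
  if (is.null(acq)) acq <- experiment_acq(experiment)
  sr <- .is_sr_experiment(experiment)
  obs <- .observable_amides(table)
  fwhm_h <- 0.66 / acq$h_t1max_s
  fwhm_n <- 0.66 / acq$n_t1max_s
  doublet_j <- if (sr) 0 else 35
  fwhm_c <- .c_width_hz(acq$c_t1max_s, doublet_j)
  fine <- if (sr) "singlet" else "doublet"
  peak <- function(i, type, c_res, atom, intensity) {
    c_ppm <- if (is.na(atom)) NA_real_
      else if (atom == "CA") table$ca_ppm[c_res] else table$cb_ppm[c_res]
    data.frame(experiment = experiment, peak_type = type,
               h_ppm = table$h_ppm[i], n_ppm = table$n_ppm[i],
               c_ppm = c_ppm, intensity = intensity,
               fwhm_h_hz = fwhm_h, fwhm_n_hz = fwhm_n,
               fwhm_c_hz = if (is.na(atom)) NA_real_ else fwhm_c,
               fine_structure = if (is.na(atom)) "singlet" else fine,
               j_hz = if (is.na(atom)) NA_real_ else doublet_j,
               res_amide = i, res_c = c_res, atom = atom)
  }
  out <- list()
  for (i in obs) {
    out[[length(out) + 1L]] <- switch(experiment,
      "HSQC15N" = peak(i, "amide", NA_integer_, NA_character_, 1),
      "HNCA" = ,
      "SR-HNCA" = rbind(peak(i, "intra", i, "CA", 1),
                        peak(i, "seq", i - 1L, "CA", intra_seq_ratio)),
      "HNcoCA" = ,
      "SR-HNcoCA" = peak(i, "seq", i - 1L, "CA", 1),
      "CBCAcoNH" = {
        p <- peak(i, "seq", i - 1L, "CA", 1)
        if (table$aa[i - 1L] != "G")
          p <- rbind(p, peak(i, "seq_cb", i - 1L, "CB", 0.6))
        p
      })
  }
  peaks <- do.call(rbind, out)
  rownames(peaks) <- NULL
  peaks
}

#' Add peak-position jitter scaled to linewidth
#'
#' Gaussian coordinate jitter per dimension with standard deviation equal
#' to half the peak's FWHM converted to ppm — peak-centre precision scales
#' with linewidth, which is how narrower SR lines translate into more
#' precise \eqn{C^\alpha} coordinates.
#'
#' @param peaks a peak data frame from [simulate_peaklist()].
#' @param seed optional integer seed.
#' @param freq_mhz named Larmor frequencies (MHz) for `h`, `n`, `c`.
#' @return The peak data frame with jittered coordinates.
#' @export
add_peak_jitter <- function(peaks, seed = NULL,
                            freq_mhz = c(h = 700, n = 70.95, c = 176.05)) {
  n <- nrow(peaks)
  .with_seed(seed, {
    peaks$h_ppm <- peaks$h_ppm +
      stats::rnorm(n, 0, peaks$fwhm_h_hz / 2 / freq_mhz[["h"]])
    peaks$n_ppm <- peaks$n_ppm +
      stats::rnorm(n, 0, peaks$fwhm_n_hz / 2 / freq_mhz[["n"]])
    jc <- stats::rnorm(n, 0, ifelse(is.na(peaks$fwhm_c_hz), 0,
                                    peaks$fwhm_c_hz) / 2 / freq_mhz[["c"]])
    peaks$c_ppm <- peaks$c_ppm + ifelse(is.na(peaks$c_ppm), 0, jc)
    peaks
  })
}

#' Mean candidate count per sequential peak
#'
#' For every sequential \eqn{C^\alpha} peak, counts the intraresidual
#' \eqn{C^\alpha} values lying within the matching tolerance, and reports
#' the mean — a transparent measure of linking ambiguity. Narrower SR lines
#' justify a tighter tolerance and hence fewer candidates. Sequential peaks
#' whose predecessor carbon is not itself observed as an intra peak (chain
#' starts and successors of prolines, identified through the simulation
#' truth) are excluded: they have no true candidate at any tolerance.
#'
#' @param peaks peak data frame containing `"intra"` and `"seq"` CA peaks.
#' @param tolerance_ppm matching tolerance; default half the mean carbon
#'   FWHM converted to ppm at 176.05 MHz.
#' @return Mean number of candidates (>= 0).
#' @export
ambiguity_metric <- function(peaks, tolerance_ppm = NULL) {
  is_seq <- peaks$peak_type == "seq" & peaks$atom %in% "CA"
  is_intra <- peaks$peak_type == "intra" & peaks$atom %in% "CA"
  linkable <- is_seq & peaks$res_c %in% peaks$res_c[is_intra]
  seqs <- peaks$c_ppm[linkable]
  intras <- peaks$c_ppm[is_intra]
  if (!length(seqs) || !length(intras))
    stop("peak list has no sequential/intra CA peaks", call. = FALSE)
  if (is.null(tolerance_ppm))
    tolerance_ppm <- mean(peaks$fwhm_c_hz, na.rm = TRUE) / 2 / 176.05
  counts <- vapply(seqs, function(s) sum(abs(intras - s) <= tolerance_ppm), 0)
  mean(counts)
}

#' Draw a random protein sequence
#'
#' Uniform over the 20 standard residues except proline and glycine, which
#' are down-weighted to roughly their natural abundance so that benchmark
#' chains are mostly contiguous.
#'
#' @param n sequence length.
#' @param seed optional integer seed.
#' @return One-letter sequence string.
#' @export
random_protein_sequence <- function(n, seed = NULL) {
  rc <- random_coil_shifts()
  w <- rep(1, nrow(rc))
  w[rc$aa == "P"] <- 0.4
  w[rc$aa == "G"] <- 0.7
  .with_seed(seed,
    paste(sample(rc$aa, n, replace = TRUE, prob = w / sum(w)),
          collapse = ""))
}
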