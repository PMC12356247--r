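# Text formats: schedule TSV/JSON, interferogram and spectrum TSV, a
# minimal NMR-STAR atom-shift loop dialect, and Sparky-style peak lists.
# All numeric fields carry explicit units in their column names; files are
# deterministic byte-for-byte for fixed inputs.

.num <- function(x) sprintf("%.15g", x)

#' Write / read a schedule as TSV
#'
#' Header lines (`# key=value`) carry every acquisition parameter and the
#' mode; the body has columns `index`, `t1_s`, `delta_used`, `t_eff_s`,
#' `phase_sign`, `n_scans`, `residual`. Output is byte-deterministic.
#'
#' @param schedule an `sr_schedule`.
#' @param path file path.
#' @return `write_schedule_tsv` returns `path` invisibly;
#'   `read_schedule_tsv` returns the schedule rows as a data frame with the
#'   parameters in `attr(, "params")`.
#' @export
write_schedule_tsv <- function(schedule, path) {
  stopifnot(inherits(schedule, "sr_schedule"))
  p <- schedule$params
  hdr <- c(sprintf("# j_hz=%s", .num(p$j_hz)),
           sprintf("# delta_a_s=%s", .num(p$delta_a_s)),
           sprintf("# delta_b_s=%s", .num(p$delta_b_s)),
           sprintf("# switch_margin_s=%s", .num(p$switch_margin_s)),
           sprintf("# t1_max_s=%s", .num(p$t1_max_s)),
           sprintf("# n_increments=%d", p$n_increments),
           sprintf("# base_scans=%d", p$base_scans),
           sprintf("# rounding_mode=%s", p$rounding_mode),
           sprintf("# boost_cap=%s", p$boost_cap),
           sprintf("# mode=%s", schedule$mode))
  r <- schedule$rows
  body <- sprintf("%d\t%s\t%s\t%s\t%d\t%d\t%s", r$index, .num(r$t1_s),
                  r$delta_used, .num(r$t_eff_s), r$phase_sign, r$n_scans,
                  .num(r$residual))
  writeLines(c(hdr,
               "index\tt1_s\tdelta_used\tt_eff_s\tphase_sign\tn_scans\tresidual",
               body), path)
  invisible(path)
}

#' @rdname write_schedule_tsv
#' @export
read_schedule_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines)
  kv <- strsplit(sub("^# ", "", lines[hdr]), "=", fixed = TRUE)
  params <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  rows <- utils::read.table(text = lines[-hdr], header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  attr(rows, "params") <- params
  rows
}

#' Write a schedule as JSON
#'
#' Parameters, mode and per-increment rows in one JSON object, for
#' programmatic consumption.
#'
#' @inheritParams write_schedule_tsv
#' @return `path`, invisibly.
#' @export
write_schedule_json <- function(schedule, path) {
  stopifnot(inherits(schedule, "sr_schedule"))
  p <- schedule$params
  obj <- list(params = p[setdiff(names(p), "metadata")],
              metadata = p$metadata, mode = schedule$mode,
              rows = schedule$rows)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write / read an interferogram as TSV
#'
#' Columns `index`, `real`, `imag` at full double precision; round-trips
#' exactly through [read_interferogram_tsv()] given the generating
#' schedule.
#'
#' @param fid an `interferogram`.
#' @param path file path.
#' @param schedule the schedule the interferogram was recorded with.
#' @return The path (write) or an `interferogram` (read).
#' @export
write_interferogram_tsv <- function(fid, path) {
  stopifnot(inherits(fid, "interferogram"))
  writeLines(c("index\treal\timag",
               sprintf("%d\t%.17g\t%.17g", seq_along(fid$values),
                       Re(fid$values), Im(fid$values))), path)
  invisible(path)
}

#' @rdname write_interferogram_tsv
#' @export
read_interferogram_tsv <- function(path, schedule) {
  stopifnot(inherits(schedule, "sr_schedule"))
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("real", "imag") %in% names(tab)))
    stop("not an interferogram TSV: ", path, call. = FALSE)
  if (nrow(tab) != nrow(schedule$rows))
    stop("interferogram length does not match the schedule", call. = FALSE)
  structure(list(values = complex(real = tab$real, imaginary = tab$imag),
                 schedule = schedule, noise_sigma = NA_real_, seed = NULL),
            class = "interferogram")
}

#' Write a spectrum as TSV
#'
#' Columns `axis_hz`, `axis_ppm`, `intensity`; byte-deterministic.
#'
#' @param spectrum an `nmr_spectrum`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  writeLines(c("axis_hz\taxis_ppm\tintensity",
               sprintf("%.10g\t%.10g\t%.10g", spectrum$axis_hz,
                       spectrum$axis_ppm, spectrum$intensity)), path)
  invisible(path)
}

.aa3_to_1 <- function(aa3) {
  rc <- random_coil_shifts()
  out <- rc$aa[match(aa3, rc$aa3)]
  out
}

#' Write / read a shift table in a minimal NMR-STAR-style loop
#'
#' One `loop_` with the tags `_Atom_chem_shift.Seq_ID`, `.Comp_ID`
#' (three-letter code), `.Atom_ID` (`N`, `H`, `CA`, `CB`) and `.Val`
#' (3 decimals ppm), terminated by `stop_`. This is a documented subset,
#' not full NMR-STAR 3.1; the reader rejects malformed files with the
#' offending line number.
#'
#' @param table a `shift_table`.
#' @param path file path.
#' @return The path (write) or a `shift_table` (read).
#' @export
write_shift_star <- function(table, path) {
  stopifnot(inherits(table, "shift_table"))
  rc <- random_coil_shifts()
  aa3 <- rc$aa3[match(table$aa, rc$aa)]
  rows <- character(0)
  for (i in seq_len(nrow(table))) {
    for (atom in c("N", "H", "CA", "CB")) {
      val <- switch(atom, N = table$n_ppm[i], H = table$h_ppm[i],
                    CA = table$ca_ppm[i], CB = table$cb_ppm[i])
      if (!is.na(val))
        rows <- c(rows, sprintf("   %d %s %s %.3f", table$res[i], aa3[i],
                                atom, val))
    }
  }
  writeLines(c("loop_",
               "   _Atom_chem_shift.Seq_ID",
               "   _Atom_chem_shift.Comp_ID",
               "   _Atom_chem_shift.Atom_ID",
               "   _Atom_chem_shift.Val",
               rows, "stop_"), path)
  invisible(path)
}

#' @rdname write_shift_star
#' @export
read_shift_star <- function(path) {
  lines <- readLines(path)
  in_loop <- FALSE; seen_stop <- FALSE
  recs <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "_")) next
    if (line == "loop_") { in_loop <- TRUE; next }
    if (line == "stop_") { seen_stop <- TRUE; break }
    if (!in_loop)
      stop("line ", ln, ": data row outside loop_", call. = FALSE)
    f <- strsplit(line, "\\s+")[[1]]
    if (length(f) != 4L)
      stop("line ", ln, ": expected 4 fields, found ", length(f),
           call. = FALSE)
    val <- suppressWarnings(as.numeric(f[4]))
    res <- suppressWarnings(as.integer(f[1]))
    if (is.na(val) || is.na(res))
      stop("line ", ln, ": non-numeric Seq_ID or Val", call. = FALSE)
    recs[[length(recs) + 1L]] <- data.frame(res = res, aa3 = f[2],
                                            atom = f[3], val = val)
  }
  if (!seen_stop)
    stop("line ", length(lines), ": truncated file, no stop_ found",
         call. = FALSE)
  recs <- do.call(rbind, recs)
  if (is.null(recs)) stop("empty shift loop", call. = FALSE)
  res_ids <- sort(unique(recs$res))
  aa1 <- .aa3_to_1(recs$aa3[match(res_ids, recs$res)])
  if (anyNA(aa1))
    stop("unknown residue code(s): ",
         paste(unique(recs$aa3[is.na(.aa3_to_1(recs$aa3))]), collapse = ", "),
         call. = FALSE)
  pick <- function(res, atom) {
    v <- recs$val[recs$res == res & recs$atom == atom]
    if (length(v)) v[1] else NA_real_
  }
  tab <- data.frame(res = res_ids, aa = aa1,
                    n_ppm = vapply(res_ids, pick, 0, atom = "N"),
                    h_ppm = vapply(res_ids, pick, 0, atom = "H"),
                    ca_ppm = vapply(res_ids, pick, 0, atom = "CA"),
                    cb_ppm = vapply(res_ids, pick, 0, atom = "CB"))
  class(tab) <- c("shift_table", "data.frame")
  tab
}

#' Write / read a shift table as TSV
#'
#' Plain-column alternative to the STAR loop (3 decimals ppm).
#'
#' @inheritParams write_shift_star
#' @export
write_shift_tsv <- function(table, path) {
  stopifnot(inherits(table, "shift_table"))
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))
  writeLines(c("res\taa\tn_ppm\th_ppm\tca_ppm\tcb_ppm",
               sprintf("%d\t%s\t%s\t%s\t%s\t%s", table$res, table$aa,
                       fmt(table$n_ppm), fmt(table$h_ppm), fmt(table$ca_ppm),
                       fmt(table$cb_ppm))), path)
  invisible(path)
}

#' @rdname write_shift_tsv
#' @export
read_shift_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("res", "aa", "n_ppm", "h_ppm", "ca_ppm", "cb_ppm")
  if (!all(need %in% names(tab)))
    stop("shift TSV is missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  class(tab) <- c("shift_table", "data.frame")
  tab
}

#' Write / read peaks in Sparky list format
#'
#' Dialect: a header `Assignment w1 w2 w3` (or `w1 w2` for 2D lists),
#' assignment labels `<aa><res>N-HN-CA[i-1]` style built from the
#' simulation truth, and ppm columns ordered w1 = \eqn{^{15}}N,
#' w2 = \eqn{^1H}, w3 = \eqn{^{13}C}, 3 decimals.
#'
#' @param peaks a peak data frame.
#' @param path file path.
#' @return The path (write) or a data frame (read).
#' @export
write_sparky_list <- function(peaks, path) {
  three_d <- !all(is.na(peaks$c_ppm))
  label <- sprintf("R%dN-HN-%s%s", peaks$res_amide,
                   ifelse(is.na(peaks$atom), "", peaks$atom),
                   ifelse(is.na(peaks$res_c), "",
                          sprintf("[%d]", peaks$res_c)))
  if (three_d) {
    lines <- c(sprintf("%-22s %8s %8s %8s", "Assignment", "w1", "w2", "w3"),
               sprintf("%-22s %8.3f %8.3f %8.3f", label, peaks$n_ppm,
                       peaks$h_ppm, ifelse(is.na(peaks$c_ppm), 0,
                                           peaks$c_ppm)))
  } else {
    lines <- c(sprintf("%-22s %8s %8s", "Assignment", "w1", "w2"),
               sprintf("%-22s %8.3f %8.3f", label, peaks$n_ppm,
                       peaks$h_ppm))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sparky_list
#' @export
read_sparky_list <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^\\s*Assignment", lines[1]))
    stop("line 1: not a Sparky list (missing Assignment header)",
         call. = FALSE)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  f <- strsplit(trimws(body), "\\s+")
  nfield <- lengths(f)
  if (length(unique(nfield)) != 1L)
    stop("line ", 1 + which(nfield != nfield[1])[1],
         ": inconsistent column count", call. = FALSE)
  out <- data.frame(assignment = vapply(f, `[`, "", 1),
                    w1 = as.numeric(vapply(f, `[`, "", 2)),
                    w2 = as.numeric(vapply(f, `[`, "", 3)))
  if (nfield[1] >= 4L) out$w3 <- as.numeric(vapply(f, `[`, "", 4))
  out
}

#' Write a peak list as TSV
#'
#' All simulator columns, tab-separated, shifts at 3 decimals.
#'
#' @inheritParams write_sparky_list
#' @export
write_peaks_tsv <- function(peaks, path) {
  out <- peaks
  for (cl in c("h_ppm", "n_ppm", "c_ppm"))
    out[[cl]] <- round(out[[cl]], 3)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
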