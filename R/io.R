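# Record I/O: the package's plain-text fixture format (CSV + JSON sidecar +
# manifest) and a minimal reader for WFDB-format CTG recordings
# (header + 16-bit signal files, as used by the public intrapartum database).

#' Write a CTG record in the fixture format
#'
#' One delimited-text file per record with columns `t_sec,fhr,uc`, plus a JSON
#' sidecar holding the identifier, metadata, label and sample rate.  Unknown
#' sidecar keys read by [read_fixture()] are preserved on rewrite.
#'
#' @param record a [ctg_record()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(record$record_id, ".csv"))
  js <- file.path(dir, paste0(record$record_id, ".json"))
  t_sec <- (seq_along(record$fhr) - 1) / record$sample_rate
  utils::write.csv(data.frame(t_sec = t_sec, fhr = record$fhr, uc = record$uc),
                   csv, row.names = FALSE)
  side <- c(list(record_id = record$record_id,
                 metadata = unclass(record$metadata),
                 label = record$label,
                 sample_rate = record$sample_rate),
            record$extra %||% list())
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(c(csv = csv, json = js))
}

#' Read a CTG record from the fixture format
#'
#' @param csv_path path to the record's `.csv`; the sidecar is looked up next
#'   to it.
#' @export
read_fixture <- function(csv_path) {
  js <- sub("\\.csv$", ".json", csv_path)
  if (!file.exists(csv_path) || !file.exists(js)) {
    stop("fixture files missing: ", csv_path, call. = FALSE)
  }
  tab <- utils::read.csv(csv_path)
  side <- jsonlite::read_json(js, simplifyVector = TRUE)
  md <- side$metadata
  rec <- ctg_record(side$record_id, tab$fhr, tab$uc,
                    maternal_metadata(md$age %||% NA, md$gravidity %||% NA,
                                      md$parity %||% NA, md$diabetes %||% NA),
                    side$label, side$sample_rate)
  extra <- side[setdiff(names(side),
                        c("record_id", "metadata", "label", "sample_rate"))]
  if (length(extra)) rec$extra <- extra
  rec
}

#' Write a dataset of records plus a manifest
#'
#' @param records list of `ctg_record`.
#' @param dir output directory.
#' @param splits optional named index list (e.g. from [stratified_split()])
#'   recorded as split assignments in the manifest.
#' @return the manifest path.
#' @export
write_fixture_dataset <- function(records, dir, splits = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in records) write_fixture(r, dir)
  assign_split <- rep(NA_character_, length(records))
  if (!is.null(splits)) {
    for (nm in names(splits)) assign_split[splits[[nm]]] <- nm
  }
  manifest <- list(records = lapply(seq_along(records), function(i) {
    r <- records[[i]]
    list(record_id = r$record_id, csv = paste0(r$record_id, ".csv"),
         json = paste0(r$record_id, ".json"), label = r$label,
         split = assign_split[i])
  }))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, na = "null")
  path
}

#' Read a dataset from a manifest
#'
#' @param manifest_path path to `manifest.json`.
#' @return list of records; the manifest's split assignments (if any) are
#'   attached as the `"splits"` attribute.
#' @export
read_fixture_dataset <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  dir <- dirname(manifest_path)
  records <- lapply(man$records, function(e) read_fixture(file.path(dir, e$csv)))
  splits <- list()
  for (i in seq_along(man$records)) {
    sp <- man$records[[i]]$split
    if (!is.null(sp) && !is.na(sp)) splits[[sp]] <- c(splits[[sp]], i)
  }
  if (length(splits)) attr(records, "splits") <- splits
  records
}

# ---- WFDB ------------------------------------------------------------------

default_wfdb_aliases <- function() {
  list(age = c("Age"), gravidity = c("Gravidity", "Grav"),
       parity = c("Parity", "Par"), diabetes = c("Diabetes", "Diab"),
       second_stage = c("Pos. II.st.", "Pos. II. st.", "PosIIst"))
}

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  comments <- lines[startsWith(trimws(lines), "#")]
  body <- lines[!startsWith(trimws(lines), "#")]
  if (length(body) < 2) stop("malformed WFDB header: ", hea_path, call. = FALSE)
  rec_tok <- strsplit(trimws(body[1]), "\\s+")[[1]]
  if (length(rec_tok) < 4) stop("malformed WFDB record line", call. = FALSE)
  n_sig <- as.integer(rec_tok[2])
  fs <- as.numeric(sub("/.*$", "", rec_tok[3]))
  n_samp <- as.integer(rec_tok[4])
  sig <- lapply(body[1 + seq_len(n_sig)], function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    fmt <- sub("[x:+].*$", "", tok[2])
    gain_tok <- tok[3]
    units <- if (grepl("/", gain_tok)) sub("^.*/", "", gain_tok) else NA_character_
    gb <- sub("/.*$", "", gain_tok)
    baseline <- if (grepl("\\(", gb)) as.numeric(sub("^.*\\((-?[0-9]+)\\).*$", "\\1", gb)) else NA_real_
    gain <- as.numeric(sub("\\(.*$", "", gb))
    # token order: file format gain adcres adczero initval checksum blocksize desc
    adc_zero <- if (length(tok) >= 5) as.numeric(tok[5]) else 0
    desc <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ") else ""
    list(file = tok[1], format = fmt,
         gain = if (is.finite(gain) && gain != 0) gain else 200,
         baseline = if (is.finite(baseline)) baseline else adc_zero,
         units = units, description = desc)
  })
  meta <- list()
  for (cm in comments) {
    m <- regmatches(cm, regexec("^#\\s*(.*\\S)\\s+(-?[0-9.]+)\\s*$", cm))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- as.numeric(m[3])
  }
  list(record = rec_tok[1], n_sig = n_sig, fs = fs, n_samples = n_samp,
       signals = sig, comments = meta)
}

#' Read a WFDB-format CTG recording
#'
#' Minimal reader for two-channel 4 Hz CTG records stored as a WFDB header
#' (`.hea`) plus a format-16 (16-bit little-endian) signal file.  The FHR
#' channel is identified by its `bpm` units (or an FHR description); the
#' other channel is taken as UC.  Maternal variables and the second-stage
#' position marker are parsed from header comment lines through a
#' configurable alias map; absent fields are returned as missing.
#'
#' @param path record path with or without the `.hea` extension.
#' @param aliases alias map, see `default_wfdb_aliases()`.
#' @return a `raw_recording`: `record_id`, `fhr`, `uc`, `sample_rate`,
#'   `header_metadata` (all parsed comment values), `metadata`
#'   (a [maternal_metadata()]) and `stage1_end` (sample index or `NA`).
#' @export
read_wfdb_record <- function(path, aliases = default_wfdb_aliases()) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("header not found: ", hea, call. = FALSE)
  hd <- parse_wfdb_header(hea)
  if (hd$n_sig != 2) {
    stop(sprintf("expected a 2-channel CTG record, found %d signals", hd$n_sig),
         call. = FALSE)
  }
  fmts <- vapply(hd$signals, function(s) s$format, character(1))
  if (!all(fmts == "16")) {
    stop("only WFDB signal format 16 is supported (found: ",
         paste(unique(fmts), collapse = ", "), ")", call. = FALSE)
  }
  dat <- file.path(dirname(hea), hd$signals[[1]]$file)
  if (!file.exists(dat)) stop("signal file not found: ", dat, call. = FALSE)
  raw_n <- file.info(dat)$size %/% 2L
  adc <- readBin(dat, "integer", n = raw_n, size = 2L, signed = TRUE,
                 endian = "little")
  n <- min(hd$n_samples, length(adc) %/% 2L)
  adc <- matrix(adc[seq_len(2L * n)], nrow = 2L)   # interleaved by sample
  chan <- lapply(1:2, function(k) {
    s <- hd$signals[[k]]
    (adc[k, ] - s$baseline) / s$gain
  })
  is_fhr <- vapply(hd$signals, function(s) {
    isTRUE(grepl("bpm", s$units %||% "", ignore.case = TRUE)) ||
      grepl("FHR", s$description, ignore.case = TRUE)
  }, logical(1))
  fhr_idx <- if (any(is_fhr)) which(is_fhr)[1] else 1L
  uc_idx <- setdiff(1:2, fhr_idx)

  lookup <- function(keys) {
    for (k in keys) if (!is.null(hd$comments[[k]])) return(hd$comments[[k]])
    NA_real_
  }
  md <- maternal_metadata(lookup(aliases$age), lookup(aliases$gravidity),
                          lookup(aliases$parity), lookup(aliases$diabetes))
  structure(list(record_id = hd$record, fhr = chan[[fhr_idx]],
                 uc = chan[[uc_idx]], sample_rate = hd$fs,
                 header_metadata = hd$comments, metadata = md,
                 stage1_end = lookup(aliases$second_stage)),
            class = "raw_recording")
}

#' Samples in an analysis window
#'
#' @param minutes window duration (default 30 minutes).
#' @param hz sampling rate (default 4 Hz).
#' @return the sample count (7200 at the defaults).
#' @export
segment_samples <- function(minutes = 30, hz = 4) {
  as.integer(round(minutes * 60 * hz))
}

#' Extract the analysis segment from a raw recording
#'
#' Takes the `segment_length` samples ending at `stage1_end` (the end of the
#' first stage of labor) or, when no marker is available, at the recording
#' end.
#'
#' @param rec a `raw_recording` from [read_wfdb_record()].
#' @param stage1_end sample index (1-based, inclusive) of the first-stage end;
#'   `NULL`/`NA` falls back to the recording's own marker, then to its end.
#' @param segment_length samples to keep (default 7200 = 30 min at 4 Hz).
#' @param label optional 0/1 label to attach (`NA` = unlabeled).
#' @return a [ctg_record()].
#' @export
select_segment <- function(rec, stage1_end = NULL, segment_length = 7200L,
                           label = NA_integer_) {
  n <- length(rec$fhr)
  end <- stage1_end %||% rec$stage1_end
  if (is.null(end) || is.na(end)) end <- n
  end <- as.integer(end)
  start <- end - as.integer(segment_length) + 1L
  if (start < 1L || end > n) {
    stop(sprintf("record ineligible: needs %d samples ending at %d, has %d",
                 segment_length, end, n), call. = FALSE)
  }
  ctg_record(rec$record_id, rec$fhr[start:end], rec$uc[start:end],
             rec$metadata, label, rec$sample_rate)
}
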