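#' Read a physiological record from disk
#'
#' `csv` is the canonical interchange format: a `t,v` header, times in
#' seconds from record start, decimal points, UTF-8, with channel metadata
#' in a JSON sidecar named like the data file with extension `.json`
#' (`{channel, unit, domain_min, domain_max, fs_nominal, record_id,
#' person_id}`). `wfdb` reads a minimal WFDB header/signal pair
#' (`.hea` plus 16-bit little-endian `.dat`), converting ADC units to
#' physical units via the declared gain and baseline. Validation is
#' deferred: the result is a raw `tc_sample_seq`; call [validate_record()]
#' or [check_continuity()] on it.
#'
#' @param path path to the `.csv` file or the WFDB record name or `.hea`
#'   file.
#' @param format `"csv"` or `"wfdb"`.
#' @return a `tc_sample_seq`.
#' @export
read_record <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv") return(.read_csv_record(path))
  .read_wfdb_record(path)
}

.sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

.read_csv_record <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("t", "v") %in% names(df)))
    stop("format error in ", path, ": expected header 't,v'",
         call. = FALSE)
  t <- suppressWarnings(as.numeric(df$t))
  v <- suppressWarnings(as.numeric(df$v))
  bad <- which(is.na(t) | (is.na(v) & df$v != "" & toupper(df$v) != "NA"))
  if (length(bad))
    stop("format error in ", path, ": non-numeric field at data line ",
         bad[1], call. = FALSE)
  meta <- list(channel = "unknown", unit = "unknown",
               domain_min = -Inf, domain_max = Inf,
               fs_nominal = NA, record_id = sub("\\.csv$", "",
                                                basename(path)),
               person_id = NA)
  sp <- .sidecar_path(path)
  if (file.exists(sp)) {
    meta <- utils::modifyList(meta, jsonlite::read_json(sp,
                                                        simplifyVector = TRUE))
  } else {
    warning("no metadata sidecar for ", path, ": unit set to 'unknown'",
            call. = FALSE)
  }
  tc_sample_seq(t, v, channel = meta$channel, unit = meta$unit,
                domain = c(as.numeric(meta$domain_min),
                           as.numeric(meta$domain_max)),
                fs_nominal = as.numeric(meta$fs_nominal),
                record_id = meta$record_id,
                person_id = as.character(meta$person_id))
}

#' Write a record to disk
#'
#' `csv` writes are lossless: floats are serialized with 17 significant
#' digits, which round-trips IEEE doubles bit-exactly, and the metadata
#' sidecar is written next to the file. `wfdb` export quantizes values by
#' the declared gain (default 200 ADC units per physical unit, i.e. a
#' 0.005 mV step for ECG); the quantization step is reported in a message.
#'
#' @param rec a `tc_record` (or `tc_sample_seq`).
#' @param path output path (`.csv`, or WFDB record name without
#'   extension).
#' @param format `"csv"` or `"wfdb"`.
#' @param gain WFDB ADC gain (units per physical unit).
#' @return the path, invisibly.
#' @export
write_record <- function(rec, path, format = c("csv", "wfdb"),
                         gain = 200) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "tc_sample_seq"))
  if (!length(rec$t)) stop("refusing to write an empty record",
                           call. = FALSE)
  if (format == "csv") {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines("t,v", con)
    writeLines(paste(sprintf("%.17g", rec$t),
                     ifelse(is.na(rec$v), "NA", sprintf("%.17g", rec$v)),
                     sep = ","), con)
    jsonlite::write_json(
      list(channel = rec$channel, unit = rec$unit,
           domain_min = rec$domain[1], domain_max = rec$domain[2],
           fs_nominal = rec$fs_nominal, record_id = rec$record_id,
           person_id = rec$person_id),
      .sidecar_path(path), auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(path))
  }
  .write_wfdb_record(rec, path, gain)
}

# Minimal WFDB support, written by hand: no WFDB reader/writer ships with
# the available R stack. Header (.hea): record line "name nsig fs nsamp",
# one signal line "file format gain(baseline)/unit adcres adczero init
# checksum blocksize description". Signal (.dat): format 16, 16-bit
# little-endian two's-complement ADC counts.
.write_wfdb_record <- function(rec, path, gain = 200) {
  st <- classify_step_time(rec)
  if (st$classification != "equidistant")
    warning("WFDB stores an equidistant grid; variable step times are ",
            "approximated by the mean sampling rate", call. = FALSE)
  fs <- 1 / st$mean_dt
  base <- sub("\\.hea$", "", path)
  name <- basename(base)
  adc <- as.integer(pmax(-32768, pmin(32767, round(rec$v * gain))))
  adc[is.na(rec$v)] <- -32768L # WFDB invalid-sample marker
  message(sprintf("wfdb export: gain %g -> quantization step %g %s",
                  gain, 1 / gain, rec$unit))
  writeLines(c(
    sprintf("%s 1 %.12g %d", name, fs, length(adc)),
    sprintf("%s.dat 16 %g(0)/%s 16 0 %d 0 0 %s",
            name, gain, rec$unit, adc[1], rec$channel)),
    paste0(base, ".hea"))
  writeBin(adc, paste0(base, ".dat"), size = 2, endian = "little")
  invisible(base)
}

.read_wfdb_record <- function(path) {
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stop("no such WFDB header: ", hea, call. = FALSE)
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines)]
  rl <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rl) < 4) stop("format error in ", hea, ": bad record line",
                           call. = FALSE)
  fs <- as.numeric(rl[3]); nsamp <- as.integer(rl[4])
  sl <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  spec <- regmatches(sl[3],
                     regexec("^([-0-9.eE+]+)(\\(([-0-9.]+)\\))?(/(.*))?$",
                             sl[3]))[[1]]
  gain <- as.numeric(spec[2])
  baseline <- if (nzchar(spec[4])) as.numeric(spec[4]) else 0
  unit <- if (nzchar(spec[6])) spec[6] else "unknown"
  adc <- readBin(paste0(base, ".dat"), "integer", n = nsamp, size = 2,
                 endian = "little", signed = TRUE)
  v <- (adc - baseline) / gain
  v[adc == -32768L] <- NA_real_
  channel <- if (length(sl) >= 9) paste(sl[9:length(sl)], collapse = " ")
  else "unknown"
  cd <- tryCatch(channel_defaults(channel), error = function(e)
    list(domain = c(-Inf, Inf)))
  tc_sample_seq(seq(0, by = 1 / fs, length.out = nsamp), v,
                channel = channel, unit = unit, domain = cd$domain,
                fs_nominal = fs, record_id = basename(base))
}

#' Write a whole database as CSV records
#'
#' @param db a `tc_database`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_database <- function(db, dir) {
  stopifnot(inherits(db, "tc_database"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(db$records))
    write_record(db$records[[id]], file.path(dir, paste0(id, ".csv")))
  invisible(dir)
}

#' Read a directory of CSV records as a database
#'
#' @param dir directory holding `.csv` files written by
#'   [write_database()].
#' @param validate validate each record (default `TRUE`).
#' @return a `tc_database`.
#' @export
read_database <- function(dir, validate = TRUE) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no .csv records in ", dir, call. = FALSE)
  recs <- lapply(files, read_record)
  if (validate) recs <- lapply(recs, validate_record)
  tc_database(recs)
}
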