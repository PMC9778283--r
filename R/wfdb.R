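# Minimal WFDB-compatible I/O: header (.hea), format-16 signal (.dat) and
# MIT-format binary annotations. Covers what the synthetic writer emits and
# what PhysioNet distributes for the databases this package targets (format
# 16, single- or multi-lead, standard annotation codes). Not a full WFDB
# implementation.

# symbol <-> MIT annotation code (subset)
wfdb_ann_codes <- function() {
  c("N" = 1L, "V" = 5L, "A" = 8L, "p" = 24L, "t" = 27L, "u" = 29L,
    "(" = 39L, ")" = 40L)
}

#' Write a synthetic record as WFDB-compatible files
#'
#' Emits `<record>.hea` (header), `<record>.dat` (format-16 signal),
#' `<record>.atr` (MIT-format annotations mirroring the reference annotation
#' style: `(`, `p`, `)` around the P wave, `(`, beat symbol, `)` around the
#' QRS, `t`, `)` for the T wave -- T onset is not annotated) and
#' `<record>_truth.csv` (per-beat fiducial truth table).
#'
#' @param record A `synthetic_record` from [generate_record()].
#' @param dir Output directory (created if needed).
#' @param record_id Record name used for the file stem.
#' @param gain ADC units per mV used to quantize the signal.
#' @param beat_symbol Annotation symbol for the beat type (default `"N"`).
#' @param leads Lead names; the synthetic signal is duplicated across leads so
#'   that two-lead processing paths are exercised.
#'
#' @return Invisibly, the record path stem.
#' @export
write_wfdb <- function(record, dir, record_id = "synth01", gain = 2000,
                       beat_symbol = "N", leads = c("MLII", "V5")) {
  stopifnot(inherits(record, "synthetic_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(record$signal)
  nsig <- length(leads)
  adc <- as.integer(round(record$signal * gain))
  adc <- pmin(pmax(adc, -32768L), 32767L)
  dat <- file.path(dir, paste0(record_id, ".dat"))
  # interleave identical copies per lead
  writeBin(rep(adc, each = nsig), dat, size = 2, endian = "little")
  hea <- c(
    paste(record_id, nsig, record$fs, n),
    vapply(leads, function(ld) {
      paste(paste0(record_id, ".dat"), 16, paste0(gain, "/mV"), 16, 0, 0, 0, 0, ld)
    }, character(1))
  )
  writeLines(hea, file.path(dir, paste0(record_id, ".hea")))

  truth <- record$truth
  ann <- dplyr::bind_rows(lapply(seq_len(nrow(truth)), function(i) {
    r <- truth[i, ]
    tibble(
      sample = c(r$p_on, r$p_peak, r$p_off, r$qrs_on, r$r_peak, r$qrs_off,
                 r$t_peak, r$t_off),
      symbol = c("(", "p", ")", "(", beat_symbol, ")", "t", ")")
    )
  }))
  ann <- dplyr::arrange(ann, .data$sample)
  write_wfdb_annotations(ann, file.path(dir, paste0(record_id, ".atr")))
  utils::write.csv(truth, file.path(dir, paste0(record_id, "_truth.csv")),
                   row.names = FALSE)
  invisible(file.path(dir, record_id))
}

# MIT annotation format: 16-bit little-endian words, high 6 bits = code, low
# 10 bits = time increment from the previous annotation. Increments >= 1024
# use a SKIP word (code 59) followed by a 32-bit interval in PDP-11 byte
# order. A zero word terminates the stream. Samples here are 1-based; times
# on disk are 0-based.
write_wfdb_annotations <- function(ann, path) {
  codes <- wfdb_ann_codes()
  unknown <- setdiff(unique(ann$symbol), names(codes))
  if (length(unknown) > 0) {
    stop_ecg(paste0("unsupported annotation symbol(s): ",
                    paste(unknown, collapse = ", ")), "bad_annotation")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(v) {  # writeBin size-2 wants the signed representation
    v <- as.integer(v)
    if (v > 32767L) v <- v - 65536L
    writeBin(v, con, size = 2, endian = "little")
  }
  word <- function(code, delta) u16(bitwOr(bitwShiftL(code, 10L), delta))
  prev <- 0L
  for (i in seq_len(nrow(ann))) {
    t0 <- ann$sample[i] - 1L
    delta <- t0 - prev
    if (delta < 0) stop_ecg("annotation samples must be non-decreasing.", "bad_annotation")
    if (delta >= 1024L) {
      word(59L, 0L)  # SKIP
      u16(delta %/% 65536L)
      u16(delta %% 65536L)
      delta <- 0L
    }
    word(codes[[ann$symbol[i]]], delta)
    prev <- t0
  }
  word(0L, 0L)
  invisible(path)
}

#' Read a WFDB record (header + format-16 signal)
#'
#' @param dir Directory containing the files.
#' @param record_id Record name (file stem).
#'
#' @return An object of class `ecg_record`: list with `record_id`, `signals`
#'   (samples x leads matrix, mV), `fs` and `leads`.
#' @export
read_wfdb_record <- function(dir, record_id) {
  hea_path <- file.path(dir, paste0(record_id, ".hea"))
  if (!file.exists(hea_path)) stop_ecg(paste0("no header: ", hea_path), "io")
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines)]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(hdr[2])
  fs <- as.numeric(strsplit(hdr[3], "/")[[1]][1])
  n <- as.integer(hdr[4])
  sig_lines <- lines[2:(1 + nsig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    fmt <- sub("x.*$", "", f[2])
    gain_field <- sub("\\(.*\\)", "", strsplit(f[3], "/")[[1]][1])
    gain <- as.numeric(gain_field)
    if (is.na(gain) || gain == 0) gain <- 200  # WFDB default gain
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else NA_character_
    list(file = f[1], fmt = fmt, gain = gain, desc = desc)
  }
  sigs <- lapply(sig_lines, parse_sig)
  if (!all(vapply(sigs, function(s) s$fmt == "16", logical(1)))) {
    stop_ecg("only format-16 signals are supported.", "io")
  }
  dat_path <- file.path(dir, sigs[[1]]$file)
  raw <- readBin(dat_path, integer(), n = n * nsig, size = 2,
                 endian = "little", signed = TRUE)
  mat <- matrix(raw, ncol = nsig, byrow = TRUE)
  for (j in seq_len(nsig)) mat[, j] <- mat[, j] / sigs[[j]]$gain
  leads <- vapply(sigs, function(s) s$desc %||% "", character(1))
  leads[leads == "" | is.na(leads)] <- paste0("sig", seq_len(nsig))[leads == "" | is.na(leads)]
  structure(
    list(record_id = record_id, signals = mat, fs = fs, leads = leads),
    class = "ecg_record"
  )
}

#' Read MIT-format binary annotations
#'
#' @param dir Directory containing the annotation file.
#' @param record_id Record name (file stem).
#' @param ext Annotation file extension (default `"atr"`).
#'
#' @return A tibble with columns `sample` (1-based) and `symbol`.
#' @export
read_wfdb_annotations <- function(dir, record_id, ext = "atr") {
  path <- file.path(dir, paste0(record_id, ".", ext))
  if (!file.exists(path)) stop_ecg(paste0("no annotation file: ", path), "io")
  nbytes <- file.info(path)$size
  words <- readBin(path, integer(), n = nbytes / 2, size = 2,
                   endian = "little", signed = FALSE)
  codes <- wfdb_ann_codes()
  sym_of <- stats::setNames(names(codes), codes)
  samples <- integer(0)
  symbols <- character(0)
  t0 <- 0L
  i <- 1L
  while (i <= length(words)) {
    w <- words[i]
    if (w == 0L) break
    code <- w %/% 1024L
    delta <- w %% 1024L
    if (code == 59L) {  # SKIP: 32-bit interval follows, PDP-11 order
      hi <- words[i + 1L]; lo <- words[i + 2L]
      t0 <- t0 + hi * 65536L + lo
      i <- i + 3L
      next
    }
    if (code >= 60L) {  # NUM/SUB/CHN/AUX modifiers: skip payload-less ones
      i <- i + 1L
      next
    }
    t0 <- t0 + delta
    if (as.character(code) %in% names(sym_of)) {
      samples <- c(samples, t0 + 1L)
      symbols <- c(symbols, sym_of[[as.character(code)]])
    }
    i <- i + 1L
  }
  tibble(sample = samples, symbol = symbols)
}
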