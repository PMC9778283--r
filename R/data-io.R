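# Reading PhysioNet-style record sets and applying the record/beat filters
# used when assembling delineation training data.

BEAT_SYMBOLS <- c("N", "V", "A")

#' Group an annotation stream into per-beat fiducial positions
#'
#' The reference annotation style marks each beat as `( p )` around the P
#' wave, `(` beat-symbol `)` around the QRS, and `t )` for the T wave (T
#' onset unannotated). This walks the stream, anchors beats at their beat
#' symbols, and associates the surrounding wave annotations; fiducials absent
#' from a beat come back as `NA`.
#'
#' @param ann Tibble with columns `sample` and `symbol`, ordered by sample.
#'
#' @return Tibble with columns `beat`, `beat_symbol` and the eight fiducial
#'   columns of [fiducial_names()] (1-based samples, `NA` when unannotated).
#' @export
extract_beat_fiducials <- function(ann) {
  ann <- dplyr::arrange(ann, .data$sample)
  n <- nrow(ann)
  r_idx <- which(ann$symbol %in% BEAT_SYMBOLS)
  empty <- function() {
    out <- tibble(beat = integer(0), beat_symbol = character(0))
    for (nm in fiducial_names()) out[[nm]] <- integer(0)
    out
  }
  if (length(r_idx) == 0) return(empty())
  # a wave symbol owns the '(' directly before it and the ')' directly after
  on_of <- function(i) {
    if (i > 1 && ann$symbol[i - 1] == "(") ann$sample[i - 1] else NA_integer_
  }
  off_of <- function(i) {
    if (i < n && ann$symbol[i + 1] == ")") ann$sample[i + 1] else NA_integer_
  }
  p_idx <- which(ann$symbol == "p")
  t_idx <- which(ann$symbol == "t")
  r_samples <- ann$sample[r_idx]
  rows <- lapply(seq_along(r_idx), function(b) {
    ri <- r_idx[b]
    r_s <- r_samples[b]
    prev_r <- if (b > 1) r_samples[b - 1] else -Inf
    next_r <- if (b < length(r_idx)) r_samples[b + 1] else Inf
    # P wave: the last p peak strictly between the previous R and this R
    pi <- utils::tail(p_idx[ann$sample[p_idx] > prev_r &
                              ann$sample[p_idx] < r_s], 1)
    # T wave: the first t peak strictly between this R and the next R
    ti <- t_idx[ann$sample[t_idx] > r_s & ann$sample[t_idx] < next_r][1]
    tibble(
      beat = b,
      beat_symbol = ann$symbol[ri],
      p_on = if (length(pi)) on_of(pi) else NA_integer_,
      p_peak = if (length(pi)) ann$sample[pi] else NA_integer_,
      p_off = if (length(pi)) off_of(pi) else NA_integer_,
      qrs_on = on_of(ri),
      r_peak = r_s,
      qrs_off = off_of(ri),
      t_peak = if (length(ti) && !is.na(ti)) ann$sample[ti] else NA_integer_,
      t_off = if (length(ti) && !is.na(ti)) off_of(ti) else NA_integer_
    )
  })
  dplyr::bind_rows(rows)
}

#' Keep only records annotated with all eight fiducial types
#'
#' A record is retained when each of the eight fiducial types occurs at least
#' once in at least one annotated beat. Applying the filter twice changes
#' nothing (it is idempotent).
#'
#' @param records List of entries, each a list with elements `record` (an
#'   `ecg_record`) and `ann` (annotation tibble).
#'
#' @return The filtered list (possibly empty).
#' @export
filter_records <- function(records) {
  keep <- vapply(records, function(entry) {
    fid <- extract_beat_fiducials(entry$ann)
    if (nrow(fid) == 0) return(FALSE)
    all(vapply(fiducial_names(), function(nm) any(!is.na(fid[[nm]])), logical(1)))
  }, logical(1))
  records[keep]
}

#' R-peak sample indices of beats of a given type
#'
#' @param record An `ecg_record` (unused beyond its identity; present so the
#'   record/annotation pair travels together).
#' @param ann Annotation tibble (`sample`, `symbol`).
#' @param type Beat type symbol, e.g. `"N"`.
#'
#' @return Integer vector of R-peak sample indices in temporal order; empty
#'   for an unknown type.
#' @export
select_beats_by_type <- function(record, ann, type = "N") {
  ann <- dplyr::arrange(ann, .data$sample)
  as.integer(ann$sample[ann$symbol == type])
}

#' Read every WFDB record in a directory
#'
#' Record names are discovered from `*.hea` files; each entry pairs the
#' signal with its annotations (records without a readable annotation file
#' are skipped).
#'
#' @param dir Directory of WFDB files.
#' @param ann_ext Annotation extension (default `"atr"`).
#'
#' @return List of `list(record = , ann = )` entries.
#' @export
read_record_set <- function(dir, ann_ext = "atr") {
  heas <- list.files(dir, pattern = "\\.hea$", full.names = FALSE)
  ids <- sub("\\.hea$", "", heas)
  out <- lapply(ids, function(id) {
    ann <- tryCatch(read_wfdb_annotations(dir, id, ann_ext),
                    error = function(e) NULL)
    if (is.null(ann)) return(NULL)
    list(record = read_wfdb_record(dir, id), ann = ann)
  })
  out[!vapply(out, is.null, logical(1))]
}
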