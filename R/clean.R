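#' Clean a single read: N removal, 3' quality trimming, length filter
#'
#' A read containing any undetermined base (`N`) is discarded outright (the
#' N check applies to the untrimmed sequence). Otherwise bases are removed
#' consecutively from the 3' end while the terminal base quality is below
#' `min_q`, stopping at the first base with quality `>= min_q` (bases of low
#' quality further 5' are kept). The read is kept only if the trimmed length
#' is at least `min_len_keep` (default 21, i.e. strictly longer than 20).
#'
#' @param record list/row with `read_id`, `sequence`, `qualities` (quality
#'   string, phred+33).
#' @param min_q phred threshold below which terminal bases are trimmed.
#' @param min_len_keep minimum trimmed length to keep the read.
#' @return the cleaned record (same shape), or a `discarded_read` sentinel
#'   whose `cause` element is `"N"` or `"too_short"` (see [is_discarded()]).
#' @export
clean_read <- function(record, min_q = 10, min_len_keep = 21) {
  if (grepl("N", record$sequence, fixed = TRUE))
    return(structure(list(cause = "N"), class = "discarded_read"))
  q <- phred_scores(record$qualities)
  ok <- which(q >= min_q)
  keep_len <- if (length(ok)) max(ok) else 0L
  if (keep_len < min_len_keep)
    return(structure(list(cause = "too_short"), class = "discarded_read"))
  record$sequence <- substr(record$sequence, 1L, keep_len)
  record$qualities <- substr(record$qualities, 1L, keep_len)
  record
}

#' Was a read discarded by [clean_read()]?
#' @param x a [clean_read()] return value.
#' @return `TRUE` for the discard sentinel (whose `cause` element names the
#'   discard reason), `FALSE` for a kept record.
#' @export
is_discarded <- function(x) inherits(x, "discarded_read")

#' Clean a FASTQ file
#'
#' Applies [clean_read()] to every record and writes the kept reads.
#'
#' @param path_in input FASTQ.
#' @param path_out output FASTQ (kept, trimmed reads).
#' @param min_q,min_len_keep see [clean_read()].
#' @return a `cleaning_report` list: `input`, `kept`, `discarded_n`,
#'   `discarded_short`, `bases_trimmed` (3' bases removed from kept reads).
#'   Always `input == kept + discarded_n + discarded_short`.
#' @export
clean_fastq <- function(path_in, path_out, min_q = 10, min_len_keep = 21) {
  rec <- read_fastq(path_in)
  n <- nrow(rec)
  if (n == 0L) {
    write_fastq(rec, path_out)
    return(structure(list(input = 0L, kept = 0L, discarded_n = 0L,
                          discarded_short = 0L, bases_trimmed = 0L),
                     class = "cleaning_report"))
  }
  has_n <- grepl("N", rec$sequence, fixed = TRUE)
  keep_len <- vapply(rec$qualities, function(qs) {
    ok <- which(utf8ToInt(qs) - 33L >= min_q)
    if (length(ok)) max(ok) else 0L
  }, 0L, USE.NAMES = FALSE)
  kept <- !has_n & keep_len >= min_len_keep
  out <- rec[kept, , drop = FALSE]
  out$sequence <- substr(out$sequence, 1L, keep_len[kept])
  out$qualities <- substr(out$qualities, 1L, keep_len[kept])
  write_fastq(out, path_out)
  structure(list(
    input = n,
    kept = sum(kept),
    discarded_n = sum(has_n),
    discarded_short = sum(!has_n & keep_len < min_len_keep),
    bases_trimmed = as.integer(sum(nchar(rec$sequence[kept]) - keep_len[kept]))),
    class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(
    "cleaning_report: %d in, %d kept, %d with N, %d too short, %d bases trimmed\n",
    x$input, x$kept, x$discarded_n, x$discarded_short, x$bases_trimmed))
  invisible(x)
}
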