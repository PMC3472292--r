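#' Read a FASTQ file (Sanger/phred+33 qualities)
#'
#' @param path FASTQ file; may be empty.
#' @return data.frame with columns `read_id`, `sequence`, `qualities`
#'   (quality string, phred+33).
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(read_id = character(0), sequence = character(0),
                      qualities = character(0), stringsAsFactors = FALSE))
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  q <- as.character(S4Vectors::mcols(x)$qualities)
  s <- as.character(x)
  df <- data.frame(read_id = names(x), sequence = unname(s),
                   qualities = unname(q), stringsAsFactors = FALSE)
  bad <- nchar(df$sequence) != nchar(df$qualities)
  if (any(bad))
    stop("FASTQ record ", df$read_id[which(bad)[1]],
         ": sequence/quality length mismatch")
  df
}

#' Write FASTQ records (Sanger/phred+33 qualities)
#'
#' @param records data.frame as returned by [read_fastq()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  bad <- nchar(records$sequence) != nchar(records$qualities)
  if (any(bad))
    stop("FASTQ record ", records$read_id[which(bad)[1]],
         ": sequence/quality length mismatch")
  if (nrow(records) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  out <- character(4L * nrow(records))
  out[seq(1, length(out), 4)] <- paste0("@", records$read_id)
  out[seq(2, length(out), 4)] <- records$sequence
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- records$qualities
  writeLines(out, path)
  invisible(path)
}

#' Convert a phred+33 quality string to integer phred scores
#' @param qual quality string.
#' @return integer vector of per-base phred scores.
#' @export
phred_scores <- function(qual) {
  if (!nchar(qual)) return(integer(0))
  utf8ToInt(qual) - 33L
}

#' Convert integer phred scores to a phred+33 quality string
#' @param scores integer vector of phred scores.
#' @return quality string.
#' @export
phred_string <- function(scores) {
  if (!length(scores)) return("")
  intToUtf8(as.integer(scores) + 33L)
}
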