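#' Read a FASTQ file into a record table
#'
#' Strict 4-line-per-record parser. Qualities stay Phred+33 encoded in the
#' `qual` column; decode per-base scores with [phred_scores()]. Malformed
#' records (truncated record, id line not starting with `@`, quality length
#' differing from sequence length) raise an error naming the offending line.
#'
#' @param path FASTQ file path.
#' @return Data.frame with columns `id`, `seq`, `qual` (one row per record).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0)
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  if (n %% 4 != 0)
    stop(sprintf("truncated FASTQ record in %s: file ends at line %d (records are 4 lines)",
                 path, n))
  hdr <- lines[seq(1, n, by = 4)]
  seqs <- lines[seq(2, n, by = 4)]
  plus <- lines[seq(3, n, by = 4)]
  qual <- lines[seq(4, n, by = 4)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop(sprintf("malformed FASTQ header in %s at line %d: %s",
                 path, (bad[1] - 1L) * 4L + 1L, hdr[bad[1]]))
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop(sprintf("malformed FASTQ separator in %s at line %d",
                 path, (bad[1] - 1L) * 4L + 3L))
  bad <- which(nchar(qual) != nchar(seqs))
  if (length(bad))
    stop(sprintf("quality length differs from sequence length in %s at line %d",
                 path, (bad[1] - 1L) * 4L + 4L))
  ids <- sub("^@", "", sub("\\s.*$", "", hdr))
  data.frame(id = ids, seq = seqs, qual = qual, stringsAsFactors = FALSE)
}

#' Write records to FASTQ (Phred+33)
#'
#' @param records Record data.frame (`id`, `seq`, `qual`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(records))
    writeLines(as.vector(rbind(paste0("@", records$id), records$seq,
                               "+", records$qual)), con)
  invisible(path)
}

#' Write records to FASTA
#'
#' @param records Record data.frame (`id`, `seq`); qualities are dropped.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::DNAStringSet(records$seq)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param qual Character vector of quality strings.
#' @return List of integer vectors, one per input string.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

#' Quality-trim read 3' ends
#'
#' Two-step 3' trimming: (1) sliding-window cut — scanning from the 5' end,
#' the read is truncated before the first position at which the mean quality
#' of the window ending there (window size `window`, shorter at the start)
#' falls below `threshold`; (2) trailing bases with quality below `threshold`
#' are then removed. Never lengthens a read; may return empty records.
#'
#' @param records Record data.frame (`id`, `seq`, `qual`); qualities required.
#' @param threshold Minimum acceptable quality (default 20).
#' @param window Sliding-window size (default 4).
#' @return Record data.frame with trimmed `seq` and `qual`.
#' @export
quality_trim <- function(records, threshold = 20, window = 4) {
  stopifnot(all(c("seq", "qual") %in% names(records)))
  if (any(is.na(records$qual))) stop("quality_trim requires qualities")
  n <- nrow(records)
  if (n == 0) return(records)
  keep_len <- integer(n)
  for (i in seq_len(n)) {
    q <- as.integer(charToRaw(records$qual[i])) - 33L
    L <- length(q)
    if (L == 0) { keep_len[i] <- 0L; next }
    # running mean of window ending at each position (shorter at the start)
    cs <- cumsum(q)
    lo <- pmax(seq_len(L) - window + 1L, 1L)
    wmean <- (cs - c(0, cs)[lo]) / (seq_len(L) - lo + 1L)
    fail <- which(wmean < threshold)
    end <- if (length(fail)) fail[1] - 1L else L
    while (end > 0 && q[end] < threshold) end <- end - 1L
    keep_len[i] <- end
  }
  records$seq <- substr(records$seq, 1L, keep_len)
  records$qual <- substr(records$qual, 1L, keep_len)
  records
}

#' Merge paired-end reads by overlap
#'
#' The reverse read is reverse-complemented, then the overlap between the
#' forward suffix and the reverse-complement prefix is scanned over all
#' lengths from `min_overlap` up to the shorter read. The accepted overlap is
#' the one with the smallest mismatch fraction (ties broken towards the
#' longer overlap) provided that fraction is at most
#' `max_mismatch_fraction`; otherwise the pair is flagged unmerged.
#' Disagreeing overlap bases are resolved to the higher-quality base, ties to
#' the forward base. Merged quality takes the per-base maximum in the
#' overlap. Merged length always equals `nchar(fwd) + nchar(rev) − overlap`.
#'
#' @param fwd,rev Record data.frames of equal length, paired by row.
#' @param min_overlap Minimum acceptable overlap (default 20).
#' @param max_mismatch_fraction Maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @return List with `merged` (record data.frame with extra columns
#'   `overlap_length`, `mismatches_in_overlap`) and `unmerged` (data.frame
#'   `id`, `reason`).
#' @export
merge_pairs <- function(fwd, rev, min_overlap = 20,
                        max_mismatch_fraction = 0.1) {
  stopifnot(nrow(fwd) == nrow(rev))
  n <- nrow(fwd)
  empty_merged <- data.frame(id = character(0), seq = character(0),
                             qual = character(0), overlap_length = integer(0),
                             mismatches_in_overlap = integer(0),
                             stringsAsFactors = FALSE)
  if (n == 0)
    return(list(merged = empty_merged,
                unmerged = data.frame(id = character(0), reason = character(0),
                                      stringsAsFactors = FALSE)))
  if (any(nchar(fwd$seq) == 0) || any(nchar(rev$seq) == 0))
    stop("merge_pairs requires nonempty reads in both mates")
  rc_seq <- revcomp_chr(rev$seq)
  ov_tab <- best_overlaps(fwd$seq, rc_seq, as.integer(min_overlap),
                          max_mismatch_fraction)
  merged <- vector("list", n)
  unmerged <- vector("list", n)
  for (i in seq_len(n)) {
    best_o <- ov_tab[i, 1]
    best_m <- ov_tab[i, 2]
    if (best_o == 0L) {
      unmerged[[i]] <- data.frame(id = fwd$id[i], reason = "no_overlap",
                                  stringsAsFactors = FALSE)
      next
    }
    f <- charToRaw(fwd$seq[i])
    r <- charToRaw(rc_seq[i])
    fq <- as.integer(charToRaw(fwd$qual[i])) - 33L
    rq <- rev(as.integer(charToRaw(rev$qual[i])) - 33L)  # rc reverses quals
    lf <- length(f); lr <- length(r)
    o <- best_o
    fo <- (lf - o + 1L):lf
    ov <- f[fo]
    use_rev <- (ov != r[seq_len(o)]) & (rq[seq_len(o)] > fq[fo])
    ov[use_rev] <- r[seq_len(o)][use_rev]
    oq <- pmax(fq[fo], rq[seq_len(o)])
    seq_out <- rawToChar(c(f[seq_len(lf - o)], ov, r[(o + 1L):lr][seq_len(max(0L, lr - o))]))
    qual_out <- rawToChar(as.raw(c(fq[seq_len(lf - o)], oq,
                                   rq[(o + 1L):lr][seq_len(max(0L, lr - o))]) + 33L))
    merged[[i]] <- data.frame(id = fwd$id[i], seq = seq_out, qual = qual_out,
                              overlap_length = o, mismatches_in_overlap = best_m,
                              stringsAsFactors = FALSE)
  }
  merged <- merged[!vapply(merged, is.null, logical(1))]
  unmerged <- unmerged[!vapply(unmerged, is.null, logical(1))]
  list(merged = if (length(merged)) do.call(rbind, c(merged, make.row.names = FALSE)) else empty_merged,
       unmerged = if (length(unmerged)) do.call(rbind, c(unmerged, make.row.names = FALSE)) else
         data.frame(id = character(0), reason = character(0),
                    stringsAsFactors = FALSE))
}

#' Retain records strictly longer than a length cutoff
#'
#' The cutoff is exclusive: a record of exactly `min_exclusive` bases is
#' dropped. Input order is preserved and the operation is idempotent.
#'
#' @param records Record data.frame.
#' @param min_exclusive Exclusive minimum length (default 450).
#' @return Filtered record data.frame.
#' @export
length_filter <- function(records, min_exclusive = 450) {
  records[nchar(records$seq) > min_exclusive, , drop = FALSE]
}
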