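#' Create a named 5' UTR insert record
#'
#' Normalizes an insert sequence (RNA-style `U` is accepted and converted to
#' `T`), validates the alphabet, and derives length and GC fraction. Records
#' carry an orientation so reverse-complement ("inverse") controls can be
#' tracked against their forward partners.
#'
#' @param name Insert name.
#' @param sequence Nucleotide string over `A`, `C`, `G`, `T`/`U` (case
#'   insensitive).
#' @param orientation `"forward"` or `"inverse"`.
#' @return A one-row tibble: `name`, `sequence`, `orientation`, `length_nt`,
#'   `gc_fraction`.
#' @examples
#' insert_record("hHBB", "ACATTTGCTTCTGACACAAC")
#' @export
insert_record <- function(name, sequence,
                          orientation = c("forward", "inverse")) {
  orientation <- match.arg(orientation)
  seq <- chartr("u", "t", tolower(sequence))
  seq <- toupper(seq)
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0) {
    abort(sprintf("Invalid character '%s' at position %d of '%s'.",
                  substr(seq, bad, bad), bad, name))
  }
  n <- nchar(seq)
  if (n == 0) abort("Sequence must be non-empty.")
  gc <- sum(strsplit(seq, "")[[1]] %in% c("G", "C")) / n
  tibble::tibble(name = name, sequence = seq, orientation = orientation,
                 length_nt = n, gc_fraction = gc)
}

#' Reverse-complement (inverse) insert control
#'
#' Returns the reverse complement of an insert with its orientation flipped.
#' Because reverse complementation swaps A with T and G with C while
#' reversing order, the control preserves both length and GC content — the
#' identity that makes inverse inserts matched controls for length- and
#' GC-dependent effects while abolishing any sequence-specific activity.
#'
#' @param record A one-row tibble from [insert_record()].
#' @return The inverse [insert_record()] (applying it twice returns the
#'   original).
#' @examples
#' rec <- insert_record("x", "AAGG")
#' make_inverse(rec)$sequence # "CCTT"
#' @export
make_inverse <- function(record) {
  stopifnot(nrow(record) == 1)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(record$sequence)))
  insert_record(record$name, rc,
                orientation = if (record$orientation == "forward")
                  "inverse" else "forward")
}

#' Read and write insert FASTA files
#'
#' Thin FASTA wrappers returning/accepting the insert-record tibble layout.
#'
#' @param path FASTA file path.
#' @return `read_inserts()`: a tibble of [insert_record()]s.
#' @export
read_inserts <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  purrr::map2(names(set), as.character(set), insert_record) |>
    purrr::list_rbind()
}

#' @rdname read_inserts
#' @param records Insert-record tibble.
#' @export
write_inserts <- function(records, path) {
  set <- Biostrings::DNAStringSet(setNames(records$sequence, records$name))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Scan a 5' UTR for upstream AUGs and uORFs
#'
#' Reports every `ATG` in the UTR with its 0-based offset, its distance to
#' the main start codon (defined to begin immediately after the last UTR
#' base, so `distance = utr_length - offset`), and its reading frame
#' relative to the main ORF (`frame = distance mod 3`; frame 0 is in-frame
#' and would contribute to translation from the main AUG, frames 1/2 are
#' out-of-frame). A uAUG is flagged as a uORF when an in-frame stop codon
#' (`TAA`, `TAG`, `TGA`) lies fully within the UTR; uAUGs without such a
#' stop run into the main ORF and are classed as overlapping.
#'
#' @param utr Non-empty UTR sequence (`U` accepted).
#' @param max_report Optional cap on the number of uAUGs returned (5' most
#'   first).
#' @return A tibble per uAUG: `offset`, `distance_nt`, `frame`, `is_uorf`,
#'   `class` (`"uORF"`, `"overlapping"`); attribute `"frame_counts"` holds
#'   the tally by frame.
#' @examples
#' scan_uaugs("CCCATGCCC") # one in-frame uAUG
#' @export
scan_uaugs <- function(utr, max_report = NULL) {
  rec <- insert_record("utr", utr)
  seq <- rec$sequence
  n <- rec$length_nt
  offsets <- as.integer(gregexpr("ATG", seq, fixed = TRUE)[[1]])
  offsets <- offsets[offsets > 0] - 1L
  if (length(offsets) == 0) {
    out <- tibble::tibble(offset = integer(), distance_nt = integer(),
                          frame = integer(), is_uorf = logical(),
                          class = character())
    attr(out, "frame_counts") <- c(`0` = 0L, `1` = 0L, `2` = 0L)
    return(out)
  }
  stops <- c("TAA", "TAG", "TGA")
  has_stop <- vapply(offsets, function(off) {
    if (off + 3L > n - 3L) return(FALSE)
    pos <- seq(off + 3L, n - 3L, by = 3L)
    any(vapply(pos, function(p) substr(seq, p + 1L, p + 3L) %in% stops,
               logical(1)))
  }, logical(1))
  out <- tibble::tibble(
    offset = offsets,
    distance_nt = n - offsets,
    frame = (n - offsets) %% 3L,
    is_uorf = has_stop,
    class = ifelse(has_stop, "uORF", "overlapping")
  )
  if (!is.null(max_report)) out <- out[seq_len(min(nrow(out), max_report)), ]
  attr(out, "frame_counts") <-
    vapply(c("0", "1", "2"),
           function(f) sum(out$frame == as.integer(f)), integer(1))
  out
}

#' Nucleotide count of a transcript interval with exclusions
#'
#' Counts the bases covered by a 1-based inclusive transcript interval,
#' minus any excluded sub-intervals (e.g. a probe target region excluding an
#' isoform-specific intron). Exclusions must nest within the interval and be
#' pairwise disjoint.
#'
#' @param start,end 1-based inclusive interval bounds, `start <= end`.
#' @param exclusions Optional list of `c(start, end)` excluded sub-intervals.
#' @return The integer nucleotide count.
#' @examples
#' interval_nt_count(2078, 2591) # 514
#' interval_nt_count(1267, 1892, list(c(1581, 1753))) # 453
#' @export
interval_nt_count <- function(start, end, exclusions = list()) {
  if (start < 1 || start > end) {
    abort("Require 1 <= start <= end.")
  }
  if (length(exclusions) > 0) {
    ex <- do.call(rbind, lapply(exclusions, function(e) {
      stopifnot(length(e) == 2)
      if (e[1] < start || e[2] > end || e[1] > e[2]) {
        abort("Exclusions must nest within [start, end].")
      }
      e
    }))
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    if (nrow(ex) > 1 && any(ex[-1, 1] <= ex[-nrow(ex), 2])) {
      abort("Exclusions must be pairwise disjoint.")
    }
    excluded <- sum(ex[, 2] - ex[, 1] + 1)
  } else {
    excluded <- 0
  }
  as.integer((end - start + 1) - excluded)
}
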