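#' Promoter sequence anchored to a transcription start site
#'
#' A `promoter_record` holds a single promoter sequence (5'->3' top strand)
#' together with the position of its transcription start site (TSS). Promoter
#' coordinates follow the usual convention: the TSS base is +1, the base
#' immediately 5' of it is -1, and there is no position 0.
#'
#' @param id Character label for the promoter (e.g. `"PeMADS2p"`).
#' @param sequence Nucleotide string over A, C, G, T, N (case-insensitive).
#' @param tss_pos 1-based index of the TSS base within `sequence`. May be
#'   `nchar(sequence) + 1` for a record that is entirely upstream of the TSS
#'   (the TSS abuts the 3' end).
#'
#' @return An object of class `promoter_record` with fields `id`, `sequence`
#'   (uppercased), `tss_pos`, and `upstream_length` (number of bases strictly
#'   5' of the TSS base).
#' @export
promoter_record <- function(id, sequence, tss_pos = nchar(sequence) + 1L) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) {
    stop("promoter sequence must be non-empty", call. = FALSE)
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("promoter sequence contains characters outside {A,C,G,T,N}",
         call. = FALSE)
  }
  tss_pos <- as.integer(tss_pos)
  if (is.na(tss_pos) || tss_pos < 1L || tss_pos > nchar(sequence) + 1L) {
    stop("tss_pos must lie in [1, nchar(sequence) + 1]", call. = FALSE)
  }
  structure(
    list(id = id, sequence = sequence, tss_pos = tss_pos,
         upstream_length = tss_pos - 1L),
    class = "promoter_record"
  )
}

#' @export
print.promoter_record <- function(x, ...) {
  cat(sprintf("<promoter_record> %s: %d bp, TSS at index %d (%d bp upstream)\n",
              x$id, nchar(x$sequence), x$tss_pos, x$upstream_length))
  invisible(x)
}

#' Convert a local sequence index to a TSS-relative position
#'
#' Bases 5' of the TSS map to -1, -2, ... (counting towards the 5' end); the
#' TSS base itself is +1. Position 0 does not exist.
#'
#' @param local_start 1-based index (or vector of indices) into the promoter
#'   sequence.
#' @param promoter A [promoter_record()].
#' @return Signed integer position(s); never 0.
#' @seealso [from_tss_coordinate()] for the inverse.
#' @export
to_tss_coordinate <- function(local_start, promoter) {
  stopifnot(inherits(promoter, "promoter_record"))
  local_start <- as.integer(local_start)
  if (any(is.na(local_start)) ||
      any(local_start < 1L | local_start > nchar(promoter$sequence))) {
    stop("local_start out of range for promoter sequence", call. = FALSE)
  }
  d <- local_start - promoter$tss_pos
  ifelse(d >= 0L, d + 1L, d)
}

#' Convert a TSS-relative position back to a local sequence index
#'
#' @param tss_position Signed TSS-relative position(s); 0 is invalid.
#' @inheritParams to_tss_coordinate
#' @return 1-based index/indices into the promoter sequence.
#' @export
from_tss_coordinate <- function(tss_position, promoter) {
  stopifnot(inherits(promoter, "promoter_record"))
  tss_position <- as.integer(tss_position)
  if (any(is.na(tss_position)) || any(tss_position == 0L)) {
    stop("TSS-relative positions are signed and never 0", call. = FALSE)
  }
  local <- ifelse(tss_position > 0L,
                  promoter$tss_pos + tss_position - 1L,
                  promoter$tss_pos + tss_position)
  if (any(local < 1L | local > nchar(promoter$sequence))) {
    stop("TSS-relative position falls outside the promoter sequence",
         call. = FALSE)
  }
  local
}

#' Truncate a promoter to the window immediately upstream of the TSS
#'
#' Keeps at most `window` bases strictly 5' of the TSS base and drops
#' everything at or 3' of the TSS. Used to restrict footprinting to a
#' common-length upstream region (e.g. the 1.3-kb windows conventionally
#' compared across paralogs).
#'
#' @inheritParams to_tss_coordinate
#' @param window Number of upstream bases to keep (default 1300).
#' @return A new [promoter_record()] whose TSS abuts the 3' end.
#' @export
truncate_upstream <- function(promoter, window = 1300L) {
  stopifnot(inherits(promoter, "promoter_record"), window >= 1L)
  keep <- min(as.integer(window), promoter$upstream_length)
  if (keep == 0L) stop("promoter has no upstream sequence", call. = FALSE)
  from <- promoter$tss_pos - keep
  seq <- substr(promoter$sequence, from, promoter$tss_pos - 1L)
  promoter_record(promoter$id, seq, tss_pos = keep + 1L)
}

#' Read promoters from a FASTA file with TSS annotations
#'
#' The TSS position of each record is taken from a `tss=` tag in the FASTA
#' header (e.g. `>PeMADS2p tss=3250`), or from the `tss` argument; records
#' with no declared TSS are treated as entirely upstream (TSS abutting the
#' 3' end).
#'
#' @param path Path to a FASTA file.
#' @param tss Optional named integer vector of 1-based TSS indices, keyed by
#'   record id; overrides header tags.
#' @return A named list of [promoter_record()] objects.
#' @export
read_promoters <- function(path, tss = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(seqs), function(i) {
    header <- names(seqs)[i]
    id <- strsplit(header, "\\s+")[[1]][1]
    tp <- nchar(as.character(seqs[[i]])) + 1L
    m <- regmatches(header, regexpr("tss=\\d+", header))
    if (length(m) == 1L) tp <- as.integer(sub("tss=", "", m))
    if (!is.null(tss) && id %in% names(tss)) tp <- as.integer(tss[[id]])
    promoter_record(id, as.character(seqs[[i]]), tss_pos = tp)
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Write promoters to FASTA with TSS header tags
#'
#' @param promoters A list of [promoter_record()] objects.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(promoters, path) {
  stopifnot(all(vapply(promoters, inherits, logical(1), "promoter_record")))
  seqs <- Biostrings::DNAStringSet(
    vapply(promoters, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(promoters, function(p) {
    sprintf("%s tss=%d", p$id, p$tss_pos)
  }, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
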