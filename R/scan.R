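#' Scan a promoter for consensus-pattern hits
#'
#' Slides the pattern over every window of the promoter sequence and reports
#' each window within the pattern's mismatch budget. Positions are reported
#' both as 1-based local indices and in TSS-relative coordinates (anchored at
#' the 5'-most base of the match; no position 0). With `strands = "both"`,
#' windows are also evaluated against the reverse complement and reported on
#' the minus strand; a minus-strand hit occupying the same genomic interval
#' as a plus-strand hit is dropped as a duplicate interval. For the two CArG
#' rules this never adds hits, because both patterns equal their own reverse
#' complements.
#'
#' @param promoter A [promoter_record()].
#' @param pattern A [consensus_pattern()].
#' @param strands `"forward"` (default) or `"both"`.
#' @return A tibble with columns `promoter_id`, `start`, `end` (1-based,
#'   inclusive local coordinates), `tss_position`, `strand`, `observed` (the
#'   matched string as read on the hit strand), `mismatches`, `pattern_name`,
#'   sorted by `start`. A sequence shorter than the pattern yields zero rows.
#' @export
scan_carg <- function(promoter, pattern, strands = c("forward", "both")) {
  stopifnot(inherits(promoter, "promoter_record"),
            inherits(pattern, "consensus_pattern"))
  strands <- match.arg(strands)
  n <- nchar(promoter$sequence)
  k <- nchar(pattern$symbols)

  fwd <- .scan_strand(promoter$sequence, pattern)
  hits <- if (nrow(fwd)) {
    tibble::tibble(start = fwd$start, strand = "+",
                   observed = fwd$observed, mismatches = fwd$mismatches)
  } else {
    tibble::tibble(start = integer(), strand = character(),
                   observed = character(), mismatches = integer())
  }

  if (strands == "both" && n >= k) {
    rev <- .scan_strand(revcomp(promoter$sequence), pattern)
    if (nrow(rev)) {
      rev_start <- n - rev$start - k + 2L
      keep <- !(rev_start %in% hits$start)
      hits <- dplyr::bind_rows(
        hits,
        tibble::tibble(start = rev_start[keep], strand = "-",
                       observed = rev$observed[keep],
                       mismatches = rev$mismatches[keep])
      )
    }
  }

  hits <- hits[order(hits$start), , drop = FALSE]
  tibble::tibble(
    promoter_id = rep(promoter$id, nrow(hits)),
    start = hits$start,
    end = hits$start + k - 1L,
    tss_position = if (nrow(hits)) to_tss_coordinate(hits$start, promoter)
                   else integer(),
    strand = hits$strand,
    observed = hits$observed,
    mismatches = hits$mismatches,
    pattern_name = rep(pattern$name, nrow(hits))
  )
}

# vectorised window scoring on one strand: one pass per pattern position
.scan_strand <- function(sequence, pattern) {
  n <- nchar(sequence)
  k <- nchar(pattern$symbols)
  if (n < k) {
    return(data.frame(start = integer(), observed = character(),
                      mismatches = integer()))
  }
  cs <- strsplit(toupper(sequence), "")[[1]]
  pc <- strsplit(pattern$symbols, "")[[1]]
  starts <- seq_len(n - k + 1L)
  mism <- integer(length(starts))
  for (j in seq_len(k)) {
    mism <- mism + !(cs[starts + j - 1L] %in% .symbol_sets[[pc[j]]])
  }
  sel <- which(mism <= pattern$max_mismatches)
  if (!length(sel)) {
    return(data.frame(start = integer(), observed = character(),
                      mismatches = integer()))
  }
  data.frame(
    start = starts[sel],
    observed = substring(sequence, starts[sel], starts[sel] + k - 1L),
    mismatches = mism[sel],
    stringsAsFactors = FALSE
  )
}

#' Classify a list of candidate decamers under one or more consensus rules
#'
#' Each entry is scored against each rule; duplicate sequences count as
#' separate entries (counts are per listed occurrence, not per distinct
#' sequence). An entry may satisfy zero, one, or several rules.
#'
#' @param entries A data frame with columns `label` and `decamer` (each
#'   decamer the same length as every rule pattern).
#' @param rules A list of [consensus_pattern()] objects.
#' @return A tibble with one row per rule: `rule`, `n_matching`, and a
#'   list-column `matching_labels`.
#' @export
classify_decamers <- function(entries, rules) {
  stopifnot(is.data.frame(entries),
            all(c("label", "decamer") %in% names(entries)))
  if (inherits(rules, "consensus_pattern")) rules <- list(rules)
  lens <- unique(vapply(rules, function(r) nchar(r$symbols), integer(1)))
  bad <- nchar(entries$decamer) != lens[1] | grepl("[^ACGTNacgtn]", entries$decamer)
  if (length(lens) != 1L) {
    stop("all rules must have the same pattern length", call. = FALSE)
  }
  if (any(bad)) {
    stop(sprintf("invalid entries (wrong length or alphabet): %s",
                 paste(entries$label[bad], collapse = ", ")), call. = FALSE)
  }
  rows <- lapply(rules, function(r) {
    ok <- vapply(entries$decamer, pattern_matches, logical(1), pattern = r,
                 USE.NAMES = FALSE)
    tibble::tibble(rule = r$name, n_matching = sum(ok),
                   matching_labels = list(entries$label[ok]))
  })
  dplyr::bind_rows(rows)
}

#' Export scan hits as BED6
#'
#' Local coordinates are converted to BED's 0-based half-open convention;
#' the TSS-relative position of the hit is carried in the `name` field.
#'
#' @param hits A hit table from [scan_carg()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
hits_to_bed <- function(hits, path) {
  bed <- data.frame(
    chrom = hits$promoter_id,
    chromStart = hits$start - 1L,
    chromEnd = hits$end,
    name = sprintf("%s@%+d", hits$pattern_name, hits$tss_position),
    score = hits$mismatches,
    strand = hits$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
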