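#' Degenerate consensus pattern with a mismatch budget
#'
#' A consensus pattern is a string over the symbols A, C, G, T, W (= A or T)
#' and N (any base), together with the maximum number of mismatches a window
#' may carry and still count as a hit. The two classical CArG-box rules are
#' provided as [carg_core()] (CC(A/T)6GG, one mismatch allowed — the
#' "9-of-10" standard) and [carg_relaxed()] (C(A/T)8G, exact match).
#'
#' @param symbols Pattern string over A, C, G, T, W, N.
#' @param max_mismatches Non-negative integer, strictly less than the pattern
#'   length.
#' @param name Label for the pattern; defaults to `symbols`.
#' @return A `consensus_pattern` object.
#' @export
consensus_pattern <- function(symbols, max_mismatches = 0L, name = symbols) {
  stopifnot(is.character(symbols), length(symbols) == 1L)
  symbols <- toupper(symbols)
  if (!nzchar(symbols) || grepl("[^ACGTWN]", symbols)) {
    stop("pattern symbols must be a non-empty string over {A,C,G,T,W,N}",
         call. = FALSE)
  }
  max_mismatches <- as.integer(max_mismatches)
  if (is.na(max_mismatches) || max_mismatches < 0L ||
      max_mismatches >= nchar(symbols)) {
    stop("max_mismatches must satisfy 0 <= max_mismatches < pattern length",
         call. = FALSE)
  }
  structure(
    list(name = name, symbols = symbols, max_mismatches = max_mismatches),
    class = "consensus_pattern"
  )
}

#' @export
print.consensus_pattern <- function(x, ...) {
  cat(sprintf("<consensus_pattern> %s: %s, <=%d mismatch(es)\n",
              x$name, x$symbols, x$max_mismatches))
  invisible(x)
}

#' @rdname consensus_pattern
#' @export
carg_core <- function() consensus_pattern("CCWWWWWWGG", 1L, name = "CCW6GG")

#' @rdname consensus_pattern
#' @export
carg_relaxed <- function() consensus_pattern("CWWWWWWWWG", 0L, name = "CW8G")

# allowed base sets per pattern symbol; N in a *window* is a mismatch unless
# the pattern symbol is N (conservative calling)
.symbol_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  W = c("A", "T"),
  N = c("A", "C", "G", "T", "N")
)

#' Count mismatches of a window against a consensus pattern
#'
#' @param window Nucleotide string over A, C, G, T, N, the same length as the
#'   pattern.
#' @param pattern A [consensus_pattern()].
#' @return Integer number of positions where the window base is not in the
#'   pattern symbol's allowed set.
#' @export
mismatch_count <- function(window, pattern) {
  stopifnot(inherits(pattern, "consensus_pattern"))
  window <- toupper(window)
  if (nchar(window) != nchar(pattern$symbols)) {
    stop(sprintf("window length %d does not match pattern length %d",
                 nchar(window), nchar(pattern$symbols)), call. = FALSE)
  }
  if (grepl("[^ACGTN]", window)) {
    stop("window contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  wc <- strsplit(window, "")[[1]]
  pc <- strsplit(pattern$symbols, "")[[1]]
  sum(!mapply(function(w, p) w %in% .symbol_sets[[p]], wc, pc))
}

#' Does a window match a consensus pattern within its mismatch budget?
#'
#' @inheritParams mismatch_count
#' @return `TRUE` iff `mismatch_count(window, pattern) <= pattern$max_mismatches`.
#' @export
pattern_matches <- function(window, pattern) {
  mismatch_count(window, pattern) <= pattern$max_mismatches
}

#' Reverse complement of a nucleotide or degenerate pattern string
#'
#' W and N are their own complements, so the two CArG rules are invariant
#' under reverse complementation.
#'
#' @param x Character string over A, C, G, T, W, N.
#' @return The reverse complement string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}
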