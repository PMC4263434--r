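# Independent brute-force oracles. These re-derive expected results by the
# most literal method available and deliberately share no code with the
# package implementations they check.

# allowed-base lookup, written out independently of the package's tables
oracle_allowed <- function(sym) {
  switch(sym,
         A = "A", C = "C", G = "G", T = "T",
         W = c("A", "T"),
         N = c("A", "C", "G", "T", "N"))
}

oracle_mismatches <- function(window, symbols) {
  w <- strsplit(toupper(window), "")[[1]]
  p <- strsplit(toupper(symbols), "")[[1]]
  n <- 0L
  for (i in seq_along(p)) if (!(w[i] %in% oracle_allowed(p[i]))) n <- n + 1L
  n
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", W = "W")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

# every-window re-scoring scan; returns data.frame(start, strand, mismatches)
oracle_scan <- function(sequence, symbols, max_mm, strands = "forward") {
  sequence <- toupper(sequence)
  k <- nchar(symbols)
  n <- nchar(sequence)
  out <- list()
  if (n >= k) {
    for (i in seq_len(n - k + 1L)) {
      w <- substr(sequence, i, i + k - 1L)
      mm <- oracle_mismatches(w, symbols)
      if (mm <= max_mm) {
        out[[length(out) + 1L]] <- data.frame(start = i, strand = "+",
                                              mismatches = mm)
      }
      if (strands == "both") {
        mmr <- oracle_mismatches(oracle_revcomp(w), symbols)
        if (mmr <= max_mm) {
          out[[length(out) + 1L]] <- data.frame(start = i, strand = "-",
                                                mismatches = mmr)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), strand = character(),
               mismatches = integer())
  # duplicate-interval rule: a minus hit at a start already hit on plus is
  # the same genomic interval
  drop <- res$strand == "-" & res$start %in% res$start[res$strand == "+"]
  res <- res[!drop, , drop = FALSE]
  res[order(res$start, res$strand), , drop = FALSE]
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

oracle_kmers <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(character())
  vapply(seq_len(n - k + 1L), function(i) substr(sequence, i, i + k - 1L),
         character(1))
}

# all-pairs Hamming enumeration: the set of k-mers observed in either
# sequence whose closest window in the other sequence is within D
oracle_pairwise_kmers <- function(seqA, seqB, k, D) {
  wA <- oracle_kmers(toupper(seqA), k)
  wB <- oracle_kmers(toupper(seqB), k)
  hit <- character()
  for (a in unique(wA)) {
    if (min(vapply(wB, oracle_hamming, integer(1), a = a)) <= D) {
      hit <- c(hit, a)
    }
  }
  for (b in unique(wB)) {
    if (min(vapply(wA, oracle_hamming, integer(1), a = b)) <= D) {
      hit <- c(hit, b)
    }
  }
  sort(unique(hit))
}

# cut-and-measure digestion: literally split the sequence string at each
# unblocked site and measure the pieces
oracle_digest_fragments <- function(reference, meth, enzymes) {
  reference <- toupper(reference)
  cuts <- integer()
  for (e in enzymes) {
    if (e %in% c("HpaII", "MspI")) {
      i <- 1L
      while (i <= nchar(reference) - 3L) {
        if (substr(reference, i, i + 3L) == "CCGG") {
          blocked <- if (e == "HpaII") (i %in% meth) || ((i + 1L) %in% meth)
                     else (i %in% meth)
          if (!blocked) cuts <- c(cuts, i)  # cut after first C
        }
        i <- i + 1L
      }
    } else if (e == "DraI") {
      i <- 1L
      while (i <= nchar(reference) - 5L) {
        if (substr(reference, i, i + 5L) == "TTTAAA") cuts <- c(cuts, i + 2L)
        i <- i + 1L
      }
    } else stop("oracle: unknown enzyme")
  }
  cuts <- sort(unique(cuts))
  pieces <- integer()
  prev <- 0L
  for (cpos in cuts) {
    pieces <- c(pieces, cpos - prev)
    prev <- cpos
  }
  pieces <- c(pieces, nchar(reference) - prev)
  sort(pieces[pieces > 0L])
}

# plain Needleman-Wunsch edit-distance DP with bisulfite-aware substitution
# cost (ref C vs clone T free), unit gap and mismatch costs
oracle_nw_cost <- function(ref, clone) {
  r <- strsplit(toupper(ref), "")[[1]]
  q <- strsplit(toupper(clone), "")[[1]]
  n <- length(r); m <- length(q)
  D <- matrix(0, n + 1L, m + 1L)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  for (i in 1:n) {
    for (j in 1:m) {
      sub <- if (r[i] == q[j] || (r[i] == "C" && q[j] == "T")) 0 else 1
      D[i + 1L, j + 1L] <- min(D[i, j] + sub, D[i, j + 1L] + 1,
                               D[i + 1L, j] + 1)
    }
  }
  D[n + 1L, m + 1L]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
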