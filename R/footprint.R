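#' Parameters for substring-parsimony footprinting
#'
#' @param k Motif size in bp (10 or 11 are the conventional choices for
#'   promoter footprinting).
#' @param max_mutations Total substitution budget D across all non-lost
#'   leaves (0 = exact conservation).
#' @param loss_cost Penalty per lost leaf. Defaults to `max_mutations + 1`
#'   so that at D = 0 a loss can never silently substitute for a mutation.
#' @param max_losses Maximum number of leaves a motif may be absent from.
#' @param strands `"forward"` (default; conserved-motif discovery on
#'   promoters is conventionally strand-aware) or `"both"`.
#' @param merge Merge overlapping exactly-conserved k-mers that arise from
#'   one longer shared substring into a single maximally extended motif
#'   (applies only when `max_mutations = 0`). Set `FALSE` for the raw
#'   un-merged k-mer list.
#' @return A `footprint_params` object.
#' @export
footprint_params <- function(k = 11L, max_mutations = 0L,
                             loss_cost = max_mutations + 1L,
                             max_losses = 0L,
                             strands = c("forward", "both"),
                             merge = TRUE) {
  k <- as.integer(k); max_mutations <- as.integer(max_mutations)
  max_losses <- as.integer(max_losses)
  stopifnot(k >= 1L, max_mutations >= 0L, loss_cost > 0, max_losses >= 0L)
  structure(
    list(k = k, max_mutations = max_mutations, loss_cost = loss_cost,
         max_losses = max_losses, strands = match.arg(strands),
         merge = isTRUE(merge)),
    class = "footprint_params"
  )
}

# all k-length windows of a sequence as a character vector
.windows <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(character())
  starts <- seq_len(n - k + 1L)
  substring(sequence, starts, starts + k - 1L)
}

# minimal Hamming distance from `kmer` to any window; windows given as a
# character matrix (rows = windows, cols = positions) for vectorisation
.window_matrix <- function(sequence, k) {
  w <- .windows(sequence, k)
  if (!length(w)) return(NULL)
  matrix(unlist(strsplit(w, ""), use.names = FALSE),
         nrow = length(w), ncol = k, byrow = TRUE)
}

.min_hamming <- function(kmer, wmat) {
  kc <- strsplit(kmer, "")[[1]]
  d <- rowSums(wmat != matrix(kc, nrow = nrow(wmat), ncol = length(kc),
                              byrow = TRUE))
  list(dist = min(d), start = which.min(d))
}

# all single-substitution variants of a k-mer (excluding the k-mer itself)
.one_neighbourhood <- function(kmer) {
  kc <- strsplit(kmer, "")[[1]]
  out <- character(0)
  for (i in seq_along(kc)) {
    for (b in setdiff(c("A", "C", "G", "T"), kc[i])) {
      v <- kc; v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

.as_sequences <- function(promoters) {
  if (is.character(promoters)) {
    stopifnot(!is.null(names(promoters)))
    return(toupper(promoters))
  }
  stopifnot(all(vapply(promoters, inherits, logical(1), "promoter_record")))
  seqs <- vapply(promoters, `[[`, character(1), "sequence")
  names(seqs) <- vapply(promoters, `[[`, character(1), "id")
  seqs
}

#' Conserved k-mers between two sequences
#'
#' Direct pairwise route of the footprinting analysis. With `max_mutations
#' = 0` it returns the distinct k-mers occurring verbatim in both sequences;
#' overlapping shared k-mers arising from one longer shared substring are
#' merged into a single motif of maximal extension (disable with
#' `merge = FALSE`). With a positive budget D it returns every k-mer
#' observed in either sequence whose closest window in the other sequence is
#' within Hamming distance D (the two-leaf parsimony score is that
#' distance).
#'
#' @param seqA,seqB Nucleotide strings or [promoter_record()]s, both at
#'   least `k` long.
#' @param k Motif size.
#' @param max_mutations Substitution budget D.
#' @param merge Merge maximal extensions (D = 0 only); default `TRUE`.
#' @return A conserved-motif tibble (see [substring_parsimony()]).
#' @export
pairwise_conserved <- function(seqA, seqB, k = 11L, max_mutations = 0L,
                               merge = TRUE) {
  seqs <- .as_sequences(
    if (is.character(seqA)) c(A = toupper(seqA), B = toupper(seqB))
    else list(seqA, seqB))
  k <- as.integer(k)
  if (any(nchar(seqs) < k)) {
    stop("both sequences must be at least k bases long", call. = FALSE)
  }
  wA <- .windows(seqs[[1]], k); wB <- .windows(seqs[[2]], k)
  ids <- names(seqs)

  if (max_mutations == 0L) {
    shared <- sort(intersect(wA, wB))
    if (isTRUE(merge)) shared <- .merge_maximal(shared, seqs)
    rows <- lapply(shared, function(m) {
      .motif_row(m, seqs, lost = character(0), subs_total = 0L,
                 loss_cost = 1L)
    })
    return(.bind_motifs(rows))
  }

  mA <- .window_matrix(seqs[[1]], k); mB <- .window_matrix(seqs[[2]], k)
  cand <- sort(unique(c(wA, wB)))
  rows <- list()
  for (cd in cand) {
    dA <- .min_hamming(cd, mA); dB <- .min_hamming(cd, mB)
    if (dA$dist + dB$dist <= max_mutations) {
      rows[[length(rows) + 1L]] <- .motif_row(
        cd, seqs, lost = character(0),
        subs_total = dA$dist + dB$dist, loss_cost = 1L)
    }
  }
  .bind_motifs(rows)
}

# merge exactly-shared k-mers that tile a longer substring shared by all
# sequences: extend each shared k-mer left/right while the extension is
# still present in every sequence, then drop strings contained in a longer
# reported string
.merge_maximal <- function(shared, seqs) {
  if (!length(shared)) return(character(0))
  in_all <- function(s) all(vapply(seqs, function(x) grepl(s, x, fixed = TRUE),
                                   logical(1)))
  ext <- vapply(shared, function(m) {
    repeat {
      grown <- FALSE
      for (b in c("A", "C", "G", "T")) {
        if (in_all(paste0(m, b))) { m <- paste0(m, b); grown <- TRUE; break }
      }
      if (!grown) break
    }
    repeat {
      grown <- FALSE
      for (b in c("A", "C", "G", "T")) {
        if (in_all(paste0(b, m))) { m <- paste0(b, m); grown <- TRUE; break }
      }
      if (!grown) break
    }
    m
  }, character(1), USE.NAMES = FALSE)
  ext <- sort(unique(ext))
  keep <- vapply(seq_along(ext), function(i) {
    !any(vapply(ext[-i], function(longer) {
      nchar(longer) > nchar(ext[i]) && grepl(ext[i], longer, fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  ext[keep]
}

.motif_row <- function(motif, seqs, lost, subs_total, loss_cost) {
  present <- setdiff(names(seqs), lost)
  occ <- lapply(present, function(id) {
    wmat <- .window_matrix(seqs[[id]], nchar(motif))
    mh <- .min_hamming(motif, wmat)
    tibble::tibble(leaf = id, start = as.integer(mh$start),
                   observed = substr(seqs[[id]], mh$start,
                                     mh$start + nchar(motif) - 1L),
                   substitutions = as.integer(mh$dist))
  })
  tibble::tibble(
    ancestral = motif,
    width = nchar(motif),
    substitutions = as.integer(subs_total),
    n_lost = length(lost),
    score = as.numeric(subs_total + loss_cost * length(lost)),
    lost_leaves = list(sort(lost)),
    occurrences = list(dplyr::bind_rows(occ))
  )
}

.bind_motifs <- function(rows) {
  if (!length(rows)) {
    return(tibble::tibble(ancestral = character(), width = integer(),
                          substitutions = integer(), n_lost = integer(),
                          score = numeric(), lost_leaves = list(),
                          occurrences = list()))
  }
  out <- dplyr::bind_rows(rows)
  out[order(out$score, out$ancestral), , drop = FALSE]
}

#' Discover k-mers conserved across promoters by substring parsimony
#'
#' For each candidate ancestral k-mer, the conservation cost in a leaf is
#' the minimal Hamming distance from the candidate to any window of that
#' leaf's sequence; a leaf may instead be declared lost at `loss_cost` (at
#' most `max_losses` leaves). A motif is reported when its total
#' substitution cost over non-lost leaves is within `max_mutations`.
#' Candidate ancestral k-mers are the k-mers observed in the leaves,
#' extended by their 1-substitution neighbourhoods when `max_mutations >=
#' 1`; this candidate set is provably exhaustive for budgets of 0 or 1.
#' Losses are assigned greedily to the costliest leaves, only as needed and
#' never beyond `max_losses`.
#'
#' @param promoters Named character vector of sequences, or a (named) list
#'   of [promoter_record()]s. Names must match the tree's tip labels.
#' @param tree An `ape::phylo` tree, a Newick string, or `NULL` for an
#'   unstructured (star) promoter set. Branch lengths are ignored by
#'   parsimony; tips are validated against the promoter ids.
#' @param params A [footprint_params()].
#' @return A tibble with one row per conserved motif: `ancestral`, `width`,
#'   `substitutions` (total over non-lost leaves), `n_lost`, `score`
#'   (substitutions + loss penalties), `lost_leaves` (list), and
#'   `occurrences` (list of per-leaf tibbles `leaf`, `start`, `observed`,
#'   `substitutions`), sorted by score then motif.
#' @export
substring_parsimony <- function(promoters, tree = NULL,
                                params = footprint_params()) {
  stopifnot(inherits(params, "footprint_params"))
  seqs <- .as_sequences(promoters)
  if (!is.null(tree)) {
    if (is.character(tree)) tree <- ape::read.tree(text = tree)
    stopifnot(inherits(tree, "phylo"))
    missing_tips <- setdiff(tree$tip.label, names(seqs))
    missing_seqs <- setdiff(names(seqs), tree$tip.label)
    if (length(missing_tips) || length(missing_seqs)) {
      stop(sprintf(
        "tree/sequence mismatch; missing sequences: [%s]; missing tips: [%s]",
        paste(missing_tips, collapse = ", "),
        paste(missing_seqs, collapse = ", ")), call. = FALSE)
    }
    seqs <- seqs[tree$tip.label]
  }
  k <- params$k; D <- params$max_mutations
  if (any(nchar(seqs) < k)) {
    stop("every sequence must be at least k bases long", call. = FALSE)
  }
  if (params$max_losses >= length(seqs)) {
    stop("max_losses must be smaller than the number of leaves", call. = FALSE)
  }
  if (params$strands == "both") {
    seqs_scan <- lapply(seqs, function(s) c(s, revcomp(s)))
  } else {
    seqs_scan <- lapply(seqs, function(s) s)
  }

  observed <- sort(unique(unlist(lapply(seqs_scan, function(ss) {
    unlist(lapply(ss, .windows, k = k), use.names = FALSE)
  }), use.names = FALSE)))
  cand <- observed
  if (D >= 1L) {
    cand <- sort(unique(c(cand, unlist(lapply(observed, .one_neighbourhood),
                                       use.names = FALSE))))
  }

  # per-leaf window sets (fast membership for D = 0) and char matrices
  wsets <- lapply(seqs_scan, function(ss) {
    unique(unlist(lapply(ss, .windows, k = k), use.names = FALSE))
  })
  wmats <- lapply(seqs_scan, function(ss) {
    do.call(rbind, lapply(ss, .window_matrix, k = k))
  })

  leaf_cost <- function(cd) {
    vapply(names(seqs), function(id) {
      if (cd %in% wsets[[id]]) return(0L)
      if (D == 0L) return(NA_integer_)  # any positive cost is fatal at D=0
      as.integer(.min_hamming(cd, wmats[[id]])$dist)
    }, integer(1))
  }

  rows <- list()
  for (cd in cand) {
    costs <- leaf_cost(cd)
    costs[is.na(costs)] <- k  # sentinel: conservation impossible at D = 0
    lost <- character(0)
    ord <- order(costs, decreasing = TRUE)
    i <- 1L
    while (sum(costs[setdiff(names(seqs), lost)]) > D &&
           length(lost) < params$max_losses && i <= length(costs)) {
      lost <- c(lost, names(seqs)[ord[i]])
      i <- i + 1L
    }
    subs <- sum(costs[setdiff(names(seqs), lost)])
    if (subs <= D) {
      rows[[length(rows) + 1L]] <- .motif_row(
        cd, seqs, lost = lost, subs_total = subs,
        loss_cost = params$loss_cost)
    }
  }
  out <- .bind_motifs(rows)

  if (params$merge && D == 0L && nrow(out)) {
    # merge only motifs conserved in the full leaf set; lossy motifs are
    # reported as-is because their extension support differs per lost set
    full <- out[out$n_lost == 0L, , drop = FALSE]
    lossy <- out[out$n_lost > 0L, , drop = FALSE]
    merged <- .merge_maximal(full$ancestral, seqs)
    rows <- lapply(merged, function(m) {
      .motif_row(m, seqs, lost = character(0), subs_total = 0L,
                 loss_cost = params$loss_cost)
    })
    lossy <- lossy[!vapply(lossy$ancestral, function(a) {
      any(vapply(merged, function(m) grepl(a, m, fixed = TRUE), logical(1)))
    }, logical(1)), , drop = FALSE]
    out <- .bind_motifs(c(rows, list(lossy)))
  }
  out
}

#' Per-promoter track of motif occurrences
#'
#' Flattens a conserved-motif table into an ordered per-promoter track,
#' suitable for drawing motif maps (occurrences may appear in a different
#' order in different promoters) or writing to TSV.
#'
#' @param promoters Named character vector or list of [promoter_record()]s;
#'   order defines track order.
#' @param motifs A conserved-motif tibble from [substring_parsimony()] or
#'   [pairwise_conserved()].
#' @return A tibble `promoter_id`, `start`, `end`, `motif`, `substitutions`,
#'   sorted by promoter then position.
#' @export
motif_map <- function(promoters, motifs) {
  seqs <- .as_sequences(promoters)
  if (!nrow(motifs)) {
    return(tibble::tibble(promoter_id = character(), start = integer(),
                          end = integer(), motif = character(),
                          substitutions = integer()))
  }
  occ <- dplyr::bind_rows(lapply(seq_len(nrow(motifs)), function(i) {
    o <- motifs$occurrences[[i]]
    tibble::tibble(promoter_id = o$leaf, start = o$start,
                   end = o$start + motifs$width[i] - 1L,
                   motif = motifs$ancestral[i],
                   substitutions = o$substitutions)
  }))
  occ <- occ[occ$promoter_id %in% names(seqs), , drop = FALSE]
  occ$promoter_id <- factor(occ$promoter_id, levels = names(seqs))
  occ <- occ[order(occ$promoter_id, occ$start, occ$motif), , drop = FALSE]
  occ$promoter_id <- as.character(occ$promoter_id)
  occ
}
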