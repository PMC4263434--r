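#' A set of bisulfite-sequenced clones over one reference region
#'
#' @param reference Untreated genomic top-strand sequence of the region.
#' @param clones Named character vector (or named list) of clone sequences,
#'   each a bisulfite PCR product of the reference top strand (unmethylated
#'   C read as T, methylated C retained).
#' @param region_label Free-text label for the amplicon.
#' @return A `bisulfite_clone_set` object.
#' @export
bisulfite_clone_set <- function(reference, clones, region_label = "region") {
  reference <- toupper(reference)
  clones <- vapply(clones, toupper, character(1))
  stopifnot(nzchar(reference), length(clones) >= 1L)
  if (is.null(names(clones)) || any(!nzchar(names(clones)))) {
    names(clones) <- sprintf("clone%02d", seq_along(clones))
  }
  structure(list(reference = reference, clones = clones,
                 region_label = region_label),
            class = "bisulfite_clone_set")
}

#' Anchor a bisulfite clone to its reference by conversion-aware alignment
#'
#' Global (Needleman-Wunsch) alignment in which a reference C aligned to a
#' clone T scores as a match-class substitution (bisulfite conversion, cost
#' 0) while every other substitution is penalised. Returns, for every
#' reference position, the clone base aligned to it (`NA` at deletions).
#'
#' @param reference Reference top-strand sequence.
#' @param clone Clone sequence.
#' @param min_identity Minimum fraction of reference positions carrying a
#'   match-class clone base (identical, or T under a reference C) for the
#'   alignment to be accepted; below it the clone is rejected with an error
#'   of class `promepi_bad_clone`.
#' @return Character vector of length `nchar(reference)`: the aligned clone
#'   base per reference position, `NA` where the clone has a gap. Attribute
#'   `identity` carries the conversion-aware identity.
#' @export
align_clone <- function(reference, clone, min_identity = 0.8) {
  reference <- toupper(reference); clone <- toupper(clone)
  mat <- .conversion_matrix()
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(reference),
    subject = Biostrings::DNAString(clone),
    type = "global", substitutionMatrix = mat,
    gapOpening = 8, gapExtension = 4)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  keep <- pat != "-"
  map <- sub[keep]
  map[map == "-"] <- NA_character_
  ok <- !is.na(map) & (map == pat[keep] | (pat[keep] == "C" & map == "T"))
  identity <- mean(ok)
  if (identity < min_identity) {
    stop(structure(
      class = c("promepi_bad_clone", "error", "condition"),
      list(message = sprintf(
        "clone alignment identity %.2f below floor %.2f", identity,
        min_identity),
        call = sys.call(-1))))
  }
  attr(map, "identity") <- identity
  map
}

# match +1; reference-C vs clone-T scores like a match (conversion);
# any other substitution -2; indexed [reference base, clone base]
.conversion_matrix <- function() {
  bases <- c("A", "C", "G", "T")
  m <- matrix(-2, 4, 4, dimnames = list(bases, bases))
  diag(m) <- 1
  m["C", "T"] <- 1
  m
}

# context of each reference C from the reference alone: CG, CHG, or CHH
# (H = A, C or T); a C too close to the 3' end to decide defaults to CHH
.cytosine_contexts <- function(reference) {
  chars <- strsplit(reference, "")[[1]]
  cpos <- which(chars == "C")
  ctx <- vapply(cpos, function(i) {
    n1 <- if (i + 1L <= length(chars)) chars[i + 1L] else ""
    n2 <- if (i + 2L <= length(chars)) chars[i + 2L] else ""
    if (n1 == "G") "CpG"
    else if (n1 %in% c("A", "C", "T") && n2 == "G") "CHG"
    else "CHH"
  }, character(1))
  tibble::tibble(position = cpos, context = ctx)
}

#' Call per-cytosine methylation from bisulfite clones
#'
#' Every clone is anchored to the reference with [align_clone()] (clones
#' below the identity floor are excluded with a warning). At each reference
#' cytosine, a clone base C is counted as methylated, T as unmethylated
#' (converted), and anything else — gap, ambiguous, sequencing error — is
#' excluded from that site's denominator. Contexts (CpG/CHG/CHH, H = A, C
#' or T) are assigned from the reference alone; every reference C gets
#' exactly one context. No statistical correction for incomplete conversion
#' is applied: apparent non-CpG methylation doubles as a conversion
#' diagnostic.
#'
#' @param cloneset A [bisulfite_clone_set()].
#' @param min_identity Passed to [align_clone()].
#' @return A tibble with one row per reference cytosine: `position`
#'   (1-based), `context`, `n_methylated`, `n_total` (clones contributing a
#'   C or T at the site), `fraction`. Zero rows (with a warning) if the
#'   reference has no C.
#' @export
call_methylation <- function(cloneset, min_identity = 0.8) {
  stopifnot(inherits(cloneset, "bisulfite_clone_set"))
  ctx <- .cytosine_contexts(cloneset$reference)
  if (!nrow(ctx)) {
    warning("reference contains no cytosine; empty profile")
    return(tibble::tibble(position = integer(), context = character(),
                          n_methylated = integer(), n_total = integer(),
                          fraction = numeric()))
  }
  maps <- list()
  for (id in names(cloneset$clones)) {
    map <- tryCatch(
      align_clone(cloneset$reference, cloneset$clones[[id]], min_identity),
      promepi_bad_clone = function(e) {
        warning(sprintf("clone %s excluded: %s", id, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (!is.null(map)) maps[[id]] <- map
  }
  if (!length(maps)) stop("no clone passed the alignment identity floor",
                          call. = FALSE)
  base_mat <- do.call(rbind, maps)[, ctx$position, drop = FALSE]
  n_meth <- colSums(base_mat == "C", na.rm = TRUE)
  n_unmeth <- colSums(base_mat == "T", na.rm = TRUE)
  n_total <- n_meth + n_unmeth
  tibble::tibble(
    position = ctx$position,
    context = ctx$context,
    n_methylated = as.integer(n_meth),
    n_total = as.integer(n_total),
    fraction = ifelse(n_total > 0, n_meth / n_total, NA_real_)
  )
}

#' Per-context methylation summary
#'
#' @param profile A per-cytosine profile from [call_methylation()].
#' @return A tibble `context`, `n_sites`, `mean_fraction` (weighted by
#'   informative clone calls: total methylated / total called).
#' @export
methylation_summary <- function(profile) {
  dplyr::summarise(
    dplyr::group_by(profile, .data$context),
    n_sites = dplyr::n(),
    mean_fraction = sum(.data$n_methylated) / pmax(sum(.data$n_total), 1L),
    .groups = "drop")
}
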