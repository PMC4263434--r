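#' Specification for a simulated promoter set
#'
#' Describes a set of promoters evolved along a phylogeny from a random
#' root, with optional planted CArG boxes (same TSS-relative position in
#' every leaf) and planted conserved k-mers (with declared per-leaf
#' substitution counts and optional lineage losses). Planting happens after
#' branch evolution, so a planted motif's divergence is exactly its
#' declared substitution count.
#'
#' @param tree Newick string or `ape::phylo`; tip labels become promoter ids.
#' @param root_length Length of the upstream region in bp (default 1300,
#'   the conventional window compared across these paralogous promoters).
#' @param substitution_prob Per-site, per-branch substitution probability
#'   (i.i.d., uniform over the three other bases).
#' @param planted_carg List of `list(decamer=, tss_position=, rule=)` items;
#'   `rule` is `"core"`, `"relaxed"` or `NULL` (unchecked). Each decamer is
#'   written into every leaf at the stated TSS-relative position and is
#'   validated against its declared rule at generation time.
#' @param planted_motifs List of `list(kmer=, substitutions=, lost=,
#'   tss_position=)` items. `substitutions` is a single count or a named
#'   per-leaf vector; `lost` names leaves the motif is omitted from;
#'   `tss_position` is optional (a collision-free position is drawn when
#'   absent, the same position in every leaf).
#' @param seed Integer seed; identical specs and seeds give identical output.
#' @return A `promoter_sim_spec` object.
#' @export
promoter_sim_spec <- function(tree, root_length = 1300L,
                              substitution_prob = 0.1,
                              planted_carg = list(),
                              planted_motifs = list(),
                              seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), root_length >= 1L,
            substitution_prob >= 0, substitution_prob <= 1)
  structure(
    list(tree = tree, root_length = as.integer(root_length),
         substitution_prob = substitution_prob,
         planted_carg = planted_carg, planted_motifs = planted_motifs,
         seed = as.integer(seed)),
    class = "promoter_sim_spec")
}

.mutate_seq <- function(chars, p) {
  if (p == 0) return(chars)
  hit <- which(stats::runif(length(chars)) < p)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  chars
}

# substitute `n` random positions of a k-mer with random other bases
.substitute_kmer <- function(kmer, n) {
  kc <- strsplit(kmer, "")[[1]]
  if (n > 0L) {
    pos <- sample(length(kc), n)
    for (i in pos) kc[i] <- sample(setdiff(c("A", "C", "G", "T"), kc[i]), 1L)
  }
  paste(kc, collapse = "")
}

#' Generate promoters evolved along a tree with planted motifs
#'
#' The root sequence is drawn uniformly over A/C/G/T and evolved down the
#' tree with i.i.d. per-site substitutions on each branch (no indels).
#' Planted CArG boxes and conserved k-mers are then written over the
#' evolved leaves; a planted motif carries exactly its declared per-leaf
#' substitutions and is omitted from its lost leaves.
#'
#' @param spec A [promoter_sim_spec()].
#' @return A list with `promoters` (named list of [promoter_record()]s, TSS
#'   abutting the 3' end), `tree`, and `truth` (tibble of every planted
#'   item: `kind`, `leaf`, `motif`, `planted` realised string, `start`
#'   local 1-based, `tss_position`, `substitutions`).
#' @export
gen_promoters <- function(spec) {
  stopifnot(inherits(spec, "promoter_sim_spec"))
  set.seed(spec$seed)
  tree <- spec$tree
  L <- spec$root_length
  tips <- tree$tip.label
  n_node <- max(tree$edge)

  root_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  seq_store <- vector("list", n_node)
  root_id <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  seq_store[[root_id]] <- root_chars
  # preorder traversal: parents appear before children in reorder()d edges
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  for (r in seq_len(nrow(edges))) {
    parent <- edges[r, 1]; child <- edges[r, 2]
    seq_store[[child]] <- .mutate_seq(seq_store[[parent]],
                                      spec$substitution_prob)
  }
  leaves <- stats::setNames(
    lapply(seq_along(tips), function(i) seq_store[[i]]), tips)

  occupied <- stats::setNames(rep(list(integer()), length(tips)), tips)
  truth <- list()
  plant <- function(leaf, chars, s, start) {
    kc <- strsplit(s, "")[[1]]
    chars[start:(start + length(kc) - 1L)] <- kc
    chars
  }
  reserve <- function(leaf, start, width) {
    span <- start:(start + width - 1L)
    if (any(span %in% occupied[[leaf]])) {
      stop(sprintf("planting collision in leaf %s at %d", leaf, start),
           call. = FALSE)
    }
    occupied[[leaf]] <<- c(occupied[[leaf]], span)
  }
  tss_to_local <- function(tss_position, width) {
    stopifnot(tss_position <= -width)
    L + tss_position + 1L
  }

  for (item in spec$planted_carg) {
    dec <- toupper(item$decamer)
    if (!is.null(item$rule)) {
      pat <- switch(item$rule, core = carg_core(), relaxed = carg_relaxed(),
                    stop("rule must be 'core' or 'relaxed'", call. = FALSE))
      if (!pattern_matches(dec, pat)) {
        stop(sprintf("planted decamer %s does not satisfy rule %s", dec,
                     item$rule), call. = FALSE)
      }
    }
    start <- tss_to_local(item$tss_position, nchar(dec))
    for (leaf in tips) {
      reserve(leaf, start, nchar(dec))
      leaves[[leaf]] <- plant(leaf, leaves[[leaf]], dec, start)
      truth[[length(truth) + 1L]] <- tibble::tibble(
        kind = "carg", leaf = leaf, motif = dec, planted = dec,
        start = start, tss_position = item$tss_position,
        substitutions = 0L)
    }
  }

  for (item in spec$planted_motifs) {
    km <- toupper(item$kmer)
    width <- nchar(km)
    lost <- if (is.null(item$lost)) character() else item$lost
    carriers <- setdiff(tips, lost)
    subs <- item$substitutions %||% 0L
    subs <- if (length(subs) == 1L && is.null(names(subs))) {
      stats::setNames(rep(as.integer(subs), length(carriers)), carriers)
    } else {
      stats::setNames(as.integer(subs[carriers]), carriers)
    }
    if (!is.null(item$tss_position)) {
      start <- tss_to_local(item$tss_position, width)
    } else {
      free <- NULL
      for (try in 1:200) {
        cand_start <- sample(L - width + 1L, 1L)
        span <- cand_start:(cand_start + width - 1L)
        if (!length(unlist(lapply(occupied[carriers], intersect, span)))) {
          free <- cand_start; break
        }
      }
      if (is.null(free)) stop("could not place planted motif without collision",
                              call. = FALSE)
      start <- free
    }
    for (leaf in carriers) {
      realised <- .substitute_kmer(km, subs[[leaf]])
      reserve(leaf, start, width)
      leaves[[leaf]] <- plant(leaf, leaves[[leaf]], realised, start)
      truth[[length(truth) + 1L]] <- tibble::tibble(
        kind = "motif", leaf = leaf, motif = km, planted = realised,
        start = start, tss_position = start - L - 1L,
        substitutions = subs[[leaf]])
    }
  }

  promoters <- lapply(tips, function(id) {
    promoter_record(id, paste(leaves[[id]], collapse = ""),
                    tss_pos = L + 1L)
  })
  names(promoters) <- tips
  list(promoters = promoters, tree = tree,
       truth = if (length(truth)) dplyr::bind_rows(truth) else
         tibble::tibble(kind = character(), leaf = character(),
                        motif = character(), planted = character(),
                        start = integer(), tss_position = integer(),
                        substitutions = integer()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specification for a simulated bisulfite clone experiment
#'
#' @param ref_length Reference region length in bp (ignored when
#'   `reference` is supplied).
#' @param reference Optional reference sequence; random uniform otherwise.
#' @param p_cpg,p_chg,p_chh Per-site methylation probabilities by context.
#'   Defaults depict a heavily methylated plant promoter region (CpG 0.8,
#'   CHG 0.5, CHH 0.1).
#' @param conversion_efficiency Probability that an unmethylated C is read
#'   as T after bisulfite treatment (default 0.99).
#' @param n_clones Number of sequenced colonies (default 10).
#' @param error_rate Per-base sequencing error probability (default 0.001).
#' @param seed Integer seed.
#' @return An `epi_sim_spec` object.
#' @export
epi_sim_spec <- function(ref_length = 400L, reference = NULL,
                         p_cpg = 0.8, p_chg = 0.5, p_chh = 0.1,
                         conversion_efficiency = 0.99, n_clones = 10L,
                         error_rate = 0.001, seed = 1L) {
  stopifnot(all(c(p_cpg, p_chg, p_chh, conversion_efficiency, error_rate)
                >= 0),
            all(c(p_cpg, p_chg, p_chh, conversion_efficiency, error_rate)
                <= 1),
            n_clones >= 1L)
  structure(
    list(ref_length = as.integer(ref_length), reference = reference,
         p_cpg = p_cpg, p_chg = p_chg, p_chh = p_chh,
         conversion_efficiency = conversion_efficiency,
         n_clones = as.integer(n_clones), error_rate = error_rate,
         seed = as.integer(seed)),
    class = "epi_sim_spec")
}

#' Generate a bisulfite clone set with known per-site methylation truth
#'
#' Each clone methylates every reference cytosine independently with its
#' context's probability; unmethylated cytosines convert to T with the
#' conversion efficiency; uniform sequencing errors are applied last. The
#' truth table records each site's context, true probability and realised
#' per-clone methylation count.
#'
#' @param spec An [epi_sim_spec()].
#' @return A list with `cloneset` (a [bisulfite_clone_set()]), `truth`
#'   (tibble `position`, `context`, `p_true`, `n_methylated_true`), and
#'   `states` (logical matrix, clones x cytosines, of true methylation).
#' @export
gen_bisulfite <- function(spec) {
  stopifnot(inherits(spec, "epi_sim_spec"))
  set.seed(spec$seed)
  reference <- if (!is.null(spec$reference)) toupper(spec$reference) else
    paste(sample(c("A", "C", "G", "T"), spec$ref_length, replace = TRUE),
          collapse = "")
  ctx <- .cytosine_contexts(reference)
  p_true <- c(CpG = spec$p_cpg, CHG = spec$p_chg, CHH = spec$p_chh)[
    ctx$context]
  refc <- strsplit(reference, "")[[1]]

  states <- matrix(FALSE, spec$n_clones, nrow(ctx))
  clones <- character(spec$n_clones)
  for (cl in seq_len(spec$n_clones)) {
    chars <- refc
    meth <- stats::runif(nrow(ctx)) < p_true
    states[cl, ] <- meth
    convert <- !meth & (stats::runif(nrow(ctx)) < spec$conversion_efficiency)
    chars[ctx$position[convert]] <- "T"
    if (spec$error_rate > 0) {
      err <- which(stats::runif(length(chars)) < spec$error_rate)
      for (i in err) {
        chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
      }
    }
    clones[cl] <- paste(chars, collapse = "")
  }
  names(clones) <- sprintf("clone%02d", seq_len(spec$n_clones))
  list(
    cloneset = bisulfite_clone_set(reference, clones, "synthetic"),
    truth = tibble::tibble(position = ctx$position, context = ctx$context,
                           p_true = unname(p_true),
                           n_methylated_true = colSums(states)),
    states = states)
}

#' Specification for simulated ChIP-qPCR and dual-luciferase assays
#'
#' @param antibody ChIP antibody (decides the internal control region).
#' @param region Target region label (default `"ATG"`).
#' @param tissue_abundance Named vector of true target abundances relative
#'   to the internal control, one per tissue.
#' @param ct_sd Gaussian Ct noise standard deviation (cycles).
#' @param n_bio,n_tech Biological and technical replicate counts (the
#'   conventional ChIP design here is 2 biological x 3 technical).
#' @param base_ct Mean control Ct (cycles).
#' @param organ_means Named vector of true mean relative luciferase
#'   activities per organ.
#' @param luc_cv Multiplicative (lognormal) coefficient of variation of
#'   firefly readings around `organ_mean x renilla`.
#' @param n_luc Luciferase replicates per organ (default 6).
#' @param renilla_mean,renilla_cv Lognormal parameters of the Renilla
#'   transfection-control readings.
#' @param seed Integer seed.
#' @return An `assay_sim_spec` object.
#' @export
assay_sim_spec <- function(antibody = "H3K9K14ac", region = "ATG",
                           tissue_abundance = c(lip = 4.9, petal = 1),
                           ct_sd = 0.15, n_bio = 2L, n_tech = 3L,
                           base_ct = 24,
                           organ_means = c(lip = 3, column = 3,
                                           sepal = 1, petal = 1),
                           luc_cv = 0.2, n_luc = 6L,
                           renilla_mean = 1e5, renilla_cv = 0.3,
                           seed = 1L) {
  stopifnot(all(tissue_abundance > 0), ct_sd >= 0, n_bio >= 1L,
            n_tech >= 1L, all(organ_means > 0), luc_cv >= 0, n_luc >= 1L)
  structure(
    list(antibody = antibody, region = region,
         tissue_abundance = tissue_abundance, ct_sd = ct_sd,
         n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
         base_ct = base_ct, organ_means = organ_means, luc_cv = luc_cv,
         n_luc = as.integer(n_luc), renilla_mean = renilla_mean,
         renilla_cv = renilla_cv, seed = as.integer(seed)),
    class = "assay_sim_spec")
}

# lognormal draws with a given mean and coefficient of variation
.rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate ChIP-qPCR Ct tables and luciferase readings with known truth
#'
#' Ct values are `base_ct - log2(true abundance) + N(0, ct_sd)` per
#' technical replicate (abundance 1 for the internal control); firefly
#' readings are `organ mean x renilla x lognormal(CV)`.
#'
#' @param spec An [assay_sim_spec()].
#' @return A list with `chip` (tibble `tissue`, `antibody`, `region`,
#'   `bio_rep`, `tech_rep`, `ct`), `luciferase` (tibble `construct`,
#'   `organ`, `replicate`, `firefly`, `renilla`), and `truth` (list of the
#'   true abundances and organ means).
#' @export
gen_assays <- function(spec) {
  stopifnot(inherits(spec, "assay_sim_spec"))
  set.seed(spec$seed)
  control <- chip_control_region(spec$antibody)
  rows <- list()
  for (tissue in names(spec$tissue_abundance)) {
    for (b in seq_len(spec$n_bio)) {
      for (region in c(spec$region, control)) {
        abundance <- if (region == control) 1 else
          spec$tissue_abundance[[tissue]]
        ct <- spec$base_ct - log2(abundance) +
          stats::rnorm(spec$n_tech, 0, spec$ct_sd)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          tissue = tissue, antibody = spec$antibody, region = region,
          bio_rep = b, tech_rep = seq_len(spec$n_tech), ct = ct)
      }
    }
  }
  chip <- dplyr::bind_rows(rows)

  luc <- dplyr::bind_rows(lapply(names(spec$organ_means), function(org) {
    renilla <- .rlnorm_cv(spec$n_luc, spec$renilla_mean, spec$renilla_cv)
    firefly <- spec$organ_means[[org]] * renilla *
      .rlnorm_cv(spec$n_luc, 1, spec$luc_cv)
    tibble::tibble(construct = "pJD-sim", organ = org,
                   replicate = seq_len(spec$n_luc),
                   firefly = firefly, renilla = renilla)
  }))

  list(chip = chip, luciferase = luc,
       truth = list(tissue_abundance = spec$tissue_abundance,
                    organ_means = spec$organ_means))
}
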