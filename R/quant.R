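#' Internal control used to normalise a ChIP antibody
#'
#' Active-chromatin marks (H3K4me3, H3K9K14ac) are normalised to the
#' euchromatic control locus ACTIN2; the repressive mark H3K9me2 to the
#' heterochromatic retrotransposon Ta3.
#'
#' @param antibody One of `"H3K4me3"`, `"H3K9K14ac"`, `"H3K9me2"`.
#' @return The control region name.
#' @export
chip_control_region <- function(antibody) {
  switch(antibody,
         H3K4me3 = "ACTIN2", H3K9K14ac = "ACTIN2", H3K9me2 = "Ta3",
         stop(sprintf("no internal control defined for antibody '%s'",
                      antibody), call. = FALSE))
}

#' Internal-control-normalised ChIP-qPCR enrichment
#'
#' Relative abundance by the delta-Ct method: within each biological
#' replicate, technical-replicate Ct values are averaged for the target
#' region and for the antibody's internal control, and the replicate's
#' relative amount is `efficiency^-(Ct_target - Ct_control)`. Biological
#' replicates are then averaged (normalisation before averaging avoids
#' pseudo-replication). The standard deviation is propagated to the
#' estimate by the first-order delta method from the technical-replicate Ct
#' variances.
#'
#' @param wells A data frame of wells for a single tissue and antibody with
#'   columns `tissue`, `antibody`, `region`, `bio_rep`, `ct` (one row per
#'   technical replicate).
#' @param target_region Name of the target region (e.g. `"ATG"`).
#' @param efficiency Amplification efficiency base (2 = perfect doubling).
#' @return An `enrichment_estimate`: list with `tissue`, `antibody`,
#'   `region`, `relative_amount`, `sd`, `n_bio`, `n_tech`.
#' @export
relative_enrichment <- function(wells, target_region, efficiency = 2) {
  stopifnot(is.data.frame(wells),
            all(c("tissue", "antibody", "region", "bio_rep", "ct") %in%
                  names(wells)))
  if (length(unique(wells$tissue)) != 1L ||
      length(unique(wells$antibody)) != 1L) {
    stop("wells must cover exactly one tissue and one antibody",
         call. = FALSE)
  }
  if (any(!is.finite(wells$ct)) || any(wells$ct <= 0)) {
    stop("Ct values must be finite and positive", call. = FALSE)
  }
  antibody <- wells$antibody[1]
  control_region <- chip_control_region(antibody)
  tgt <- wells[wells$region == target_region, , drop = FALSE]
  ctl <- wells[wells$region == control_region, , drop = FALSE]
  if (!nrow(tgt)) stop(sprintf("no wells for target region '%s'",
                               target_region), call. = FALSE)
  if (!nrow(ctl)) {
    stop(sprintf("missing internal control '%s' required for %s",
                 control_region, antibody), call. = FALSE)
  }
  bio <- sort(intersect(unique(tgt$bio_rep), unique(ctl$bio_rep)))
  if (!length(bio)) stop("no biological replicate has both target and control",
                         call. = FALSE)
  le <- log(efficiency)
  rel <- var_rel <- numeric(length(bio))
  n_tech <- integer(length(bio))
  for (i in seq_along(bio)) {
    ct_t <- tgt$ct[tgt$bio_rep == bio[i]]
    ct_c <- ctl$ct[ctl$bio_rep == bio[i]]
    dct <- mean(ct_t) - mean(ct_c)
    rel[i] <- efficiency^(-dct)
    v_t <- if (length(ct_t) > 1L) stats::var(ct_t) / length(ct_t) else 0
    v_c <- if (length(ct_c) > 1L) stats::var(ct_c) / length(ct_c) else 0
    var_rel[i] <- (rel[i] * le)^2 * (v_t + v_c)
    n_tech[i] <- length(ct_t)
  }
  structure(
    list(tissue = wells$tissue[1], antibody = antibody,
         region = target_region,
         relative_amount = mean(rel),
         sd = sqrt(sum(var_rel)) / length(bio),
         n_bio = length(bio), n_tech = max(n_tech)),
    class = "enrichment_estimate")
}

#' @export
print.enrichment_estimate <- function(x, ...) {
  cat(sprintf(
    "<enrichment_estimate> %s %s @ %s: %.3g +/- %.3g (n_bio=%d, n_tech=%d)\n",
    x$tissue, x$antibody, x$region, x$relative_amount, x$sd, x$n_bio,
    x$n_tech))
  invisible(x)
}

#' Fold change between two tissues' enrichment estimates
#'
#' @param est_a,est_b [relative_enrichment()] estimates for the same
#'   antibody and region in two different tissues; the fold is a / b
#'   (ratio of normalised means), with delta-method uncertainty.
#' @return A list `fold`, `sd`, plus the two tissue labels.
#' @export
fold_between <- function(est_a, est_b) {
  stopifnot(inherits(est_a, "enrichment_estimate"),
            inherits(est_b, "enrichment_estimate"))
  if (est_a$antibody != est_b$antibody || est_a$region != est_b$region) {
    stop("fold requires matching antibody and region", call. = FALSE)
  }
  fold <- est_a$relative_amount / est_b$relative_amount
  sd <- abs(fold) * sqrt((est_a$sd / est_a$relative_amount)^2 +
                           (est_b$sd / est_b$relative_amount)^2)
  list(numerator = est_a$tissue, denominator = est_b$tissue,
       antibody = est_a$antibody, region = est_a$region,
       fold = fold, sd = sd)
}

#' Relative luciferase activity of one sample
#'
#' @param firefly Firefly luminometer reading (experimental reporter).
#' @param renilla Renilla luminometer reading (transfection control);
#'   must be strictly positive, otherwise the sample is rejected as a
#'   failed transfection control.
#' @return `firefly / renilla` (vectorised).
#' @export
luciferase_ratio <- function(firefly, renilla) {
  if (any(!is.finite(renilla)) || any(renilla <= 0)) {
    stop("Renilla reading <= 0: failed transfection control", call. = FALSE)
  }
  firefly / renilla
}

#' Compact letter display from pairwise t-tests
#'
#' All group pairs are compared by a two-tailed two-sample t-test
#' (Student's equal-variance by default, matching the classical "T-test";
#' Welch via `var_equal = FALSE`). Letters are built by insert-and-absorb
#' so that two groups share a letter iff their pairwise p-value is >=
#' `alpha`. Letter assignment is deterministic: groups are ordered by
#' decreasing mean and letters issued a, b, c, ... in that order. If both
#' groups of a pair have zero variance the pair is decided by exact
#' equality of means (logged as a message). No multiple-testing correction
#' is applied by default (`p_adjust = "holm"` is available).
#'
#' @param groups Named list of numeric replicate vectors (>= 2 groups, each
#'   with >= 2 replicates).
#' @param alpha Significance level (default 0.01).
#' @param var_equal Use the pooled-variance t-test (default `TRUE`).
#' @param p_adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @return A list with `table` (tibble `group`, `n`, `mean`, `sd`,
#'   `letters`, sorted by decreasing mean) and `pairwise_p` (symmetric
#'   matrix).
#' @export
letter_groups <- function(groups, alpha = 0.01, var_equal = TRUE,
                          p_adjust = "none") {
  stopifnot(is.list(groups), length(groups) >= 2L,
            !is.null(names(groups)), all(nzchar(names(groups))))
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("every group needs at least 2 replicates", call. = FALSE)
  }
  ids <- names(groups)
  means <- vapply(groups, mean, numeric(1))
  ord <- ids[order(-means, ids)]  # deterministic: by mean, ties by name
  p <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  pvec <- vapply(pairs, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      message(sprintf(
        "groups %s and %s both constant; comparing means exactly",
        pr[1], pr[2]))
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    }
    stats::t.test(a, b, var.equal = var_equal)$p.value
  }, numeric(1))
  if (p_adjust != "none") pvec <- stats::p.adjust(pvec, method = p_adjust)
  for (i in seq_along(pairs)) {
    p[pairs[[i]][1], pairs[[i]][2]] <- pvec[i]
    p[pairs[[i]][2], pairs[[i]][1]] <- pvec[i]
  }
  diag(p) <- 1

  # insert-and-absorb over significant pairs, in deterministic order
  letters_sets <- list(ord)
  for (pr in pairs) {
    if (p[pr[1], pr[2]] >= alpha) next
    new_sets <- list()
    for (s in letters_sets) {
      if (all(pr %in% s)) {
        new_sets <- c(new_sets, list(setdiff(s, pr[1])),
                      list(setdiff(s, pr[2])))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb subsets
    keep <- vapply(seq_along(new_sets), function(i) {
      !any(vapply(seq_along(new_sets), function(j) {
        j != i && all(new_sets[[i]] %in% new_sets[[j]]) &&
          (length(new_sets[[j]]) > length(new_sets[[i]]) || j < i)
      }, logical(1)))
    }, logical(1))
    letters_sets <- new_sets[keep]
  }
  # order letter sets by the best-ranked group they contain; label a, b, ...
  rank_of <- stats::setNames(seq_along(ord), ord)
  set_rank <- vapply(letters_sets, function(s) min(rank_of[s]), numeric(1))
  letters_sets <- letters_sets[order(set_rank)]
  lab <- letters[seq_along(letters_sets)]
  group_letters <- vapply(ord, function(g) {
    paste(lab[vapply(letters_sets, function(s) g %in% s, logical(1))],
          collapse = "")
  }, character(1))

  tab <- tibble::tibble(
    group = ord,
    n = vapply(groups[ord], length, integer(1)),
    mean = vapply(groups[ord], mean, numeric(1)),
    sd = vapply(groups[ord], stats::sd, numeric(1)),
    letters = unname(group_letters)
  )
  list(table = tab, pairwise_p = p, alpha = alpha)
}
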