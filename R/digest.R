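#' Predict methylation-sensitive restriction digestion
#'
#' Enumerates recognition sites on the reference top strand, marks each as
#' blocked or cuttable given the methylated cytosine positions, and returns
#' the fragment lengths produced by cutting at every unblocked site.
#' Supported enzymes:
#'
#' * `HpaII` — recognises CCGG; by default blocked when **either** cytosine
#'   of the site is methylated (set `hpaII_internal_only = TRUE` for the
#'   stricter internal-C-only convention).
#' * `MspI` — recognises CCGG; blocked **only** by methylation of the first
#'   (outer) cytosine (mCCGG); internal-C methylation is tolerated.
#' * `DraI` — recognises TTTAAA; insensitive to cytosine methylation.
#'
#' Combinations are written `"DraI+HpaII"` etc. and cut at the union of the
#' member enzymes' unblocked cut positions.
#'
#' @param reference Nucleotide string (top strand).
#' @param methylated_positions Integer vector of 1-based positions of
#'   methylated cytosines on the top strand (symmetric methylation of the
#'   bottom strand is assumed and not separately specified).
#' @param enzymes Character vector of enzyme names and/or `+`-joined
#'   combinations. Unknown names are rejected.
#' @param hpaII_internal_only If `TRUE`, HpaII is blocked only by
#'   methylation of the internal C of CCGG.
#' @return A named list (one entry per requested enzyme/combination) of
#'   objects with `enzyme`, `site_positions` (1-based starts of recognition
#'   sites, per member enzyme), `blocked` (logical per site), `cut_positions`
#'   (position after which the duplex is cut), and `fragments` (integer
#'   lengths summing to `nchar(reference)`).
#' @export
digest_predict <- function(reference, methylated_positions = integer(),
                           enzymes = c("HpaII", "MspI"),
                           hpaII_internal_only = FALSE) {
  reference <- toupper(reference)
  meth <- as.integer(methylated_positions)
  refc <- strsplit(reference, "")[[1]]
  if (any(meth < 1L | meth > length(refc))) {
    stop("methylated position outside the reference", call. = FALSE)
  }
  if (length(meth) && any(refc[meth] != "C")) {
    stop("methylated positions must point at reference cytosines",
         call. = FALSE)
  }
  out <- lapply(enzymes, function(e) {
    .digest_one(reference, meth, e, hpaII_internal_only)
  })
  names(out) <- enzymes
  out
}

.enzyme_defs <- list(
  # cut_offset: the cut falls after site_start + cut_offset - 1
  HpaII = list(site = "CCGG", cut_offset = 1L),
  MspI  = list(site = "CCGG", cut_offset = 1L),
  DraI  = list(site = "TTTAAA", cut_offset = 3L)
)

.find_sites <- function(reference, site) {
  m <- gregexpr(sprintf("(?=%s)", site), reference, perl = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

.site_blocked <- function(enzyme, starts, meth, hpaII_internal_only) {
  if (enzyme == "DraI") return(rep(FALSE, length(starts)))
  outer_meth <- starts %in% meth
  inner_meth <- (starts + 1L) %in% meth
  if (enzyme == "HpaII") {
    if (hpaII_internal_only) inner_meth else (outer_meth | inner_meth)
  } else if (enzyme == "MspI") {
    outer_meth
  } else {
    stop(sprintf("unknown enzyme: %s", enzyme), call. = FALSE)
  }
}

.digest_one <- function(reference, meth, enzyme, hpaII_internal_only) {
  members <- strsplit(enzyme, "+", fixed = TRUE)[[1]]
  unknown <- setdiff(members, names(.enzyme_defs))
  if (length(unknown)) {
    stop(sprintf("unknown enzyme: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  site_positions <- list(); blocked <- list(); cuts <- integer()
  for (m in members) {
    def <- .enzyme_defs[[m]]
    starts <- .find_sites(reference, def$site)
    bl <- .site_blocked(m, starts, meth, hpaII_internal_only)
    site_positions[[m]] <- starts
    blocked[[m]] <- bl
    cuts <- c(cuts, starts[!bl] + def$cut_offset - 1L)
  }
  cuts <- sort(unique(cuts))
  fragments <- diff(c(0L, cuts, nchar(reference)))
  fragments <- fragments[fragments > 0L]
  list(enzyme = enzyme, site_positions = site_positions, blocked = blocked,
       cut_positions = cuts, fragments = as.integer(fragments))
}
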