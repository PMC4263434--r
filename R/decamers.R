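#' Published CArG-box decamers of the PeMADS2-6 promoter regions
#'
#' The catalog of putative CArG-box decamers reported for the upstream
#' regions of the five Phalaenopsis B-class MADS-box genes (PeMADS2-6),
#' with their published TSS-relative locations and the consensus rule each
#' was called under: `"core"` for the 9-of-10 CC(A/T)6GG standard and
#' `"relaxed"` for the exact C(A/T)8G standard. Duplicate sequences at
#' different locations are distinct rows. One location was printed with an
#' extra digit in the original table; the value used here (-1912) follows
#' the running text.
#'
#' @return A tibble with columns `promoter`, `decamer`, `location` (signed
#'   TSS-relative position of the reported hit), and `rule`.
#' @export
pemads_carg_decamers <- function() {
  tibble::tribble(
    ~promoter, ~decamer,     ~location, ~rule,
    "PeMADS2", "CCCTAAATGG",     -214L, "core",
    "PeMADS2", "CCATTCTAGG",     -248L, "core",
    "PeMADS2", "CTTTAAATGG",     -318L, "core",
    "PeMADS2", "CTATATTAAG",     -750L, "relaxed",
    "PeMADS2", "CATAATTTTG",    -1254L, "relaxed",
    "PeMADS2", "CCAAAATTTG",    -1548L, "core",
    "PeMADS2", "CTAATTTTAG",    -1891L, "relaxed",
    "PeMADS2", "CAAAATTTAG",    -2236L, "relaxed",
    "PeMADS2", "CATATTAAAG",    -2586L, "relaxed",
    "PeMADS3", "CAAAAAAAAG",     -443L, "relaxed",
    "PeMADS3", "CTTTTATAAG",    -1097L, "relaxed",
    "PeMADS4", "CTTATAAAAG",      -65L, "relaxed",
    "PeMADS4", "CTATTATAGG",     -434L, "core",
    "PeMADS4", "CATATTATAG",     -559L, "relaxed",
    "PeMADS4", "CATATTTTGG",    -1231L, "core",
    "PeMADS4", "CCTATGTAGG",    -1912L, "core",
    "PeMADS4", "CATATATTAG",    -2523L, "relaxed",
    "PeMADS4", "CTTTTTTATG",    -2656L, "relaxed",
    "PeMADS4", "CAAAATTTTG",    -2980L, "relaxed",
    "PeMADS4", "CAAAATTTTG",    -3258L, "relaxed",
    "PeMADS5", "GCTTAATTGG",     -175L, "core",
    "PeMADS5", "TCAAAATTGG",     -738L, "core",
    "PeMADS5", "CATAAATATG",     -862L, "relaxed",
    "PeMADS5", "CTTTATATTG",    -1041L, "relaxed",
    "PeMADS5", "CGATTTAAGG",    -1263L, "core",
    "PeMADS6", "CCAAATTTGA",     -678L, "core",
    "PeMADS6", "CAAATTTAAG",     -774L, "relaxed",
    "PeMADS6", "GCAAAATAGG",     -881L, "core"
  )
}
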