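test_that("pairwise conservation handles identity and disjoint sequences", {
  x <- "ACGTTGCACGA"
  m <- pairwise_conserved(x, x, k = 11, max_mutations = 0)
  expect_identical(nrow(m), 1L)
  expect_identical(m$ancestral, x)
  expect_identical(m$score, 0)

  # alphabets restricted to disjoint halves share no k-mer
  a <- paste(sample(c("A", "C"), 60, TRUE), collapse = "")
  b <- paste(sample(c("G", "T"), 60, TRUE), collapse = "")
  expect_identical(nrow(pairwise_conserved(a, b, k = 11)), 0L)

  expect_error(pairwise_conserved("ACGT", "ACGT", k = 11), "at least k")
})

test_that("pairwise conservation equals the all-pairs Hamming oracle", {
  set.seed(23)
  for (rep in 1:6) {
    a <- random_dna(200); b <- random_dna(200)
    got <- pairwise_conserved(a, b, k = 11, max_mutations = 0,
                              merge = FALSE)
    expect_identical(got$ancestral, oracle_pairwise_kmers(a, b, 11, 0))
  }
  for (rep in 1:4) {
    a <- random_dna(60); b <- random_dna(60)
    got <- pairwise_conserved(a, b, k = 8, max_mutations = 1)
    expect_identical(got$ancestral, oracle_pairwise_kmers(a, b, 8, 1))
  }
})

test_that("a longer shared substring is merged into one maximal motif", {
  set.seed(29)
  core <- "ACGTTGCACGATCG"  # 14 bp shared run
  a <- paste0(paste(sample(c("A", "C"), 40, TRUE), collapse = ""), core,
              paste(sample(c("A", "C"), 40, TRUE), collapse = ""))
  b <- paste0(paste(sample(c("G", "T"), 40, TRUE), collapse = ""), core,
              paste(sample(c("G", "T"), 40, TRUE), collapse = ""))
  merged <- pairwise_conserved(a, b, k = 11, max_mutations = 0)
  raw <- pairwise_conserved(a, b, k = 11, max_mutations = 0, merge = FALSE)
  expect_identical(merged$ancestral, core)
  expect_identical(nrow(raw), 4L)  # 14 - 11 + 1 tiling 11-mers
})

test_that("substring parsimony on two leaves reduces to the pairwise scan", {
  set.seed(31)
  for (D in 0:1) {
    for (rep in 1:5) {
      seqs <- c(A = random_dna(60), B = random_dna(60))
      pw <- pairwise_conserved(seqs[["A"]], seqs[["B"]], k = 8,
                               max_mutations = D, merge = FALSE)
      sp <- substring_parsimony(
        seqs, tree = "(A,B);",
        footprint_params(k = 8, max_mutations = D, merge = FALSE))
      expect_identical(sp$ancestral, pw$ancestral)
      expect_identical(sp$substitutions, pw$substitutions)
    }
  }
})

# four leaves whose backgrounds share nothing >= k, with a planted 11-mer
quartet_with_motif <- function(motif, mutated_leaf = NULL) {
  stems <- list(
    L1 = strrep("AC", 30), L2 = strrep("AG", 30),
    L3 = strrep("TC", 30), L4 = strrep("TG", 30))
  mut <- motif
  if (!is.null(mutated_leaf)) {
    substr(mut, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                                 substr(motif, 3, 3))[1]
  }
  seqs <- vapply(names(stems), function(id) {
    m <- if (!is.null(mutated_leaf) && id == mutated_leaf) mut else motif
    paste0(stems[[id]], m, stems[[id]])
  }, character(1))
  seqs
}

test_that("planted motifs are scored by parsimony with losses as budgeted", {
  motif <- "ACGTTGCACGA"
  tree <- "((L1,L2),(L3,L4));"

  exact <- substring_parsimony(quartet_with_motif(motif), tree,
                               footprint_params(k = 11, max_mutations = 0))
  expect_true(motif %in% exact$ancestral)
  expect_identical(exact$n_lost[exact$ancestral == motif], 0L)
  expect_identical(exact$score[exact$ancestral == motif], 0)

  # one substitution in one leaf: invisible at D=0 without losses,
  # recovered via a loss when one is budgeted, and at cost 1 when D=1
  seqs <- quartet_with_motif(motif, mutated_leaf = "L4")
  d0 <- substring_parsimony(seqs, tree, footprint_params(11, 0))
  expect_false(motif %in% d0$ancestral)
  d0l <- substring_parsimony(seqs, tree,
                             footprint_params(11, 0, max_losses = 1))
  expect_true(motif %in% d0l$ancestral)
  row <- d0l[d0l$ancestral == motif, ]
  expect_identical(row$lost_leaves[[1]], "L4")
  expect_identical(row$score, row$n_lost * 1)  # loss_cost = D + 1 = 1
  d1 <- substring_parsimony(seqs, tree, footprint_params(11, 1))
  expect_true(motif %in% d1$ancestral)
  expect_identical(d1$substitutions[d1$ancestral == motif], 1L)
  expect_identical(d1$n_lost[d1$ancestral == motif], 0L)
})

test_that("losses are sound and never spent when unnecessary", {
  motif <- "ACGTTGCACGA"
  tree <- "((L1,L2),(L3,L4));"
  res <- substring_parsimony(quartet_with_motif(motif), tree,
                             footprint_params(11, 0, max_losses = 2))
  row <- res[res$ancestral == motif, ]
  expect_identical(row$n_lost, 0L)
  # a reported motif always satisfies the budgets
  expect_true(all(res$substitutions <= 0L))
  expect_true(all(res$n_lost <= 2L))
})

test_that("the motif set is monotone in the mutation budget D", {
  set.seed(37)
  for (rep in 1:4) {
    seqs <- c(A = random_dna(70), B = random_dna(70), C = random_dna(70))
    m0 <- substring_parsimony(seqs, NULL,
                              footprint_params(7, 0, merge = FALSE))
    m1 <- substring_parsimony(seqs, NULL,
                              footprint_params(7, 1, merge = FALSE))
    expect_true(all(m0$ancestral %in% m1$ancestral))
  }
})

test_that("conservation at size k+1 implies conservation of both k-windows", {
  set.seed(41)
  for (rep in 1:5) {
    shared <- random_dna(9)  # guarantees at least two conserved 8-mers
    seqs <- c(A = paste0(random_dna(60), shared, random_dna(60)),
              B = paste0(random_dna(60), shared, random_dna(60)))
    big <- substring_parsimony(seqs, NULL,
                               footprint_params(8, 0, merge = FALSE))
    expect_gt(nrow(big), 0L)
    small <- substring_parsimony(seqs, NULL,
                                 footprint_params(7, 0, merge = FALSE))
    for (m in big$ancestral) {
      expect_true(substr(m, 1, 7) %in% small$ancestral)
      expect_true(substr(m, 2, 8) %in% small$ancestral)
    }
  }
})

test_that("identical inputs give identical ordered output", {
  set.seed(43)
  seqs <- c(A = random_dna(100), B = random_dna(100), C = random_dna(100))
  p <- footprint_params(7, 1, merge = FALSE)
  expect_identical(substring_parsimony(seqs, NULL, p),
                   substring_parsimony(seqs, NULL, p))
})

test_that("tree/sequence mismatches are rejected with the missing ids", {
  seqs <- c(A = strrep("ACGT", 10), B = strrep("TGCA", 10))
  expect_error(substring_parsimony(seqs, "(A,X);", footprint_params(8, 0)),
               "X")
})

test_that("planted motifs are recovered iff mutations fit the budget", {
  tree <- "((L1,L2),(L3,L4));"
  recovered <- matrix(NA, nrow = 50, ncol = 2,
                      dimnames = list(NULL, c("m1_D0", "m1_D1")))
  for (s in 1:50) {
    spec <- promoter_sim_spec(
      tree, root_length = 120, substitution_prob = 0.4,
      planted_motifs = list(list(
        kmer = "ACGTTGCACGA",
        substitutions = c(L1 = 0L, L2 = 0L, L3 = 0L, L4 = 1L))),
      seed = 1000 + s)
    gp <- gen_promoters(spec)
    d0 <- substring_parsimony(gp$promoters, gp$tree,
                              footprint_params(11, 0, merge = FALSE))
    d1 <- substring_parsimony(gp$promoters, gp$tree,
                              footprint_params(11, 1, merge = FALSE))
    recovered[s, ] <- c("ACGTTGCACGA" %in% d0$ancestral,
                        "ACGTTGCACGA" %in% d1$ancestral)
  }
  # one planted substitution: never recoverable at D=0, always at D=1
  expect_false(any(recovered[, "m1_D0"]))
  expect_true(all(recovered[, "m1_D1"]))
})

test_that("motif maps preserve per-promoter occurrence order", {
  m1 <- "ACGTTGCACGA"; m2 <- "GGATCCTTAGC"
  seqs <- c(P1 = paste0(strrep("AC", 10), m1, strrep("AC", 10), m2,
                        strrep("AC", 5)),
            P2 = paste0(strrep("TG", 10), m2, strrep("TG", 10), m1,
                        strrep("TG", 5)))
  motifs <- substring_parsimony(seqs, NULL, footprint_params(11, 0))
  mm <- motif_map(seqs, motifs)
  expect_identical(mm$motif[mm$promoter_id == "P1"], c(m1, m2))
  expect_identical(mm$motif[mm$promoter_id == "P2"], c(m2, m1))
  empty <- motif_map(seqs, motifs[0, ])
  expect_identical(nrow(empty), 0L)
})
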