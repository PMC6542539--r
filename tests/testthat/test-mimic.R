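test_that("mutation strings parse and apply with U/T equivalence", {
  m <- parse_mutations("T1101A")
  expect_equal(m$position, 1101L)
  expect_equal(m$ref, "T")
  expect_equal(m$alt, "A")
  expect_error(parse_mutations("T1101"), "cannot parse")
  expect_error(parse_mutations("T1101T"), "identical")

  expect_equal(apply_mutations("GGT", "T3A"), "GGA")
  expect_equal(apply_mutations("GGU", "T3A"), "GGA")   # U matches T ref
  expect_equal(nchar(apply_mutations(strrep("ACGT", 25), "C2G")), 100)
  err <- expect_error(apply_mutations("GGT", "A2C"), "position 2")
  expect_match(conditionMessage(err), "expected A")
  expect_match(conditionMessage(err), "found G")
  expect_error(apply_mutations("GGT", "T9A"), "outside")
})

test_that("mutations apply identically in any order", {
  cds <- "GGTACCGGTACC"
  muts <- c("T3A", "C6G", "G8T")
  perms <- list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1), c(3, 1, 2))
  res <- vapply(perms, function(p) apply_mutations(cds, muts[p]), "")
  expect_length(unique(res), 1)
  expect_equal(res[1], "GGAACGGTTACC")
})

test_that("synonymy follows the standard genetic code", {
  expect_true(is_synonymous(strrep("GGT", 4), "T3A"))    # GGT->GGA, Gly
  # Met has a single codon: every substitution is nonsynonymous
  cds <- paste0("ATG", "GGT")
  for (mut in c("A1C", "A1G", "A1T", "T2A", "T2C", "T2G",
                "G3A", "G3C", "G3T"))
    expect_false(is_synonymous(cds, mut))
  expect_error(is_synonymous("ACGT", "A1C"), "multiple of 3")
})

test_that("synonymy agrees with full-sequence translation on all 576 cases", {
  has_bs <- requireNamespace("Biostrings", quietly = TRUE)
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  n_checked <- 0
  for (codon in codons) {
    for (pos in 1:3) {
      ref <- substr(codon, pos, pos)
      for (alt in setdiff(bases, ref)) {
        mut <- paste0(ref, pos, alt)
        got <- is_synonymous(codon, mut)
        mutated <- apply_mutations(codon, mut)
        want <- if (has_bs) {
          as.character(Biostrings::translate(
            Biostrings::DNAString(codon), no.init.codon = TRUE)) ==
            as.character(Biostrings::translate(
              Biostrings::DNAString(mutated), no.init.codon = TRUE))
        } else {
          aarsrip:::GENETIC_CODE_STANDARD[codon] ==
            aarsrip:::GENETIC_CODE_STANDARD[mutated]
        }
        expect_identical(got, unname(want),
                         label = paste("codon", codon, mut))
        n_checked <- n_checked + 1
      }
    }
  }
  expect_equal(n_checked, 576)
})

test_that("the scanner finds a planted mimic at the truth position", {
  sim <- simulate_cds_with_mimic(300, "GUG", insert_pos = 150,
                                 stem_len = 5, seed = 11)
  h <- scan_mimic(sim$seq)
  expect_equal(nrow(h), 1)
  expect_equal(h$triplet_pos, sim$truth$triplet_pos)
  expect_gte(h$stem_len, 2)
  # flank randomness does not move the hit
  for (seed in c(22, 33, 44)) {
    sim2 <- simulate_cds_with_mimic(300, "GUG", insert_pos = 150,
                                    stem_len = 5, seed = seed)
    h2 <- scan_mimic(sim2$seq)
    expect_equal(unique(h2$triplet_pos), 150)
  }
  # a sequence without the triplet yields no hits
  expect_equal(nrow(scan_mimic(strrep("AC", 30), "GUG")), 0)
})

test_that("scan completeness holds across planted stem lengths and positions", {
  set.seed(9)
  for (i in 1:15) {
    stem <- sample(3:6, 1)
    pos <- sample(30:160, 1)
    sim <- simulate_cds_with_mimic(200, "GUG", insert_pos = pos,
                                   stem_len = stem, seed = i)
    h <- scan_mimic(sim$seq, min_stem = 2)
    expect_true(pos %in% h$triplet_pos,
                label = paste("planted mimic at", pos, "stem", stem))
  }
})

test_that("mimic CDS generator validates its geometry", {
  expect_error(simulate_cds_with_mimic(100, "GUG", 50, stem_len = 0), ">= 3")
  expect_error(simulate_cds_with_mimic(100, "GUG", 2, stem_len = 5),
               "does not fit")
  expect_error(simulate_cds_with_mimic(100, "GUG", 99, stem_len = 5),
               "does not fit")
  sim <- simulate_cds_with_mimic(120, "GUG", 60, stem_len = 4, seed = 1)
  expect_equal(nchar(sim$seq), 120)
})

test_that("variant classification separates the three mutation classes", {
  toy <- "GGCACGUGGUGCC"   # 5-bp stem, loop GUG at 6-8
  # loop mutation GUG -> GAG: the anticodon-like sequence itself is lost
  expect_equal(classify_variant(toy, "U7A")$class, "anticodon_lost")
  # two stem bases broken: the refolded closing stem loses the outer pairs
  d <- classify_variant(toy, c("C3A", "G11A"))
  expect_equal(d$class, "stem_disrupted")
  expect_lt(d$diagnostics$pairs_retained, 0.5)
  # compensatory swap C3G/G11C keeps every closing-stem pair position
  p <- classify_variant(toy, c("C3G", "G11C"))
  expect_equal(p$class, "stem_preserved")
  expect_equal(p$diagnostics$pairs_retained, 1)
  # no mutations: the wild-type element classifies as preserved
  expect_equal(classify_variant(toy, character())$class, "stem_preserved")
  # cross-check the disrupt call against the enumeration oracle: no optimal
  # structure of the mutant keeps the wild-type outer stem pair (3,11)
  mut <- apply_mutations(toy, c("C3A", "G11A"))
  e <- enumerate_structures(mut)
  np <- vapply(e, nrow, integer(1))
  best <- e[np == max(np)]
  has_pair <- vapply(best, function(pp)
    any(pp[, 1] == 3 & pp[, 2] == 11), TRUE)
  expect_false(any(has_pair))
})

test_that("variant classification validates its inputs", {
  toy <- "GGCACGUGGUGCC"
  expect_error(classify_variant(toy, "U20A"), "outside the window")
  # CDS-coordinate mutations map into the window via window_start
  res <- classify_variant(toy, "U1007A", window_start = 1001)
  expect_equal(res$class, "anticodon_lost")
  expect_error(classify_variant("AAACCCAAA", "A2C"), "no 'GUG'")
  # anticodon_lost is decided from sequence alone even if folding would
  # relocate: mutating a loop base always reports anticodon_lost
  expect_equal(classify_variant(toy, c("G6A", "C3A", "G11A"))$class,
               "anticodon_lost")
})

test_that("FASTA sequences round-trip", {
  seqs <- c(geneA = "ATGGGTACCGTA", geneB = strrep("ACGT", 40))
  f <- tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  back <- read_cds_fasta(f)
  expect_equal(back, seqs)
  expect_error(read_cds_fasta(tempfile()), "not found")
})
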