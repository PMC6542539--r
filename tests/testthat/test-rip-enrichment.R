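test_that("RPM normalization scales each column to one million", {
  m <- matrix(c(50), 1, 1, dimnames = list("g1", "s"))
  ct <- count_table(m, data.frame(role = "Input", strain = "x",
                                  protocol = "TAP"))
  expect_equal(unname(normalize_rpm(ct)$rpm[1, 1]), 1e6)

  m2 <- matrix(c(30, 99970, 10, 99990), 2, 2,
               dimnames = list(c("g1", "g2"), NULL))
  samples <- data.frame(role = c("Input", "Bound"), strain = "x",
                        protocol = "TAP")
  colnames(m2) <- aarsrip:::sample_label(samples)
  rpm <- normalize_rpm(count_table(m2, samples))
  expect_equal(unname(rpm$rpm["g1", 1]), 300)   # 30 / 100,000 * 1e6
  expect_equal(unname(colSums(rpm$rpm)), rep(1e6, 2), tolerance = 1e-6)
})

test_that("an all-zero sample column is rejected by name", {
  m <- matrix(c(5, 3, 0, 0), 2, 2,
              dimnames = list(c("g1", "g2"), NULL))
  samples <- data.frame(role = c("Input", "Bound"), strain = "x",
                        protocol = "TAP")
  colnames(m) <- aarsrip:::sample_label(samples)
  ct <- count_table(m, samples)
  expect_error(normalize_rpm(ct), "x.TAP.Bound")
})

test_that("input-coverage filter uses an exclusive <15 boundary and drops noncoding", {
  # 10M-read input library: counts 149 / 150 / 5000 give RPM 14.9 / 15 / 500
  tot <- 1e7
  m <- cbind(c(149, 150, 5000, tot - 5299), c(1, 1, 1, tot - 3))
  rownames(m) <- c("g1", "g2", "g3", "filler")
  samples <- data.frame(role = c("Input", "Bound"), strain = "x",
                        protocol = "TAP")
  colnames(m) <- aarsrip:::sample_label(samples)
  ct <- count_table(m, samples, coding = c(TRUE, TRUE, FALSE, TRUE))
  rpm <- normalize_rpm(ct)
  kept <- filter_transcripts(rpm, "x", "TAP")
  expect_false("g1" %in% kept)   # 14.9 < 15 dropped
  expect_true("g2" %in% kept)    # exactly 15 retained
  expect_false("g3" %in% kept)   # noncoding dropped despite high coverage
  kept2 <- filter_transcripts(rpm, "x", "TAP",
                              filter_params(0, drop_noncoding = FALSE))
  expect_setequal(kept2, rownames(m))
  kept3 <- filter_transcripts(rpm, "x", "TAP",
                              filter_params(0, drop_noncoding = TRUE))
  expect_setequal(kept3, c("g1", "g2", "filler"))
})

test_that("RIP efficiency is Bound RPM over Input RPM", {
  ct <- tiny_experiment()
  rpm <- normalize_rpm(ct)
  e <- rip_efficiency(rpm, "HisRS", "TAP", genes = paste0("g", 1:5))
  expect_equal(e$efficiency[e$gene_id == "g1"], 300 / 50)  # 6.0
  expect_equal(e$efficiency[e$gene_id == "g3"], 5 / 200)
  # identical Bound and Input columns give efficiency 1 everywhere
  m <- cbind(c(10, 90), c(10, 90))
  rownames(m) <- c("a", "b")
  samples <- data.frame(role = c("Input", "Bound"), strain = "x",
                        protocol = "TAP")
  colnames(m) <- aarsrip:::sample_label(samples)
  e2 <- rip_efficiency(normalize_rpm(count_table(m, samples)), "x", "TAP",
                       genes = c("a", "b"))
  expect_equal(e2$efficiency, c(1, 1))
  # a gene absent from Bound has efficiency 0
  m[1, 2] <- 0
  e3 <- rip_efficiency(normalize_rpm(count_table(m, samples)), "x", "TAP",
                       genes = c("a", "b"))
  expect_equal(e3$efficiency[e3$gene_id == "a"], 0)
  # missing pair errors
  expect_error(rip_efficiency(rpm, "nope", "TAP"), "no Input sample")
})

test_that("background correction subtracts the untagged efficiency on the gene intersection", {
  t_eff <- data.frame(gene_id = c("a", "b", "c"), rpm_input = 1,
                      rpm_bound = 1, efficiency = c(6, 2, 1))
  u_eff <- data.frame(gene_id = c("a", "b"), efficiency = c(1.5, 2))
  cc <- background_correct(t_eff, u_eff)
  expect_equal(cc$corrected, c(4.5, 0))
  expect_false("c" %in% cc$gene_id)       # failed filter in untagged
  cz <- background_correct(t_eff, u_eff, mode = "zero")
  expect_equal(cz$corrected[cz$gene_id == "c"], 1)   # untagged treated as 0
  # self-subtraction gives exactly zero
  cs <- background_correct(t_eff, t_eff[, c("gene_id", "efficiency")])
  expect_equal(cs$corrected, c(0, 0, 0))
})

test_that("ranking is descending in corrected value with a total tie-break order", {
  rec <- data.frame(gene_id = c("a", "b", "c"), rpm_bound = 1,
                    corrected = c(0.1, 5, 2))
  r <- rank_genes(rec)
  expect_equal(r$gene_id[r$rank], c("b", "c", "a"))
  expect_equal(r$rank[match(c("a", "b", "c"), r$gene_id)], c(3, 1, 2))

  # ties: larger rpm_bound first, then lexicographic gene id
  rec2 <- data.frame(gene_id = c("z", "y", "b", "a"),
                     rpm_bound = c(5, 9, 3, 3), corrected = c(1, 1, 1, 1))
  r2 <- rank_genes(rec2)
  expect_equal(r2$gene_id, c("y", "z", "a", "b"))
  # brute-force check that the stated order is total: every permutation of
  # the input rows ranks identically
  for (p in list(c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 2, 4))) {
    expect_equal(rank_genes(rec2[p, ])$gene_id, r2$gene_id)
  }
})

test_that("small tables rank exactly as the hand-computed ordering", {
  ct <- tiny_experiment()
  enr <- rip_enrichment(ct, "HisRS", "TAP", params = filter_params(0))
  # hand arithmetic: per-gene e_tagged - e_untagged (all libs total 1000,
  # so RPM ratios equal count ratios)
  et <- c(300, 30, 5, 40, 25) / c(50, 100, 200, 400, 250)
  eu <- c(50, 98, 210, 390, 252) / c(50, 100, 200, 400, 250)
  cc <- et - eu
  names(cc) <- paste0("g", 1:5)
  expected <- names(sort(cc, decreasing = TRUE))
  got <- enr$records$gene_id[enr$records$gene_id != "filler"]
  expect_equal(got, expected)
  expect_equal(enr$records$corrected[match(names(cc), enr$records$gene_id)],
               unname(cc))
})

test_that("scaling any sample column leaves efficiencies and ranks unchanged", {
  ct <- tiny_experiment()
  enr1 <- rip_enrichment(ct, "HisRS", "TAP", params = filter_params(0))
  ct2 <- ct
  ct2$counts[, 2] <- ct2$counts[, 2] * 7      # tagged Bound deeper library
  ct3 <- ct
  ct3$counts[, 1] <- ct3$counts[, 1] * 3      # tagged Input deeper library
  for (alt in list(ct2, ct3)) {
    enr2 <- rip_enrichment(alt, "HisRS", "TAP", params = filter_params(0))
    expect_equal(enr2$records$corrected, enr1$records$corrected)
    expect_equal(enr2$records$gene_id, enr1$records$gene_id)
  }
})

test_that("raising a gene's tagged Bound count never worsens its rank", {
  ct <- tiny_experiment()
  base <- rip_enrichment(ct, "HisRS", "TAP", params = filter_params(0))
  rank_of <- function(enr, g) enr$records$rank[match(g, enr$records$gene_id)]
  for (bump in c(10, 100, 400)) {
    ct2 <- ct
    ct2$counts["g3", 2] <- ct2$counts["g3", 2] + bump
    ct2$counts["filler", 2] <- ct2$counts["filler", 2] - bump
    enr2 <- rip_enrichment(ct2, "HisRS", "TAP", params = filter_params(0))
    expect_lte(rank_of(enr2, "g3"), rank_of(base, "g3"))
  }
})

test_that("count tables round-trip through TSV", {
  ct <- tiny_experiment()
  f <- tempfile(fileext = ".tsv")
  write_count_table(ct, f)
  back <- read_count_table(f)
  expect_equal(back$counts, ct$counts)
  expect_equal(back$samples$role, ct$samples$role)
  expect_equal(back$genes$coding, ct$genes$coding)
  expect_error(read_count_table(tempfile()), "not found")
})

test_that("count table validation rejects malformed input", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(count_table(m, data.frame(role = c("Bound", "Bound"),
                                         strain = "x", protocol = "TAP")),
               "matching Input")
  m2 <- m; m2[1, 1] <- -1
  expect_error(count_table(m2, data.frame(role = c("Input", "Bound"),
                                          strain = "x", protocol = "TAP")),
               "nonnegative")
  m3 <- m; rownames(m3) <- c("a", "a")
  expect_error(count_table(m3, data.frame(role = c("Input", "Bound"),
                                          strain = "x", protocol = "TAP")),
               "unique")
})
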