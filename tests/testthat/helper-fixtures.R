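# shared fixtures and independent oracles, built in code

# a tiny four-sample experiment (tagged + untagged, TAP) with known counts
tiny_experiment <- function(counts_tagged_bound = c(300, 30, 5, 40, 25),
                            lib = 1000) {
  n <- 5
  gene_id <- paste0("g", 1:n)
  inp <- c(50, 100, 200, 400, 250)
  m <- cbind(inp, counts_tagged_bound, inp, c(50, 98, 210, 390, 252))
  m <- rbind(m, lib - colSums(m))          # filler gene absorbs the rest
  rownames(m) <- c(gene_id, "filler")
  samples <- data.frame(role = c("Input", "Bound", "Input", "Bound"),
                        strain = c("HisRS", "HisRS", "untagged", "untagged"),
                        protocol = "TAP", stringsAsFactors = FALSE)
  colnames(m) <- paste(samples$strain, samples$protocol, samples$role,
                       sep = ".")
  count_table(m, samples)
}

# brute-force Venn decomposition over all membership patterns
venn_oracle <- function(lst) {
  genes <- sort(unique(unlist(lst)))
  out <- list()
  for (g in genes) {
    pat <- paste(names(lst)[vapply(lst, function(s) g %in% s, TRUE)],
                 collapse = "&")
    out[[pat]] <- c(out[[pat]], g)
  }
  out[order(names(out))]
}

# independent recursive count of non-crossing structures (no enumeration)
count_structures_oracle <- function(seq, min_loop = 3) {
  b <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  ok <- function(x, y) paste0(x, y) %in%
    c("AU", "UA", "GC", "CG", "GU", "UG")
  n <- length(b)
  memo <- new.env()
  cnt <- function(i, j) {
    if (j - i < min_loop + 1) return(1)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    tot <- cnt(i, j - 1)
    for (k in i:(j - min_loop - 1))
      if (ok(b[k], b[j]))
        tot <- tot + (if (k > i) cnt(i, k - 1) else 1) * cnt(k + 1, j - 1)
    memo[[key]] <- tot
    tot
  }
  cnt(1, n)
}

random_rna <- function(len) paste(sample(c("A", "C", "G", "U"), len,
                                         replace = TRUE), collapse = "")

recovery_run <- function(seed, n_genes = 2000, fold = 20, gene = 7,
                         dispersion = 0.1) {
  sim <- simulate_ripseq(rip_sim_params(
    n_genes = n_genes, dispersion = dispersion, seed = seed,
    planted = data.frame(gene = gene, fold = fold)))
  enr <- rip_enrichment(sim$counts, "tagged", "TAP")
  g <- sprintf("gene%05d", gene)
  i <- match(g, enr$records$gene_id)
  list(enr = enr, gene = g,
       rank1 = !is.na(i) && enr$records$rank[i] == 1,
       called = g %in% call_targets(enr)$genes)
}
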