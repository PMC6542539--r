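## Seeded generators for the three kinds of input the pipeline consumes:
## RIP-seq count tables with a planted enriched transcript, tiling-panel
## fRIP signals with a planted binding-site fragment, and coding sequences
## with a planted anticodon-mimic stem-loop. Seeds are explicit arguments;
## the caller's RNG state is saved and restored.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old))
      rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  force(code)
}

#' Parameters for the RIP-seq count simulator
#'
#' Defaults describe a bulk yeast RIP-seq experiment: about 5,000 detected
#' mRNAs, 10-18 million reads per library, gamma-Poisson (negative
#' binomial) count noise, and a bead background that captures every
#' transcript nonspecifically at the same rate in the tagged and untagged
#' strains — the assumption that justifies correcting by subtraction of
#' the untagged efficiency.
#'
#' @param n_genes number of genes (default 5000).
#' @param lib_size_input,lib_size_bound reads per Input / Bound library
#'   (default 12e6, within the 10-18 million per-sample range of a typical
#'   run).
#' @param dispersion negative binomial dispersion a, with
#'   var = mu + a * mu^2; 0 gives Poisson counts (default 0.1).
#' @param background_capture fraction of each transcript captured
#'   nonspecifically by the beads (default 0.05); shared by tagged and
#'   untagged strains.
#' @param planted data.frame with columns \code{gene} (index) and
#'   \code{fold} (enrichment of tagged-strain capture over background,
#'   >= 1); default none.
#' @param abundance_sdlog sdlog of the log-normal latent transcript
#'   abundances (default 1.2, a realistic bulk-mRNA spread under which
#'   the vast majority of genes clear a 15-RPM input floor).
#' @param strain,protocol labels for the tagged samples.
#' @param seed integer seed.
#' @return a \code{rip_sim_params} list.
#' @export
rip_sim_params <- function(n_genes = 5000, lib_size_input = 12e6,
                           lib_size_bound = 12e6, dispersion = 0.1,
                           background_capture = 0.05,
                           planted = NULL, abundance_sdlog = 1.2,
                           strain = "tagged", protocol = "TAP",
                           seed = 1) {
  if (!(is.numeric(n_genes) && n_genes >= 2))
    stop("invalid n_genes: need at least 2 genes")
  if (lib_size_input <= 0 || lib_size_bound <= 0)
    stop("invalid lib_size: library sizes must be positive")
  if (dispersion < 0) stop("invalid dispersion: must be >= 0")
  if (background_capture <= 0 || background_capture > 1)
    stop("invalid background_capture: must be in (0, 1]")
  if (is.null(planted))
    planted <- data.frame(gene = integer(), fold = numeric())
  stopifnot(all(c("gene", "fold") %in% names(planted)))
  if (nrow(planted)) {
    if (any(planted$fold < 1)) stop("invalid planted: folds must be >= 1")
    if (any(planted$gene < 1 | planted$gene > n_genes))
      stop("invalid planted: gene indices must be in 1..n_genes")
  }
  structure(list(n_genes = as.integer(n_genes),
                 lib_size_input = lib_size_input,
                 lib_size_bound = lib_size_bound,
                 dispersion = dispersion,
                 background_capture = background_capture,
                 planted = planted, abundance_sdlog = abundance_sdlog,
                 strain = strain, protocol = protocol,
                 seed = seed),
            class = "rip_sim_params")
}

rnb <- function(n, mu, dispersion) {
  if (dispersion == 0) stats::rpois(n, mu)
  else stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate a RIP-seq experiment with planted enrichment
#'
#' Draws latent log-normal transcript abundances, then four count columns:
#' tagged and untagged Input libraries (multinomial expectations over the
#' abundances) and tagged and untagged Bound libraries, where each gene's
#' capture is proportional to abundance times the bead-background rate,
#' multiplied — in the tagged strain only — by its planted enrichment
#' fold. Counts are negative binomial around these expectations. The truth
#' sidecar records what was planted and the latent abundances; the
#' analysis stages never see it.
#'
#' @param params a \code{\link{rip_sim_params}}.
#' @return list with \code{counts} (a \code{\link{count_table}} with four
#'   samples) and \code{truth} (list: \code{planted}, \code{abundance}).
#' @examples
#' sim <- simulate_ripseq(rip_sim_params(n_genes = 200, seed = 42,
#'   planted = data.frame(gene = 5, fold = 20)))
#' sim$counts
#' @export
simulate_ripseq <- function(params) {
  stopifnot(inherits(params, "rip_sim_params"))
  p <- params
  with_seed(p$seed, {
    abund <- stats::rlnorm(p$n_genes, meanlog = 0, sdlog = p$abundance_sdlog)
    fold <- rep(1, p$n_genes)
    fold[p$planted$gene] <- p$planted$fold
    frac_in <- abund / sum(abund)
    cap_un <- p$background_capture * abund
    cap_tag <- cap_un * fold
    counts <- cbind(
      rnb(p$n_genes, p$lib_size_input * frac_in, p$dispersion),
      rnb(p$n_genes, p$lib_size_bound * cap_tag / sum(cap_tag), p$dispersion),
      rnb(p$n_genes, p$lib_size_input * frac_in, p$dispersion),
      rnb(p$n_genes, p$lib_size_bound * cap_un / sum(cap_un), p$dispersion))
    rownames(counts) <- sprintf("gene%05d", seq_len(p$n_genes))
    samples <- data.frame(
      role = c("Input", "Bound", "Input", "Bound"),
      strain = c(p$strain, p$strain, "untagged", "untagged"),
      protocol = p$protocol, stringsAsFactors = FALSE)
    colnames(counts) <- sample_label(samples)
    list(counts = count_table(counts, samples),
         truth = list(planted = p$planted, abundance = abund))
  })
}

#' Parameters for the tiling-panel fRIP simulator
#'
#' Models mild-RNase fragmentation followed by pull-down: the fragment
#' carrying the binding site dominates the Bound signal, and partial
#' cleavage leaves longer fragments that light up the amplicons
#' immediately upstream of the site with geometrically decaying intensity.
#' The leak is truncated at \code{max_leak_depth} fragments: with ~200-nt
#' fragments and amplicons spaced ~117 nt apart, a site-containing
#' fragment rarely spans more than two upstream windows. The
#' fragmented-input signal reflects per-amplicon RT-PCR efficiency only.
#'
#' @param n_fragments number of tiling amplicons (default 14).
#' @param site_fragment index of the true binding-site fragment.
#' @param carryover partial-cleavage leak fraction per upstream fragment,
#'   in [0, 1) (default 0.4).
#' @param pcr_efficiency positive per-fragment amplification efficiency
#'   vector (default all 1).
#' @param max_leak_depth upstream fragments receiving leak (default 2).
#' @param baseline off-site Bound signal relative to the site (default
#'   0.02).
#' @param noise_sd sdlog of multiplicative log-normal intensity noise
#'   (default 0.1; 0 gives a deterministic panel).
#' @param cds_length,product_len panel geometry passed to
#'   \code{\link{design_tiling}} (defaults 1644 and 150).
#' @param seed integer seed.
#' @export
frip_sim_params <- function(n_fragments = 14, site_fragment = 10,
                            carryover = 0.4,
                            pcr_efficiency = rep(1, n_fragments),
                            max_leak_depth = 2, baseline = 0.02,
                            noise_sd = 0.1, cds_length = 1644,
                            product_len = 150, seed = 1) {
  if (site_fragment < 1 || site_fragment > n_fragments)
    stop("invalid site_fragment: must be in 1..n_fragments")
  if (carryover < 0 || carryover >= 1)
    stop("invalid carryover: must be in [0, 1)")
  if (length(pcr_efficiency) != n_fragments || any(pcr_efficiency <= 0))
    stop("invalid pcr_efficiency: need ", n_fragments, " positive values")
  structure(list(n_fragments = as.integer(n_fragments),
                 site_fragment = as.integer(site_fragment),
                 carryover = carryover, pcr_efficiency = pcr_efficiency,
                 max_leak_depth = as.integer(max_leak_depth),
                 baseline = baseline, noise_sd = noise_sd,
                 cds_length = cds_length, product_len = product_len,
                 seed = seed),
            class = "frip_sim_params")
}

#' Simulate a tiling-panel fRIP signal table
#'
#' @param params a \code{\link{frip_sim_params}}.
#' @return data.frame (a fragment signal table): \code{fragment},
#'   \code{start}, \code{end}, \code{bound}, \code{input}, with the truth
#'   site index as attribute \code{"site_fragment"}.
#' @export
simulate_frip <- function(params) {
  stopifnot(inherits(params, "frip_sim_params"))
  p <- params
  panel <- design_tiling(p$cds_length, p$n_fragments, p$product_len)
  with_seed(p$seed, {
    d <- p$site_fragment - panel$fragment       # upstream distance to site
    leak <- ifelse(d == 0, 1,
                   ifelse(d >= 1 & d <= p$max_leak_depth,
                          p$carryover^d, 0))
    noise <- function(n) if (p$noise_sd == 0) rep(1, n)
      else stats::rlnorm(n, 0, p$noise_sd)
    bound <- (leak + p$baseline) * p$pcr_efficiency *
      noise(p$n_fragments)
    input <- p$pcr_efficiency * noise(p$n_fragments)
    out <- data.frame(fragment = panel$fragment, start = panel$start,
                      end = panel$end, bound = bound, input = input)
    attr(out, "site_fragment") <- p$site_fragment
    out
  })
}

#' Simulate a coding sequence with a planted anticodon-mimic hairpin
#'
#' Builds a CDS-length sequence whose flanks are random and pairing-poor
#' (A-rich, no G/U outside the element) and embeds one designed hairpin:
#' a \code{stem_len}-bp stem of complementary C/G arms closing a 3-nt loop
#' that holds the query triplet, with the triplet's first base at
#' \code{insert_pos} (1-based). Because the flanks cannot pair, the
#' planted hairpin is the optimal fold of any window covering it.
#'
#' @param length total sequence length in nt.
#' @param triplet loop triplet (default "GUG").
#' @param insert_pos 1-based position of the triplet's first base.
#' @param stem_len stem length in base pairs (>= 3).
#' @param seed integer seed.
#' @param as_dna return DNA alphabet (default TRUE, as a CDS FASTA would).
#' @return list with \code{seq} (character), \code{truth} (list:
#'   \code{triplet_pos}, \code{hairpin_start}, \code{hairpin_end},
#'   \code{stem_len}).
#' @export
simulate_cds_with_mimic <- function(length, triplet = "GUG",
                                    insert_pos, stem_len = 5, seed = 1,
                                    as_dna = TRUE) {
  if (stem_len < 3) stop("stem_len must be >= 3")
  triplet <- as_rna(triplet)
  if (nchar(triplet) != 3) stop("triplet must be a 3-mer")
  h0 <- insert_pos - stem_len
  h1 <- insert_pos + 2 + stem_len
  if (h0 < 1 || h1 > length)
    stop("hairpin [", h0, ", ", h1, "] does not fit inside 1..", length)
  with_seed(seed, {
    flank <- function(n) if (n == 0) character() else
      sample(c("A", "C"), n, replace = TRUE, prob = c(0.9, 0.1))
    arm5 <- sample(c("C", "G"), stem_len, replace = TRUE)
    arm3 <- strsplit(chartr("CG", "GC", paste(rev(arm5), collapse = "")),
                     "")[[1]]
    b <- c(flank(h0 - 1), arm5, strsplit(triplet, "")[[1]], arm3,
           flank(length - h1))
    s <- paste(b, collapse = "")
    if (as_dna) s <- chartr("U", "T", s)
    list(seq = s,
         truth = list(triplet_pos = insert_pos, hairpin_start = h0,
                      hairpin_end = h1, stem_len = stem_len))
  })
}
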