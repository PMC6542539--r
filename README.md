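# aarsrip

Aminoacyl-tRNA synthetases (aaRSs) charge tRNAs with their amino acids, but
several of them also bind mRNAs — including, strikingly, the mRNAs that
encode them. `aarsrip` implements the computational side of that kind of
study as a reusable, tested R pipeline for anyone analysing RIP-seq of a
tagged RNA-binding protein against an untagged bead-background control:

* **RIP-seq enrichment.** For gene *g*, RIP efficiency is
  *e(g) = RPM_Bound(g) / RPM_Input(g)* after reads-per-million
  normalization; the background-corrected efficiency is
  *c(g) = e_tagged(g) − e_untagged(g)*, subtracting nonspecific bead
  capture measured in an untagged strain under the same purification
  protocol (TAP or GFP-Trap). Transcripts with Input RPM < 15 and
  noncoding RNAs are filtered first; genes are ranked by *c* with a fully
  specified tie-break.
* **Target calling.** A gene is a bound target when
  *c(g) > Q3 + 1.5·IQR* of the per-experiment distribution (the boxplot
  whisker convention; a mean-centred variant is available). Exclusive and
  shared targets across several proteins are reported as Venn regions.
* **Binding-site localization (fRIP).** For fragmentation-RIP tiling
  panels (14 amplicons of ~150 bp across an ORF), per-fragment
  Bound/Input ratios are computed at a common unsaturated PCR cycle,
  low-amplification fragments are flagged, and the peak fragment is
  called together with the partial-cleavage smear expected immediately
  upstream of the true site.
* **Anticodon-mimic scanning.** Sliding 15-nt windows are folded by
  Nussinov base-pair maximization (Watson–Crick + GU wobble, minimum
  loop 3); a hit is an anticodon triplet (e.g. GUG, read by HisRS)
  presented entirely within a hairpin loop. Point mutations are checked
  for synonymy under the standard genetic code and classified as
  `anticodon_lost`, `stem_disrupted` or `stem_preserved` by refolding.
* **Synthetic data.** Seeded negative binomial count simulators, tiling
  panels and mimic-bearing sequences with recorded ground truth let every
  stage — and every test — run without external downloads.

## Worked example

Simulate a 2,000-gene experiment in which gene 7's transcript is captured
20-fold over bead background, then run the enrichment and target-calling
stages:

```r
library(aarsrip)
sim <- simulate_ripseq(rip_sim_params(n_genes = 2000, seed = 42,
        planted = data.frame(gene = 7, fold = 20)))
enr <- rip_enrichment(sim$counts, strain = "tagged", protocol = "TAP")
enr
#> RIP enrichment: tagged ( TAP ) vs untagged, 1956 retained genes
#> top of ranking:
#>     gene_id rpm_input rpm_bound efficiency efficiency_untagged corrected rank
#> 1 gene00007   2128.41   26002.9     12.217              0.7716    11.445    1
#> 2 gene01021    483.41    2506.7      5.185              1.0015     4.184    2
#> 3 gene01575     61.91     233.5      3.772              0.3698     3.402    3
call_targets(enr)
#> target set 'tagged': 35 genes above 1.809 (quartile + 1.5 IQR, of 1956 genes)
```

The planted transcript ranks first with corrected efficiency 11.4 —
i.e. its Bound:Input ratio exceeds the bead background by ~11 — and enters
the called target set, whose threshold 1.81 is the upper boxplot whisker
of the 1,956 retained genes.

Localize a binding site on a 14-fragment tiling panel (true site in
fragment 10, amplicon 11 nearly dead):

```r
eff <- rep(1, 14); eff[11] <- 0.01
sig <- simulate_frip(frip_sim_params(site_fragment = 10, carryover = 0.4,
        pcr_efficiency = eff, noise_sd = 0, seed = 1))
peak_fragment(fragment_enrichment(sig))
#> binding-site peak at fragment 10; upstream partial-cleavage smear: 8, 9;
#> low-confidence fragment(s): 11
```

Fold a candidate element and classify mutations:

```r
fold_window("GGCACGUGGUGCC")
#> GGCACGUGGUGCC
#> (((((...)))))  (5 pairs)
classify_variant("GGCACGUGGUGCC", c("C3A", "G11A"))
#> variant class: stem_disrupted
#>   triplet intact: TRUE | closing-stem pairs retained: 0.2
```

The 13-mer folds into a 5-bp stem presenting GUG in its loop; breaking
two stem bases leaves only 20% of the closing stem intact, so the element
is called disrupted, while the loop mutation `U7A` (GUG→GAG) would be
`anticodon_lost` and the compensatory swap `C3G`+`G11C` is
`stem_preserved`.

A command-line wrapper (`exec/aarsrip`) exposes the same stages as
subcommands (`simulate`, `enrich`, `targets`, `frip`, `scan-mimic`,
`classify-variant`, `run`), with `run` driven by a YAML config and
emitting a hashed run manifest.

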