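# gstpatterns

Phylogenetic analysis of *GSTM1*/*GSTT1* null allele frequencies across
geographically assorted human populations.

The glutathione-S-transferase genes *GSTM1* and *GSTT1* commonly carry
whole-gene deletions ("null" alleles) detected as absence of a PCR band.
Their frequencies differ markedly between human populations, which makes
them informative both for pharmacogenetics and for coarse population
comparison.  `gstpatterns` packages a complete, tested workflow for this
kind of presence/absence survey data, together with a compiled table of 45
populations (plus seven printed continental aggregates) and their
geographic coordinates:

* **frequency estimation** — null-genotype counting from per-individual
  calls, with binomial standard errors and sample-size-weighted regional
  aggregation;
* **Nei (1972) standard genetic distance** over biallelic null/present
  loci: `D = -ln I` with
  `I = Σ_l j_xy / sqrt(Σ_l j_x · Σ_l j_y)`, where for allele vectors
  `x = (q_x, 1-q_x)`, `y = (q_y, 1-q_y)` the per-locus identities are
  `j_x = Σ x²`, `j_y = Σ y²`, `j_xy = Σ x·y` (ratio of summed identities,
  the `gendist` form);
* **UPGMA** clustering (size-weighted average linkage, deterministic
  tie-breaking) with Newick and PHYLIP matrix I/O;
* **locus-resampling bootstrap** with strict majority-rule consensus and
  per-clade support;
* **pattern assignment** — each population joins the least-distance anchor
  among the seven recurring frequency patterns (Xhosa, Zimbabwe, Ethiopia,
  Egypt, Afghanistan, Caucasian, Andhra Pradesh), mapped onto three
  geographic splits (Africa / out of Africa / other than Africa), plus the
  longitude/latitude scatter export behind the split map;
* **synthetic genotype generation** with known ground truth, so the whole
  pipeline is testable end to end without any external data.

## Worked example

```r
library(gstpatterns)

# the 20-continental-region analysis set (13 populations + 7 printed
# aggregates) and its pairwise Nei distance matrix
tab <- load_gahp_fixture("regions20")
d   <- nei_distance_matrix(tab)
round(d["sAs_Ind", "eAf_Zim"], 6)
#> [1] 0.007203
```

0.007203 is the smallest distance from the Indian aggregate to any other
region — India attaches to the Zimbabwe frequency pattern.  The full
pipeline, including a 1000-replicate bootstrap and pattern assignment:

```r
out <- run_analysis("regions20", outdir = tempfile(),
                    replicates = 1000, seed = 1)
#> anchor(s) not in this analysis set, dropped: Ind_Ap
head(out$patterns[, c("id", "anchor_id", "pattern", "split")], 6)
#>         id anchor_id pattern             split
#> 1      eAs   eAf_Eth     III     out_of_Africa
#> 2     seAs   nAf_Egt      IV     out_of_Africa
#> 3  sAs_Ind   eAf_Zim      II     out_of_Africa
#> 4  sAs_Afg   sAs_Afg       V other_than_Africa
#> 5 sAs_Iran   eAf_Eth     III     out_of_Africa
#> 6  sAs_Pak   sAs_Afg       V other_than_Africa
```

Each population is labelled with its nearest anchor's pattern (anchors
label themselves — Afghanistan is pattern V at distance 0) and the split
that pattern belongs to.  With only two loci the bootstrap is deliberately
coarse (three possible resamples, weights 0.5/0.25/0.25), so consensus
supports sit near 75%:

```r
ape::write.tree(out$consensus)
#> ((eAs,(seAs,nAf_Egt)75,(sAs_Afg,sAs_Pak)75,sAs_Iran,nEu,(wEu,sEu,eEu)75,
#>   eAf_Eth,eAf_Som,wAs_Cau,sAm_Brz)75,
#>  (sAs_Ind,wAf_Nig,sAf_Xho,sAf_Nam,mAf_Cam,eAf_Zim)75)100;
```

Counting a frequency from raw presence/absence calls:

```r
calls <- data.frame(population = "guj", individual = 1:504,
                    GSTT1 = rep(c(1L, 0L), c(179, 325)))
count_null_frequency(calls, "GSTT1")
#> q_hat = 0.3552  (n = 504, SE = 0.0213)
```

A command-line wrapper for the same pipeline ships in
`inst/scripts/run_analysis.R`.

## Data notes

The packaged survey stores every printed frequency/sample-size cell
verbatim.  Two published quirks are preserved deliberately: the
continental aggregates are kept as printed (they are not exactly the
weighted means of their member rows), and the distance cells involving the
Caucasian aggregate are *not* reproducible from its printed frequencies —
the package computes what the frequencies imply and flags assignments won
by that anchor.  See the vignette (`vignettes/gst-null-phylogeny.Rmd`) for
the full account of the model, parameters, and limitations.

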