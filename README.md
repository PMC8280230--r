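# kelpbeta

Hierarchical beta-diversity analysis for paired eDNA-metabarcoding and
underwater-visual-census (UVC) fish surveys.

Coastal fish communities are sampled at nested spatial grains — replicate
water bottles within a transect, transects within a rocky-reef site, sites
along a coastline — and the two standard survey instruments (sequencing the
DNA that fish shed into the water, and divers counting fish on transects)
resolve that structure very differently. `kelpbeta` provides the analysis
chain needed to quantify and compare the spatial structure each instrument
sees:

* **Taxonomy curation** of OTU tables from BLAST tabular hits: top-percent
  hit filtering (identity ≥ 85 %, bitscore ≥ 100, top 2 % of the best
  bitscore), majority (85 %) lowest-common-ancestor assignment,
  rank-threshold gates (species 97 %/300, genus 95 %/200) with elevation,
  no-template-control and blacklist contaminant removal, and hierarchical
  genus/family merging of rank-unassigned OTUs, with a read-conserving
  curation log.
* **Additive partitioning** of regional richness,
  `gamma = alpha + beta_bottle + beta_transect + beta_site`, with an
  individual-based two-margin randomization null (999 iterations) and
  one-sided add-one p-values per component.
* **Taxa–area relationships**: spatially contiguous accumulation curves
  over all starting samples, competing linear / exponential / power /
  one-breakpoint piecewise fits (Muggeo-style iterative linearization with
  a delta-method CI on the breakpoint), historical-pool bootstrap
  extension, and effort-to-target inversion.
* **Compositional beta diversity**: Bray–Curtis on square-root reads or raw
  biomass, distance decay of similarity with one-tailed Mantel tests,
  simulation-based Mantel **power curves conditioned on the sampling
  geometry**, nested (site / transect / bottle) variance components from
  distance-based sums of squares, and NMDS.
* **Indicator taxa** (Dufrêne–Legendre IndVal with permutation tests and
  Holm adjustment), cross-method taxon harmonization at the finest shared
  rank, and the joint reads–biomass regression.
* A **synthetic landscape generator** reproducing the nested study design
  (11 sites on an ~80 km coastline, 27 transects, 49 bottles with one
  triplicate transect per site), with lognormal abundances, spatially
  correlated site-level species sorting, multinomial read sampling, and a
  detectability-biased visual census — so everything above is testable with
  known ground truth.

## Worked example

Simulate a strongly site-sorted landscape, observe it through the eDNA
process, and partition regional richness:

```r
library(kelpbeta)
sim <- simulate_study(simulation_config(sorting_strength = 0.8), seed = 2026)
partition_significance(sim$edna, sim$design_edna,
                       levels = c("transect_id", "site_id"),
                       n_iter = 999, seed = 1)
#> additive partition: gamma = 76
#>          component observed null_mean null_sd p_low p_high flag
#> 1            alpha   34.388    54.497  0.1700 0.001  1.000    -
#> 2      beta_sample    2.872     2.861  0.1881 0.520  0.482   NS
#> 3 beta_transect_id   10.013     5.779  0.3096 1.000  0.001    +
#> 4     beta_site_id   28.727    12.864  0.3251 1.000  0.001    +
#> ( 999 randomizations, individual scheme )
```

Of the 76 taxa detected regionally, a mean of 34.4 appears in a single
bottle; replicate bottles add almost nothing beyond chance (NS), while the
among-transect and especially the among-site components are far larger than
their null expectations (`+`) — the signature of species sorting across
reefs. The compositional view agrees:

```r
geo <- geo_distances(sim$design_edna)
D <- bray_curtis(sim$edna)           # square-root reads
hierarchical_varpart(D, sim$design_edna)
#>     component    variance   percent
#> 1     site_id 0.186579950 81.407342
#> 2 transect_id 0.007655452  3.340177
#> 3    residual 0.034957624 15.252482

distance_decay(D, geo, n_perm = 999, seed = 1)
#> distance decay: similarity = 0.5128 + -0.004961 * km
#> Mantel r = 0.6117 , p = 0.001 ( 999 permutations )
```

81 % of compositional variance lies among sites; similarity between
replicate bottles (the intercept) is 0.51 and falls by 0.005 per km. The
taxa–area curve saturates quickly:

```r
curve <- build_tar(sim$edna, geo)
fit_tar_models(curve)[[1]]
#> power fit: a=35.38, b=0.1965
#>   RSS: 31.11  AIC: -16.258
samples_to_reach(curve, 50)
#> [1] 5.900901
```

About 6 spatially contiguous bottles suffice to detect 50 taxa on this
landscape. `mantel_power()` compares survey designs: under the default
geometries, the 49-bottle eDNA design detects a spatial correlation of 0.2
with power ≈ 0.88, the 27-transect UVC design with ≈ 0.7.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/kelpbeta.R simulate --seed 1 --out out/
Rscript inst/cli/kelpbeta.R partition --counts out/edna_reads.csv \
    --meta out/edna_metadata.csv --iters 999 --seed 1 --out out/
```

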