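---
title: "Methods: haplotype sharing analysis for co-distributed species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype sharing analysis for co-distributed species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Closely related plant species often share chloroplast (cpDNA) haplotypes.
Two processes produce this pattern and predict different geographies.
Retained **ancestral polymorphism** predicts that shared haplotypes are
scattered at random across each species' range, because the sharing predates
the species boundaries. **Introgression** (chloroplast capture through
hybridisation and backcrossing) predicts *local* sharing: a haplotype passed
between species where they meet stays near the contact zone, because cpDNA
is maternally inherited and moves only by seed.

`haploshare` implements the complete analysis chain used to separate the two
signals in co-distributed oaks and similar systems: character coding of
non-coding plastid alignments, haplotype collapsing, a median-joining
network, diversity and differentiation statistics with permutation nulls,
hierarchical AMOVA, individual-level spatial autocorrelograms, and the
distance-stratified comparison of interspecific gene identities that is the
core test. A synthetic-data generator reproduces the statistical structure
the analysis assumes, so every stage is testable without external data.

## Character coding

Non-coding plastid loci carry substitutions, indels, inversions and
homopolymer (mononucleotide-repeat) length variation. The coding rules are:

* **Substitutions** — one character per alignment column with two or more
  distinct bases. Columns whose only polymorphism is base-versus-gap belong
  to indels. `N` and gap states are recorded as missing.
* **Indels (simple gap coding)** — each maximal gap run with identical start
  and end coordinates across its bearers is one binary character, so an
  indel counts as a single mutation event regardless of length. A sequence
  whose own gap overlaps a character's coordinates without matching them
  exactly is scored missing for that character (strict simple coding:
  nested gaps are missing, overlapping-but-not-nested gaps are distinct
  characters with mutual missing states). Runs touching the alignment ends
  are treated as missing data, not indels.
* **Inversions** — the region is supplied in the configuration (it is
  identified by inspection, not auto-detected). Rows closer to the reverse
  complement of the majority orientation are rewritten to the majority
  orientation, and one binary character records orientation — again a
  single mutation event.
* **Homopolymer masking** — alignment columns spanned by a run of at least
  `min_run` identical bases (default 5, the shortest run usually treated as
  a homopolymer microsatellite; configurable) are masked for *indel*
  coding, because repeat length variation is highly homoplasic. A
  substitution to a different base inside a run remains callable.

**Missing data.** A missing state matches nothing, so individuals with any
missing state at a retained character are excluded from the haplotype
catalog with a warning. This keeps haplotype identity exact at the cost of
sample size; catalogs report the excluded IDs.

**Labels.** Haplotypes are labelled `H1, H2, ...` by descending total
count, ties broken by first occurrence in input order (deterministic).
Published haplotype numbers are rarely frequency-ranked, so
`collapse_haplotypes()` accepts a label map for reproduction runs.

## Median-joining network

Distances between haplotypes are Hamming counts over coded characters; an
indel or inversion character contributes one step like a substitution, and
all characters have equal weight. The minimum spanning network (MSN) is the
union of all minimum spanning trees — an edge is kept whenever its
endpoints are not connected by strictly cheaper edges, so all ties are
retained — relaxed by an integer `epsilon` (default 0, the usual program
default).

Median joining iterates: build the MSN over the current node set; for each
connected triplet propose the per-character majority median (three distinct
states keep the central node's state — a deterministic tie rule); add the
new medians whose connection cost is within `epsilon` of the round minimum;
remove inferred nodes of degree two or less; stop at a fixpoint (bounded by
`max_iter = 50`; typical data converge in fewer than five rounds). Once a
proposed median has been pruned it is not re-added, which guarantees
termination. The returned network always *displays* the observed-haplotype
MSN: any observed link that the medians do not resolve into an equal-length
path is retained as a direct edge. Node frequency is display metadata only
and never affects topology.

Lineages are delimited by user-named diagnostic characters (for example a
single transition and a diagnostic indel): `cut_lineages()` removes every
edge whose endpoints differ at a diagnostic character and labels the
connected components.

## Diversity and differentiation

Per population: the haplotype count *h*; Nei's unbiased gene diversity
*Hd = n(1 − Σp²)/(n − 1)*; and nucleotide diversity per site
*π = n/(n−1) · Σᵢ<ⱼ 2pᵢpⱼdᵢⱼ / L*, where *d* counts substitution
differences only (indels and inversions are excluded from *π*, matching the
gap-free site-counting convention) and *L* is the total aligned length
(1340 bp at the default generator settings).

Across populations, the unbiased multi-population estimators weight
populations equally (the conventional unweighted variant): per-population
*ĥₖ = nₖ(1 − Σx²)/(nₖ − 1)*, *h_S* their mean, and
*h_T = 1 − Σx̄² + h_S/(Kñ)* with *ñ* the harmonic mean sample size. With an
inter-haplotype distance matrix the analogous *v*-statistics give *v_S*,
*v_T*. Then *G_ST = (h_T − h_S)/h_T* and *N_ST = (v_T − v_S)/v_T*.
*N_ST > G_ST* means related haplotypes co-occur within populations —
phylogeographic structure. Its significance comes from permuting the
haplotype identities of the distance matrix (10,000 permutations by
default; one-tailed, +1-corrected p). Small negative excursions of
*h_T − h_S* are legitimate estimator behaviour and are never clipped.
Standard errors are delete-one jackknife over populations; the original
small-sample variance expressions are not reproduced here, and jackknife
SEs may differ somewhat from program-specific ones. Populations with one
individual are excluded from these estimators (the unbiased ĥ is undefined)
but stay in all haplotype tallies.

## AMOVA

The hierarchical analysis of molecular variance uses squared
inter-individual distances, with the inter-haplotype distance equal to the
coded mutation count (the pairwise-difference convention for haplotypic
data; squared Euclidean distances enter the sum-of-squares formula). Sums
of squares per stratum are within-group pair sums divided by group size;
variance components come from the expected mean squares with the standard
unequal-sample-size coefficients. Negative components are reported as
computed, with a warning, and percentages of variation use the signed total
— zeroing them would silently bias the percentages. Fixation indices:
*F_CT* (among species), *F_SC* (among populations within species), *F_ST*
(overall), with the identity *F_ST = F_CT + (1 − F_CT)·F_SC* holding to
numerical precision.

Permutation schemes follow the stratum being tested: individuals among all
populations for *F_ST*, whole populations among species for *F_CT*, and
individuals among populations within species for *F_SC* (10,000
permutations by default, +1 correction). A three-level design requires at
least two populations in every species; the degenerate one-population
species case is rejected rather than silently collapsed.

## Spatial autocorrelation

The individual-level multivariate autocorrelogram double-centres the
squared genetic distance matrix into a covariance-like matrix
*c = −½(d² − row means − column means + grand mean)* and computes, for each
distance class *h*,
*r(h) = Σᵢ≠ⱼ∈h cᵢⱼ / Σᵢ≠ⱼ∈h cᵢᵢ*. Genetic distance between individuals is
the squared haplotype Hamming distance (the haploid convention; a 0/1
mismatch option is provided). Distance classes are discrete half-open 50-km
bins (`[0,50), [50,100), ...`, 20 classes by default), not cumulative; pairs
beyond the last bin are excluded with their count reported.

Inference: permutation shuffles the individual-to-location mapping
wholesale, once per replicate, shared across classes; bootstrap resamples
pairs within a class. Positive structure is declared when the observed *r*
exceeds the upper 95% permutation bound or when the bootstrap CI excludes
zero. Like Moran's I, the statistic has an O(1/n) negative null bias; the
calibration tests account for it.

## The sharing test

For every heterospecific population pair the gene identity is the
normalised (Nei) identity *J = Σxᵢyᵢ / √(Σxᵢ²·Σyᵢ²)*, bounded in [0, 1];
the unnormalised *Σxᵢyᵢ* of parts of the older literature is available as
`method = "raw"` because the two cannot be distinguished from published
descriptions alone. Pairs are grouped by a 300-km threshold (strict `<`,
chosen where autocorrelation flattens): nearby-and-sharing (*J₁*), nearby
(*J₂* ⊇ *J₁*), distant (*J₃*). Group means *M₁, M₂, M₃* are unweighted over
pairs, and the distributions are compared with two-sided Wilcoxon rank-sum
tests (*P₁₂, P₁₃, P₂₃*); two-sided because published values near 1 are
inconsistent with a one-sided formulation. The Wilcoxon implementation uses
the exact distribution when both groups have ≤20 untied observations and
the normal approximation with tie correction otherwise.

The analysis is run with and without the most widespread haplotype: a
high-frequency ancestral haplotype present almost everywhere swamps *J*
with a constant contribution, hiding the local signal. Exclusion removes
all carriers (not just the frequency coordinate) and drops populations left
empty — this is what makes the pair counts shrink between the two panels of
the output table — and sharing status is re-evaluated after exclusion.
`enumerate_sharing_pairs()` lists the nearby heterospecific pairs that
share any haplotype other than the excluded one, with the shared labels and
distances.

Interpretation: *M₂ ≈ M₃* (flat *P₂₃*) is the ancestral-polymorphism
signature; *M₂ > M₃* with small *P₂₃*, typically emerging only after the
top-haplotype exclusion, is the introgression signature. Note the *J*
values of overlapping pairs share populations, so the rank-sum test is
approximate under dependence; the generator-based calibration shows its
null behaviour is conservative at the default design.

## The synthetic generator

`simulate_dataset()` emulates the study conditions the analysis assumes:

* three species with 33, 19 and 41 populations (5–19 individuals each),
  placed around six refugium clusters (centres ≥500 km apart, populations
  scattered with SD 1.0°) in a bounding box shaped like subtropical-to-
  temperate East Asia (23–41°N, 100–122°E);
* a pool of 27 haplotypes in three lineages: three ancestral cores with
  global sampling mass 0.39/0.16/0.11, eight ancestral satellites with
  total mass 0.176 shared randomly across species, and sixteen rare tips
  (about 1% each) private to one species within one cluster — matching the
  published composition in which the three commonest haplotypes carry 65.5%
  of individuals, eleven shared haplotypes carry 83.3%, and sixteen private
  haplotypes average 1.0%;
* lineage diagnostics planted as one A/G transition (726-bp locus) and one
  8-bp indel (614-bp locus); one tip carries a 32-bp inversion and two tips
  carry 5–6-bp private indels, so the full coding stack is exercised on
  actual nucleotide sequences rather than abstract haplotype IDs;
* satellites and tips sit mostly one substitution from their core
  (steps 1–3 with probabilities 0.7/0.2/0.1), the near-star shape of
  observed plastid networks;
* within each population one locally drawn dominant haplotype has frequency
  0.9 and the remaining individuals draw again from the same local pool.
  Drawing minors from the same pool as the dominant keeps co-resident
  haplotype pairs exchangeable, which is what reproduces the published
  no-phylogeographic-structure regime (*N_ST ≈ G_ST*) while still giving
  the high differentiation of near-fixed populations (*G_ST ≈ 0.8*);
* introgression copies a tip haplotype between heterospecific populations
  closer than 300 km with probability `introgression_rate` per eligible
  pair, at a `Beta(1, 3)` sink frequency (at least one individual),
  recording every event in the ground truth. The default rate of 0.1 makes
  roughly a fifth of nearby heterospecific pairs share a non-top haplotype
  — the low prevalence seen in real range-wide surveys — while keeping
  per-species differentiation in the published 0.66–0.89 band; rate 0 (no
  tip ever occupies two species) is the null regime and rate 1 the
  maximal-signal regime used in the power study.

Core and satellite assignment is geography-independent by construction (a
drifted global frequency sampled binomially per population, not a
coalescent); the generator therefore does **not** emulate isolation by
distance within species, coalescent genealogies, sequencing error, or
heteroplasmy. Passing tests show the statistics behave correctly under the
assumed structure, not that real data meet those assumptions.

## Numerical and design choices

* Coordinates are decimal degrees (WGS84 assumed); great-circle distances
  use the haversine formula with Earth radius 6371.0088 km, with no
  projection.
* All tables are UTF-8 TSV; write-then-read round trips are exact.
  Networks are exported as GraphML plus a plain edge list with mutation
  counts.
* Every randomised procedure takes an explicit seed; fixed seed and fixed
  inputs give byte-identical outputs.
* Permutation p-values always use the (hits + 1)/(n + 1) correction and are
  never zero.
* Individuals present in metadata but absent from an alignment (or vice
  versa) are a hard error — the dataset contract assumes every sample was
  sequenced at every locus.
* The test suite runs its calibration studies at reduced problem sizes (6–8
  populations, 99 permutations, 500 simulations; 100 generator replicates
  for the planted-introgression power study) — sizes chosen so the whole
  suite runs in minutes while keeping binomial error small; the acceptance
  script runs the full default design with 10,000 permutations for GST/NST
  and AMOVA and 999 for the spatial correlogram.

## Known limitations

* The median-joining fixpoint here follows the simplified
  propose-majority-medians scheme described above; with `epsilon > 0` or
  highly reticulate data its topology beyond the displayed MSN backbone may
  differ from other implementations.
* Jackknife SEs for h/G/N-statistics are not the original closed-form
  variance estimators.
* The AMOVA is haplotypic and single-matrix: no locus-by-locus partitioning
  or covariance-based distance options.
* The sharing test treats population pairs as exchangeable sampling units;
  p-values are approximate under the induced dependence (shared
  populations across pairs).
* Reproducing the printed statistics of the motivating study requires its
  per-population haplotype table and coordinates, which are not
  redistributable here; the package ships the machinery
  (`catalog_from_counts()`, label maps) to do so when that table is
  available.
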