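---
title: "Methods behind fjordflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind fjordflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fjordflux)
```

This vignette explains the models and procedures the package implements,
the tunable parameters that matter, the numerical choices made where the
methods literature leaves freedom, and what the synthetic-data generator
does and does not establish.

## Water-mass classification

Arctic fjords on the Atlantic inflow path are conventionally described
with seven water masses defined by rectangular envelopes in the
temperature–salinity plane (after Cottier et al. 2005, J. Geophys. Res.
110, C12005): three externally sourced classes (Atlantic Water AW,
Transformed Atlantic Water TAW, Arctic Water ArW) and four formed locally
(Surface Water SW, Intermediate Water IW, Local Water LW, Winter-cooled
Water WCW). AW and TAW carry an extra density constraint,
σθ < 27.92 kg m⁻³.

The classifier applies a fixed decision ladder per record: (1) collect all
envelopes containing the record under their full constraints; (2) a single
match wins; (3) several matches are resolved by a configurable
`precedence` order; (4) if nothing matched but the record sits in the AW
or TAW T–S box with σθ at or above the threshold, it keeps the Atlantic
label (AW checked before TAW) — dense Atlantic-derived water is still
Atlantic-derived; (5) if nothing matched and the record is fresher than
the ArW salinity floor *and* colder than the LW temperature floor, it is
ArW — cold polar water outside every box; (6) otherwise `Unclassified`,
retained and counted, never silently dropped.

Choices worth knowing:

* **Envelope bounds are configuration, not code.** The shipped
  `envelopes.yaml` transcribes the standard Svalbard scheme; any study can
  substitute its own. Tests exercise the ladder on small toy envelopes
  whose geometry is fully controlled.
* **Half-open intervals.** Lower bounds closed, upper bounds open by
  default, so adjacent envelopes partition the plane; per-edge flags can
  override this.
* **Precedence default** is WCW, ArW, LW, SW, IW, TAW, AW — coldest and
  most specific first — because the ArW/LW/WCW envelopes genuinely
  overlap and a deterministic, auditable order is required. Ambiguous
  records are reported via an attribute.
* **Density.** σθ comes from the UNESCO EOS-80 one-atmosphere polynomial
  (inputs treated as practical salinity and temperature at p = 0),
  reproducing the published check values ρ(0,5,0) = 999.96675,
  ρ(35,5,0) = 1027.67547 and ρ(35,25,0) = 1023.34306 kg m⁻³ to 1e-5.
  Modern data often arrive in TEOS-10 conventions (conservative
  temperature, absolute salinity); at upper-ocean ranges the difference is
  far below the envelope resolution, and a precomputed `sigma_theta`
  column bypasses the internal computation entirely.

## Nutrient statistics

Bottle profiles are vertically autocorrelated, so inference never runs on
raw bottles. Samples are first collapsed to one median per (region, year,
water mass, station); those cells are the independent observations.

* **Mann–Whitney U** is implemented from rank sums with midranks. With no
  ties and a combined n ≤ 12 the two-sided p is exact, from the null
  distribution of U built by the standard rank recurrence; otherwise the
  normal approximation with tie correction and a continuity correction is
  used. Degenerate data (all values identical) return p = 1, flagged. The
  exact path is verified in the tests against full enumeration of all
  rank splits.
* **Benjamini–Hochberg** is the step-up rule applied across all tests
  actually performed; water masses present in only one region are skipped
  (there is nothing to compare), mirroring the dashes of a two-fjord
  summary table.
* **Bootstrap CIs** are percentile intervals for the arithmetic mean,
  B = 9999 by default, resampling station cells, with a fixed default
  seed (20160725) so tables are reproducible; the method choice is
  stated here because "bootstrap" alone underdetermines it.
* **Quantiles** use type-7 linear interpolation of order statistics (R's
  default), stated so that q25/q75 columns are reproducible elsewhere.
* **Detection limits** (0.5 nitrate+nitrite, 0.06 nitrite and phosphate,
  0.7 silicic acid, 0.09 ammonium, mmol m⁻³) only set flags; measured
  values are never substituted or censored. Callers can decide their own
  policy with the flags in hand.

## Model II regressions and the mixing estimator

Both mixing-diagram axes (salinity, concentration) carry error, so
ordinary least squares is inappropriate. The package fits the
standardized major axis — slope sign(r)·s_y/s_x through the centroid —
and Deming regression, whose λ = 1 case (equal error variances) is the
major axis: the first principal axis of the 2×2 covariance matrix, a fact
the tests exploit as an independent eigenvector oracle. Significance for
both is the two-sided t test of zero Pearson correlation on n − 2 df;
the Deming slope additionally gets a leave-one-out jackknife standard
error. One regression is fitted per (region, year, analyte, water mass)
stratum; strata too small (n < 3) or degenerate (zero variance) are kept
as NA rows so the count of attempted diagrams is auditable, and BH
correction runs across the fitted strata.

The source/sink estimator compares the observed mean fjord concentration
against conservative mixing of the mean shelf water with a freshwater
endmember:

$$\mathrm{Sources-Sinks} = C_{fjord} - \Big[C_0 + (S_{fjord}-S_0)
\frac{C_{shelf}-C_0}{S_{shelf}-S_0}\Big]$$

Means are arithmetic over all qualifying bottle samples (station roster,
water-mass label, depth ≤ 100 m) — deliberately different from the median
aggregation used for the descriptive tables, which targets inference, not
budgets. The default endmember is S₀ = 0, C₀ = 0. When the true
freshwater source carries nutrients, this choice overstates dilution and
shifts the estimate *positive* by exactly C₀(1 − S_fjord/S_shelf): true
sinks are understated, never manufactured. The estimator is linear in
C_fjord with unit coefficient. Concentrations are accepted in mmol m⁻³
and reported as µmol kg⁻¹ without a density conversion; for seawater the
two differ by ~2–3%, well below the between-water-mass signal, and the
approximation is flagged here rather than hidden.

## Community analysis

All community statistics are implemented in the package; vegan appears
only in the test suite as an independent oracle.

* **Bray–Curtis** is computed directly from its definition,
  Σ|x−y| / Σ(x+y); pairs of all-zero samples are an error rather than a
  silent 0/0.
* **nMDS** minimizes Kruskal stress-1 by alternating monotone regression
  (pool-adjacent-violators over pairs ordered by dissimilarity, ties
  treated as primary/"weak": tied pairs are pre-sorted by current
  configuration distance) with a Guttman majorization step. The search
  runs from a principal-coordinates start plus 20 random starts
  (configurable), accepts only stress-decreasing iterations — so the
  reported stress sequence is non-increasing by construction — and stops
  when the improvement drops below 1e-6 or at 300 iterations. The best
  configuration is centred and rotated to principal axes. With a fixed
  seed the result is bit-reproducible.
* **PERMANOVA** uses the distance-matrix identity
  SS_total = Σ_{i<j} d²_ij / N and group-size-scaled within sums; labels
  are permuted freely (no strata). When the number of distinct
  relabelings of the label multiset is at most `n_perm`, the null is
  enumerated exhaustively and p is the proportion of labelings with
  F ≥ F_obs (observed included); otherwise p = (1 + #{F_perm ≥ F_obs}) /
  (1 + n_perm).
* **Dispersion homogeneity** embeds the distances by principal
  coordinates, keeps the negative-eigenvalue axes, and combines them by
  difference of squared distances to the group centroid (truncated at
  zero) — the standard semi-metric contract. The group effect on centroid
  distances is a one-way F whose null comes from permuting the centroid
  distances across samples (vegan's permutest permutes model residuals
  instead; with one factor the two agree closely, and the simpler scheme
  is easier to audit).
* **Nitrifier guilds** are lineage-rule subsets (AOA: class
  Nitrososphaeria; AOB: family Nitrosomonadaceae or genus
  *Nitrosococcus*; NOB: phyla Nitrospinota/Nitrospirota or genera
  *Nitrotoga*/*Nitrobacter*), expressed against the **total** community —
  the nitrifier subset is never rescaled to 100%, so a guild value of
  0.02 means 2% of all reads. Overlapping rules (possible with
  user-supplied guilds) are counted once under AOA > AOB > NOB precedence
  and the number of overlaps reported.

## Gene coverage and ACN

Coverage is mapped reads over gene length in bp. A gene annotated on
several contigs in one sample is pooled as total reads over total length
(length-weighted); the per-contig mean is available behind a flag, since
either convention appears in practice. ACN divides a gene's coverage by
the mean coverage of the single-copy genes *recA*, *gyrB*, *rpoB* —
whichever of them are detected (≥ 1), with the count reported, which keeps
sparse assemblies usable at the cost of a noisier denominator. ACN is
exactly invariant under uniform scaling of all read counts, which is the
point: it removes sequencing depth. Gene symbols match the panel
case-insensitively; fuzzy annotation parsing is upstream's job.

## The synthetic generator: what a green test establishes

The generator builds the world the analyses assume, nothing more:

* **Profiles** are exact two-endmember blends (marine S = 35 with fixed
  nutrient concentrations; freshwater S = 0, C = 0), with a layer table
  per region designed so the default envelopes produce all seven classes,
  fjord stations slightly fresher than shelf stations in the upper
  layers, and a uniform sink δ subtracted from fjord nutrients at
  ≤ 100 m. Noise is Gaussian truncated at zero, default off. Because the
  construction is exactly conservative, the estimator must return 0
  (δ = 0) or −δ to machine precision — a sharp correctness check, not a
  statistical one.
* **Communities** are Dirichlet-multinomial: each water mass has a mean
  composition (default: a favoured block of ASVs at 8:1 weight;
  overridable per water mass), and a nitrifier overlay grows with depth
  as g_max·z/(z + 150 m), default g_max = 0.3 — deep samples approach a
  30% nitrifier fraction, echoing deep Thermoproteota-rich Arctic
  communities. Default concentration 200 and 5·10⁴ reads per sample are
  realistic for amplicon data.
* **Gene counts** are Poisson with mean copy_number × reference_coverage
  × length × scale, references at copy number 1, so true ACN equals the
  configured copy number.

What the generator does **not** emulate: advection and tidal mixing,
chlorophyll dynamics coupled to nutrients, amplicon chimera/error
profiles, compositional coupling between taxa and genes, or realistic
spatial autocorrelation beyond the layer structure. A green end-to-end
test therefore establishes that the estimators recover what their own
model class generates — it does not validate the oceanography of any
particular field data set.

## Degenerate inputs and tie-breaks, in one place

* Unclassifiable CTD records: labeled `Unclassified`, kept, counted.
* All-identical Mann–Whitney data: p = 1, flagged degenerate.
* Zero-variance regression axes: error naming the axis.
* Deming with zero covariance and equal variances: orientation undefined,
  error; unequal variances give the vertical/horizontal axis.
* Zero or missing ratio denominators: missing ratio plus flag.
* Samples with zero total counts: excluded from relative abundance,
  listed in an attribute.
* Samples without positive reference-gene coverage: ACN missing, sample
  flagged.
* Single-observation bootstrap: degenerate interval with a warning.

## Known limitations

* The mmol m⁻³ ≈ µmol kg⁻¹ identification ignores density (~2–3%).
* PERMANOVA is one-factor; sequential multi-factor models are out of
  scope.
* The nMDS tie treatment is primary only; secondary ("strict ties") is
  not implemented.
* EOS-80 rather than TEOS-10; supply `sigma_theta` precomputed if the
  distinction matters for a borderline record.
* Detection-limit flags are informational; no censoring estimators are
  provided.
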