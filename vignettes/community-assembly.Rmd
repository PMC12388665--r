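---
title: "Quantifying stochastic community assembly with the Sloan neutral model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stochastic community assembly with the Sloan neutral model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

Microbial communities in sediments, soils and water assemble under two kinds
of forces. *Stochastic* processes — ecological drift in small populations and
dispersal from a regional pool — shuffle taxa without regard to their traits.
*Deterministic* processes — environmental filtering along gradients such as
pH, water content or nutrient concentrations, plus biotic interactions —
select for particular taxa. `ncmtools` quantifies the balance between the two
from nothing more than an OTU/ASV count table, the situation of a typical
16S amplicon survey (for example, sediment cores from several wetlands, two
depth layers, a few replicates each).

## The neutral occupancy–abundance model

The core statistic is Sloan's neutral community model for prokaryotes. Each
local community of size $N$ evolves by death–birth updates: when an
individual dies it is replaced, with probability $m$, by an immigrant drawn
from the metacommunity (where taxon $i$ has relative abundance $p_i$), and
otherwise by the offspring of a local individual. In the diffusion limit the
stationary distribution of taxon $i$'s local relative abundance $x_i$ is

$$x_i \sim \mathrm{Beta}\big(N m\, p_i,\; N m\,(1 - p_i)\big),$$

so the probability of *detecting* the taxon — seeing it at or above a
detection limit of $d$ reads, i.e. above the fraction $x = d/N$ — is

$$f_i \;=\; 1 - I_{d/N}\big(N m\, p_i,\; N m\,(1-p_i)\big),$$

with $I$ the regularised incomplete beta function. A single parameter, the
migration–dispersal magnitude $Nm$, thus predicts every taxon's occurrence
frequency from its mean relative abundance. `fit_ncm()`:

1. computes per-taxon $(p_i, f_i)$ with `occurrence_stats()` — $p_i$ the mean
   of within-sample relative abundances, $f_i$ the fraction of samples with
   at least $d$ reads (default $d = 1$);
2. sets $N$ to the mean reads per sample (the standard convention when the
   true community size is unobserved; it makes $Nm$ comparable across
   tables);
3. estimates $m$ by least squares on the frequencies, minimising
   $\sum_i (f_i - \hat f_i(m))^2$ over $m \in (10^{-6}, 1]$ with Brent's
   method on $\log m$. One bounded parameter needs no Jacobian and no
   Levenberg–Marquardt machinery, and the log scale keeps the bracket
   well-conditioned across four orders of magnitude;
4. reports $R^2 = 1 - \mathrm{SSR}/\mathrm{SST}$, the coefficient of
   determination of observed against predicted frequencies. High $R^2$ means
   the occupancy–abundance cloud is explained by drift plus migration alone
   (stochastic assembly); low $R^2$ flags deterministic structure;
5. wraps a 95% Wilson score band (`wilson_interval()`, the `binconf`
   convention, with $n$ = number of samples) around the prediction and
   partitions taxa into `above` (more widespread than neutrality predicts),
   `neutral`, and `below` — the candidates for deterministic selection.

Degenerate inputs are refused loudly: fewer than two samples, all-equal
frequencies (undefined $R^2$), abundances outside $(0,1)$. Fits on fewer
than 10 taxa warn. The objective is empirically unimodal in $m$; the test
suite checks the fitted optimum against a dense grid on every exercised
table.

## What the synthetic generator emulates — and what it does not

No public accession accompanies the kind of survey this package targets, so
the package carries its own data model, used both as the test bed and the
power-analysis tool. Its defaults mirror a two-layer, seven-site sediment
survey with three replicates (21 samples per layer, $\sim 10^4$ reads each,
300 taxa):

* `make_metacommunity(S, meta_sigma)` — lognormal regional pool, normalised.
  A single evenness knob (`meta_sigma = 2` by default, the long-tailed
  rank–abundance shape typical of 16S surveys) is all the NCM fit is
  sensitive to; a log-series pool would add a parameter without changing the
  occupancy–abundance geometry.
* `simulate_neutral_samples()` — the *stationary sampler*: compositions drawn
  from $\mathrm{Dirichlet}(Nm\,\mathbf p)$ (the multivariate form of the
  stationary Beta law), then reads as multinomial at the requested depth.
  Sequencing depth is deliberately decoupled from the biological community
  size $N$ — the two play different roles in the model.
* `simulate_neutral_dynamic()` — the explicit Hubbell death–birth–immigration
  chain, kept as an independent oracle for the stationary sampler. It is
  $O(\text{generations} \times N)$ and not meant for routine use. A
  50-generation burn-in is enforced (outputs are flagged when shorter). Its
  exact stationary law is beta-binomial with shape $m p (N-1)/(1-m)$, which
  converges to the Sloan Beta law only in the diffusion regime ($m$ small,
  $N$ large); cross-oracle comparisons therefore run at $m = 0.1$ and
  $N = 10^4$ with read depth below $N$, so that the latent $1/N$ granularity
  sits below the detection scale. Snapshots are taken from one chain at
  25-generation spacing, beyond the chain's $N/m$-step relaxation time.
* `simulate_filtered_samples()` — the deterministic alternative: a Gaussian
  niche model where taxon $i$ has an optimum $o_i$ on an environmental
  gradient $g_j$ and sampling weight $p_i\exp(-\lambda (o_i - g_j)^2)$.
  $\lambda = 0$ reduces exactly to multinomial sampling of the pool;
  $\lambda = 5$ over a gradient spanning 4 units gives niches much narrower
  than the gradient, a strong-filtering scenario.
* `simulate_metadata()` — eleven physicochemical covariates (pH, WC, TC,
  TSC, MBC, TN, AN, TP, AP, TK, AK) as monotone transforms of an
  equicorrelated Gaussian latent field (default latent correlation 0.5),
  keeping pH in (0,14), water content in [0,100]% and concentrations
  positive, with total potassium centred above 10 g/kg as in survey
  sediments.

What the generator does *not* emulate: phylogenetic correlation among taxa,
temporal dynamics, multiple source pools, chimeras/contamination, and
compositional artefacts of primer bias. Passing tests therefore certify the
statistical machinery under the model's own assumptions — they do not certify
that any real community is neutral.

### A caveat the tests surface deliberately

Read detection is *soft*: the probability that a taxon present at fraction
$q$ yields at least one read among $D$ is $1-(1-q)^D$, not a hard threshold
at $q = 1/D$. Fitting the hard-threshold Sloan curve to read tables
therefore *overestimates* the generator's latent $Nm$ by a factor that grows
with $Nm/D$ — about 1.2 at $Nm = 500$ and 1.35 at $Nm = 5000$ for
$D = 10^4$, a bias we verified against the closed-form beta-binomial
occupancy curve. $R^2$ is essentially unaffected (it stays above 0.9 on
neutral data), so the stochastic-vs-deterministic *verdict* is robust, but
absolute $Nm$ values from read tables should be read as upper-bound-flavoured
estimates, and compared only between tables fit at similar depth. The
acceptance suite reports the measured recovery error rather than hiding it.

## The surrounding workflow

* **Rarefaction** (`rarefy()`): subsampling without replacement to a common
  depth, default the minimum column sum; shallower samples are dropped, not
  padded, so columns stay comparable.
* **Diversity**: `richness()`, `shannon()` (natural log; the bound
  $H \le \ln S$ is asserted), `bray_curtis()` via vegan, `pcoa()` via
  classical scaling, and `nmds()` — global NMDS on dissimilarity ranks
  through vegan's monoMDS engine (Kruskal stress-1, ties averaged, random
  restarts seeded deterministically from the master seed). Stress below 0.2
  is the conventional adequacy line; rank invariance is part of the test
  suite.
* **Environment associations**: `mantel()` and `partial_mantel()` with the
  one-tailed permutation convention of vegan/linkET,
  $p = (1 + \#\{r_\pi \ge r\})/(1 + n_\pi)$, joint row/column permutation,
  and exhaustive enumeration available below $n = 8$ for exact checks.
  Environmental distances are Euclidean on z-scores; "diversity" responses
  are absolute differences of per-sample Shannon/richness. No multiplicity
  correction is applied across a Mantel panel (significance bands are
  reported instead).
* **Group comparisons**: `anova_lsd_cld()` — one-way ANOVA, unprotected
  Fisher LSD with the pooled error mean square, and a compact letter display
  built by insert-and-absorb so that letter sharing encodes non-significance
  exactly (verified by reconstruction in the tests). Being unprotected, the
  family-wise error across many groups is well above the per-pair
  $\alpha$ — the null simulation in the test suite records rates in the
  0.1–0.5 range for seven groups — which is the classical behaviour of the
  procedure, not a defect.
* **Core taxa and networks**: `core_taxa()` (presence = group-level relative
  abundance above a threshold, default any reads; Venn region counts
  partition the union), `bipartite_network()` (the edge criterion and its
  direction are exposed because distance-style thresholds differ between
  studies), `cooccurrence_network()` (Spearman on relative abundances by
  default, so per-sample depth rescaling cannot change the graph; t-approximation
  p-values, optional BH adjustment).

## The pipeline

`run_full_analysis()` chains the stages for a full two-layer design —
simulate (or ingest) → rarefy → alpha diversity with LSD letters by site →
Bray–Curtis + NMDS → NCM fit → Mantel panel → core phyla — and emits a
report serialised to canonical JSON at fixed precision, so one seed gives a
byte-identical file. The default scenario makes archaea neutral (surface
layer $m = 0.2$, deep layer $m = 0.1$) and bacteria niche-filtered on the
water-content gradient (stronger at depth), so `compare_layers()` reproduces
the qualitative contrast such surveys report: archaeal $R^2$ high and
declining with depth, bacterial $R^2$ low. Stage seeds fan out from the
master seed by fixed offsets so any stage can be rerun in isolation.

## Problem sizes and numerical choices

The shipped checks run at the design scale of the emulated survey: $S = 300$
taxa, 21 samples per layer, depth $10^4$, 20 replicate seeds for recovery
and contrast experiments, 1000 null replicates (199 permutations each) for
Mantel calibration, and 2000 post-burn-in snapshots for the drift oracle.
Brent tolerance on $\log m$ is $10^{-10}$; the beta CDF is evaluated by
`pbeta`, which the tests cross-check against adaptive quadrature to
$10^{-10}$. Ties in NMDS isotonic regression are averaged; Wilson intervals
are clipped to $[0,1]$.

## Known limitations

* $Nm$ from read tables inherits the soft-detection inflation described
  above; no confidence interval on $m$ itself is provided.
* The NCM here is the one-parameter Sloan form; multi-parameter neutral
  models and null-model partitioning frameworks (βNTI/RCbray) are out of
  scope.
* The drift oracle models one community per chain; snapshots are thinned to
  near-independence rather than drawn from independent chains.
* UniFrac/Chao1/PD and any phylogeny-aware statistics are out of scope, as
  is figure rendering of the report (tables and JSON only, plus
  `autoplot()` methods for interactive use).
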