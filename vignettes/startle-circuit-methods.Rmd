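---
title: "Methods: models and design choices in startlecircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices in startlecircuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(startlecircuit)
```

# Scope

`startlecircuit` implements the computational analyses used to
characterise a whole-body hydrodynamic startle response in planktonic
annelid larvae: extraction of the sensory-motor circuit downstream of
collar-receptor (CR) mechanosensory neurons from synapse-level
connectivity tables, network motif readouts on that circuit,
mixture-model classification of behavioral responses, ratiometric
quantification of two-channel calcium traces, and paired predation-rate
statistics. A synthetic-data module generates inputs with recorded
ground truth for each stage, so the whole pipeline is testable without
any laboratory data.

# Circuit extraction

The input is a pair of tables: one neuron per row (cell class, group,
body side, segment, soma flag, bilateral partner) and one aggregated
directed edge per (presynaptic, postsynaptic) pair with an integer
synapse count. Each synapse counts as 1 regardless of its anatomical
extent, so counts are conservative connection strengths taken at face
value.

Extraction proceeds in four rule-based steps:

1. **Inclusion.** A neuron enters the first circuit layer if it receives
   at least `min_synapses` (default 3) synapses in total from at least
   `min_distinct_seeds` (default 2) distinct seed neurons. The totals
   pool all seeds regardless of body region (head and pygidial seeds
   combined); this is the natural reading of the rule and is what the
   defaults implement.
2. **Bilateral rescue.** Neurons with any seed input that fail the rule
   are added if their bilateral partner passed it. The semantics are
   deliberately single-pass: rescued neurons do not themselves rescue,
   so a second application over the enlarged set is a no-op. Rescued
   neurons are otherwise full first-layer members; in particular their
   postsynaptic targets are eligible for the motoneuron layer.
3. **Exclusion.** Soma-less fragments and glia are removed even when
   they pass the synapse filter. Removal of unpaired neurons is opt-in
   *per cell class* (`require_bilateral`), because curated circuits of
   this kind keep some unpaired midline neurons (e.g. an unpaired
   pygidial sensory-motor cell) while dropping other unpaired cells; a
   blanket rule would be wrong in both directions.
4. **Motoneuron layer.** Targets of the first layer are kept only if
   they are motoneurons, defined operationally as carrying the
   motoneuron class label *or* innervating at least one muscle or
   ciliary-band effector. On fully labelled data the two routes agree;
   the union makes the rule robust to missing class labels.

Self-loops are retained but reported. Grouped wiring diagrams sum
member-level edges into group-level edges (synapse totals are conserved
exactly, an invariant the tests check as integer equality), carry
`log10(total)` display weights, and can be thinned with the display
filters used in published diagrams (fewer than 5 synapses for the full
network, fewer than 2 for side-sorted views). The boundary is strict:
an edge with exactly the threshold count survives.

# Motif readouts

**Pathways.** Startle initiation is assumed to use the paths with the
fewest intervening synapses, so pathway search minimises hop count and
ignores edge weights; the weakest edge weight along each path is
reported so downstream consumers can filter. All minimum-hop paths per
target are returned; unreachable targets are reported as such.

**Convergence.** Shared-target analysis counts distinct postsynaptic
neurons (not synapses) passing a class filter, partitioned into the
2^k − 1 regions of the k-set Venn diagram. Disjointness and covering
are exact set identities, checked exhaustively in the tests.

**Laterality.** The anatomical ipsi/contra distinction refers to axon
trajectory, which a connectivity table cannot encode. The package uses
the side of postsynaptic *effectors* relative to the soma side as a
proxy, yielding `ipsilateral`, `contralateral`, `mixed` (both sides —
the signature of motoneurons with ipsilateral plus decussating
branches) or `undetermined` (no sided effector targets). Output is
flagged as an approximation; it is invariant under a global left-right
relabelling, which the tests verify.

**Bilateral symmetry.** The underlying description ("target-group sets
reached from left vs right seeds, per downstream group") admits more
than one formalisation. The package computes, for every group reachable
from the seed set, the Jaccard index between the target-group-label
sets of the group's left-side members and of its right-side members,
and averages over groups. This satisfies the three anchor cases: a
perfectly mirrored circuit scores 1 in every group, one-sided wiring
scores 0, and small perturbations give hand-computable intermediate
values.

# Behavioral kinematics and the mixture model

Parapodial elevation angles are normalized per larva (each larva's
maximum maps to 1), making trials comparable across animals with
different absolute angular ranges; normalization is invariant under
uniform rescaling of a larva's raw angles. Filament speed is the
maximum consecutive-frame displacement times the frame rate (µm/ms);
latencies are exact frame arithmetic.

The bimodal angle distribution is split into low-angle and wide-angle
responses by a two-component finite mixture. The component family is a
Gaussian truncated to [0, 1] — the simplest family consistent with a
bounded, bimodal histogram; the source analysis named only "finite
mixture model", so the family is a package choice. Fitting is by EM
with conditional maximization: the weighted truncated-normal MLE has no
closed form, so each M-step maximises the component's weighted
log-likelihood by box-constrained quasi-Newton (a generalized EM, which
still increases the likelihood monotonically). Numerical choices:
initialization from the means of the two extreme quartiles (deterministic,
no random restarts), relative log-likelihood tolerance 1e-8, at most
500 iterations, component SDs bounded below at 1e-3 to avoid
degenerate spikes. Non-convergence returns the best fit with
`converged = FALSE` rather than an error.

The **cutoff** is the angle between the two component means at which
the posterior component probabilities are equal (for equal weights and
SDs this reduces to the midpoint of the means). How the published
cutoff of 0.4 was derived from the fit was not specified; the
equal-posterior point is the canonical decision boundary for a
two-component mixture. Its 95% interval is a nonparametric bootstrap
(default 1000 refits) resampling *larvae*, not trials, because trials
within a larva are dependent; with no larva identifiers the bootstrap
falls back to observation resampling.

Response classification combines the cutoff with the ciliary-closure
flag into five classes (`no_response`, `closure_only`, `closure_lowE`,
`closure_wideE`, `wideE_only`). The five-class scheme has no slot for
sub-cutoff elevation without closure; such trials are classified
`no_response`, on the grounds that low-angle responses co-occur with
closures and an isolated sub-threshold elevation is measurement noise.
Latency summaries use the conventional notched-boxplot interval,
median ± 1.58·IQR/√n. Onsets falling in the same frame are below the
recording's temporal resolution and are reported as a bound (≤ one
frame period), never as zero.

# Ratiometric imaging

Both channels are background-adjusted (scalar per channel per
recording), F0 is the mean over half of the pre-stimulus window, and
the response is

$$R(t) = \frac{F(t)_{\mathrm{GCaMP}} \cdot F0_{\mathrm{tdTom}}}
             {F0_{\mathrm{GCaMP}} \cdot F(t)_{\mathrm{tdTom}}}.$$

Two deliberate choices:

* The formula as printed in the source description is a ratio of
  ratios, i.e. $R(t)/R_0$, not $(R - R_0)/R_0$, despite the ΔR/R
  label. The package emits both: `ratio_series` (as printed, 1 at
  baseline) and `delta_r_over_r` (`ratio_series − 1`, 0 at baseline).
* "Half the pre-stimulation period" does not say which half. The
  default is the *first* half (farthest from the stimulus, least
  contaminated by anticipatory activity); `half = "last"` selects the
  other reading.

Any factor multiplying both channels — the focal Z-drift the reference
channel exists to cancel — drops out of the ratio algebraically; the
tests verify cancellation to 1e-9 and the synthetic generator plants a
known amplitude that the stage recovers to 1e-6 with zero noise.
Channel values at or below background are clipped to a small positive
floor (with a warning) so ratios stay defined; a channel entirely at or
below background is an error, not a warning. Trace averaging aligns on
stimulus onset and resamples mixed-rate recordings (4 vs 2.6 Hz) onto
the slowest grid by linear interpolation, without extrapolation.

# Predation statistics

Rates follow $I = (C_i - C_f)/(N \cdot T)$ per genotype within a shared
container; no cross-genotype correction is applied, matching the
formula's use. Trials in which all predators died are excluded from
pairing (the rate is undefined), with a warning. Paired differences are
tested with an exact one-sided Wilcoxon signed-rank test using Pratt's
zero handling: zeros are ranked with the rest, then their ranks are
discarded; ties get average ranks. The null distribution is exact and
conditional on the realized rank vector — the standard
exact-conditional treatment when ties are present. For small m the
package enumerates all 2^m sign assignments; for larger m a
count-convolution over doubled (hence integer) ranks gives the
identical distribution, so no normal approximation is used at any
sample size. Per-trial differences (not per-batch aggregates) enter the
test by default, matching a design of repeated trials within batches.

# The synthetic-data generators

The generators define the conditions under which the package's claims
are tested; their defaults are fixed once and mirror the study design
where it is documented:

* **Connectome**: a layered, bilaterally mirrored network (seed CR
  groups in head and pygidium → interneuron relays → motoneurons →
  muscle and ciliary effectors) over 3 trunk segments, 2 neurons per
  group per side, with an unpaired midline ciliomotor cell. Synapse
  counts are overdispersed (negative binomial, mean 4, dispersion 2,
  shifted to ≥ 1) to stress the ≥3/≥5 count filters. The left side is
  wired first and mirrored through the partner map; `asymmetry_rate`
  breaks mirrored edges, creating natural rescue cases, and
  `orphan_fragment_rate` plants soma-less fragments that pass the
  synapse rule, exercising the exclusion step. Ground truth (rule
  passes, layer-1 members, fragments, rescue candidates) is tallied by
  a direct pass over the final edge table, independent of the selection
  code it validates.
* **Behavior**: 9 larvae × 10 filament speeds (5–95 µm/ms), angles from
  a truncated-Gaussian mixture (weights 0.35/0.65, means 0.20/0.75, SDs
  0.08/0.12 — a bimodal profile with a wide-angle majority), logistic
  closure probability in speed, latency locations at the reported
  medians (~32 ms wide-angle elevation, ~65 ms prototroch closure,
  ~46 ms bodytroch closure), 250 fps.
* **Traces**: 16 trials at 4 Hz, 10 s pre- and 30 s post-stimulus;
  difference-of-exponentials transient (rise 0.5 s, decay 4 s,
  amplitude 1.5) normalized to peak at exactly 1 *on the sample grid*,
  so the planted amplitude is recoverable exactly; shared multiplicative
  drift (sinusoid plus linear trend, a smooth deterministic stand-in
  for focal drift) and per-channel backgrounds.
* **Predation**: 12 batches × 3 trials, 25 prey per genotype in 0.2 L,
  5 predators, 1 day, baseline consumption 0.3, additive mutant effect
  0.3, a batch-level logit-normal random effect (SD 0.5) shared by both
  genotypes — this is what makes the pairing informative — and 5%
  predation-independent background mortality (controls therefore
  survive at ~95%).

What the generators do **not** emulate: real connectome noise
(reconstruction errors, polyadic synapses, partial arbors), video-level
kinematics (angles arrive already digitized), photobleaching or
motion artifacts beyond shared multiplicative drift, and copepod
behavior (consumption is binomial, not a functional response). Passing
tests therefore demonstrate correctness of the *computations* under
the stated statistical structure, not robustness to every artifact of
real recordings.

# Problem sizes and runtime choices

The validation suite uses sizes chosen to make each check sharp yet
quick: randomized graphs up to 200 nodes for oracle equivalence (the
brute-force rules are quadratic), 500 angles × 20 seeds for mixture
recovery (separation ≥ 4 SD, the regime where EM is identifiable),
2000 replicate experiments for type-I error (standard error ≈ 0.5% at
α = 0.05) and 200 for power. Bootstrap sizes in examples and the
validation script use 200 refits; the package default for final
analyses is 1000.

# Known limitations

* The laterality classification is a connectivity proxy for an
  anatomical property; neurons whose axons decussate but synapse
  ipsilaterally are misclassified by construction.
* The equal-posterior cutoff is undefined when the two fitted
  components coincide; the midpoint of the means is returned in that
  degenerate case.
* The exact test's conditional treatment of ties is standard but not
  unique; mid-p or unconditional variants would give slightly different
  p-values.
* `read_circuit_tables` expects aggregated per-pair synapse counts; it
  sums duplicate rows but does not parse raw annotation-tool exports.
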