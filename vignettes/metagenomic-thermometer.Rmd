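---
title: "The metagenomic thermometer: model, design and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The metagenomic thermometer: model, design and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metathermo)
```

## The model

Prokaryotic proteomes adapt their amino-acid composition to growth
temperature: across bacteria and archaea, the proteome-wide fraction of
the seven residues isoleucine, valine, tyrosine, tryptophan, arginine,
glutamate and leucine — written $F_{IVYWREL}$ — correlates strongly with
the species' optimal growth temperature (OGT), and OGT can be predicted
by the single-variable linear calibration

$$ T \;=\; 937 \, F_{IVYWREL} \;-\; 335 \quad [^\circ\mathrm{C}]. $$

This package extends the per-genome predictor to whole communities.
Because environmental temperature filters which lineages thrive, the
*pooled* coding composition of a shotgun metagenome carries a temperature
signal: translating the coding fraction of all reads, pooling residue
counts and applying the same calibration yields a *metagenomic predicted
temperature* (MPT) for the sampled environment.  The approach works best
where temperature is warm, stable, and the community is not dominated by
immigrant organisms adapted elsewhere (a human-gut signal in sewage, for
instance, biases MPT toward body temperature).

Two deliberate reporting conventions follow from the linearity of the
calibration.  Counts are **pooled** across all coding fragments —
equivalent to length-weighted averaging — rather than averaging per-read
fractions; this matches the definition of $F_{IVYWREL}$ over a proteome,
and makes the result invariant to how the protein stream is chunked.
And the prediction is reported **unclamped** with a warning outside the
0–100 °C calibration regime: masking extrapolation would hide upstream
QC problems rather than fix them.

## The pipeline

`predict_mpt()` chains four stages, each separately exposed:

1. **Quality filtering** (`quality_filter()`): reads shorter than 50 bp
   or with more than one ambiguous base are dropped.  Both limits are
   inclusive ("limit" read as the permitted extreme), and a read failing
   both is tallied under length only, so the tallies partition the input.
   Other IUPAC ambiguity codes are normalised to `N` on input so there is
   a single ambiguity currency.  Optionally, reads named in an exclusion
   list (e.g. host-mapped read ids produced by an external mapper) are
   removed first (`exclude_by_id()`).
2. **Six-frame ORF extraction** (`find_orfs()`): every maximal stop-free
   stretch of at least 20 residues, in any of the six frames, is a
   candidate coding fragment (`fragment` mode).  Short reads rarely span
   complete genes, so stretches truncated at read edges are admitted and
   flagged via `has_start`/`has_stop`; `complete` mode, which demands
   both a start codon and a terminal stop, is available for assembled
   contigs.  Translation uses genetic code table 11; codons containing an
   ambiguous base translate to `X` and are excluded from all composition
   counts — no residue is fabricated.  A call beginning at one of the
   table-11 initiation codons (ATG, GTG, TTG) has its first residue
   reported as `M`, per bacterial convention.
3. **Per-read frame resolution** (`select_orfs()`): see below; the
   default is a two-pass codon-usage likelihood.
4. **Pooling and calibration** (`pool_composition()`, `mpt_from_f()`).

The default `min_aa = 20` (60 nt) keeps per-call composition noise from
being dominated by length; below that, stop-free stretches arise so often
by chance in non-coding frames that they carry almost no signal.

A sample yielding no ORF at all has no coding signal: the report then
carries the explicit status `"insufficient coding signal"` rather than a
number, and command-line runs treat this as a successful run with a
negative result.

## Why frames must be resolved, and how

Six-frame scanning is intentionally exhaustive, which makes it wrong to
pool everything it returns.  For a read lying inside a gene, the true
frame contributes a stretch spanning the whole read, but each of the five
wrong frames also contributes whenever it happens to be stop-free for 20
or more codons — which, at typical codon statistics, is often.  Pooling
all calls therefore mixes a large minority of wrong-frame residues into
the composition, and because wrong-frame composition is only weakly
coupled to the community's, the temperature estimate is pulled strongly
toward the middle of the scale: in our simulations an 80 °C community
pooled over all six-frame calls reads out in the mid-30s.

Simple per-read policies are also subtly biased, in ways we measured
before settling on the default:

* *Longest call per read* still errs by several degrees at the extremes:
  a wrong frame that is stop-free across the read ties the true frame's
  length, and ties are guessed.
* *Dropping ambiguous reads* (those with near-tied frames) removes the
  guessing but conditions the retained set on stop content of the
  shifted frames, which is correlated with composition — a selection
  bias of a few degrees, uniform across targets.
* *Amino-acid likelihood scoring* of candidate frames feeds back on the
  measurand: whenever the seven signal residues are individually more
  frequent than the others, it preferentially picks IVYWREL-rich frames
  and inflates the estimate badly.

The default, `orf_selection = "likelihood"`, scores frames on **codon**
usage instead, the same signal trained gene callers exploit.  Pass one
takes, per read, the unique longest call where one exists — almost always
the true frame — and estimates codon frequencies from those unambiguous
calls.  Candidates within one residue of each read's longest call (one
residue covers the frame-capacity difference between frames of the same
read) are then rescored by mean per-codon log-likelihood, and the winner
per read is kept; one retraining iteration on the winners follows.  Every
read keeps exactly one call, so there is no selection bias, wrong picks
are rare, and — importantly — the wrong picks that do occur resemble the
trained codon distribution, so they barely displace the pooled
composition.  The procedure is deterministic: ties are broken by call
order, and no random number is consumed.

`find_orfs()` itself still reports *all* calls — the exhaustive set is
the right substrate for oracle testing and for users who want their own
selection policy (`"longest"` and `"all"` are provided).

## The synthetic-community generator

`simulate_community()` builds the ground truth the pipeline is tested
against: a proteome of `n_genes` × `gene_len_aa` residues whose pooled
$F_{IVYWREL}$ matches a target temperature exactly up to integer
quantisation (error at most one residue in the pool, reported as
`achieved_f`); reverse translation with uniform synonymous codons of
table 11 and a terminal `TAA`; and shotgun-style shredding into
fixed-length reads at Poisson coverage, drawn from both strands with
equal probability, with optional per-base `N` corruption and an optional
intergenic fraction of random sequence.  All draws derive from the spec's
seed (proteome: seed; codons: seed+1; shredding: seed+2), so every object
is bit-reproducible.

Defaults describe a modest but realistic sample: 200 genes of 150
residues, 181-bp reads (a typical post-trimming average for short-read
metagenomes), 5× coverage, no ambiguous bases.  Codon usage is uniform
over synonymous codons on purpose: MPT depends only on amino-acid
composition, and a GC- or species-specific codon-bias model would add
unvalidated realism without touching the quantity under test.  Reads are
drawn from coding sequence only by default, which isolates the
composition signal; the intergenic knob exists to stress the ORF caller,
not to emulate genome architecture.

What the generator deliberately does **not** emulate: sequencing-error
substitutions and quality-score structure, species-abundance skew,
strain variation, and real codon bias.  Passing recovery tests on these
communities therefore demonstrates that the *pipeline* is unbiased under
its own assumptions — not that real environments predict this well;
cold and high-influx environments in particular are known to read out
warm.

Under the default conditions at targets of 20–80 °C, seed-averaged
recovery in the test suite is accurate to well under ±3 °C with no trend
across the range; individual simulations scatter with a standard
deviation near 1.3 °C, which is the intrinsic sampling noise of 5×
coverage over a 30,000-residue proteome, not frame error.

## The seasonal fitter

Seasonal series of water temperature and MPT are summarised by the fixed
annual period sinusoid $y = A \sin(2\pi(x+\phi)/P) + C$ with $P = 12$
months.  Fixing the period makes the fit an ordinary linear regression on
$\sin(2\pi x/P)$ and $\cos(2\pi x/P)$, solved in closed form — no
starting values, no iteration, no seed.  The $(A, \phi)$ pair is
canonicalised to $A \ge 0$, $\phi \in [0, P)$ to resolve the
$(-A, \phi + P/2)$ aliasing deterministically; when the fitted amplitude
is numerically zero the phase is unidentifiable and reported as 0 by
convention.  Designs in which the sample times are all congruent modulo
the period are rejected as underdetermined.

`phase_lag(a, b)` reports the smallest-magnitude signed lag in
$(-P/2, P/2]$, positive when the first cycle trails the second; the
boundary case of exactly half a period is reported as $+P/2$.  A
community cycle trailing the water-temperature cycle by about two months
— microbial communities answer temperature change slowly — appears as a
lag near `+2`.

## Numerical and degenerate-input choices

* Quality filtering is pure and idempotent; its tallies always partition.
* `translate_dna()` requires a length divisible by 3 and errors
  otherwise; the empty string translates to the empty protein.
* Composition counting ignores `X`, `*`, `B`, `Z`, `U` and gaps in both
  numerator and denominator; an empty pool yields an undefined fraction,
  never 0/0 masquerading as a temperature.
* `mpt_from_f()` rejects inputs outside $[0,1]$ rather than clamping.
* Machine reports contain no timestamp, so identical input and
  configuration give byte-identical files; human-readable output prints
  temperatures to 0.01 °C, machine output at full precision.
* Test and acceptance simulations use 200 genes × 150 aa at 5× coverage
  and ten seeds per target — the smallest size at which coverage noise
  (≈1.3 °C sd) is comfortably inside the ±3 °C recovery band being
  asserted.

## Known limitations

* The ORF stage is a deterministic six-frame scanner with a codon-usage
  frame resolver, not a trained gene finder: it has no model of gene
  starts, ribosome-binding sites or coding hexamer bias beyond what it
  learns from the sample itself.  On real reads a trained caller may
  differ, most visibly at gene boundaries.  This is the package's
  largest fidelity gap relative to production pipelines and is the
  reason the exhaustive call set is kept available for inspection.
* The calibration is prokaryotic.  Eukaryotic and viral reads are not
  screened out; in typical shotgun samples their share is small, but
  samples rich in them are outside the model.
* Cold environments systematically over-predict: cold adaptation lacks a
  consistent compositional signature, so the linear calibration loses
  accuracy below roughly 10–15 °C.
* Paired-end structure is ignored; reads are processed as given.
  Adapter and quality trimming are assumed done upstream.
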