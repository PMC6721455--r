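---
title: "Models and methods behind mirep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mirep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mirep implements the computational side of a dual-luciferase reporter
screen for microRNA (miRNA) targets: designing reporter inserts around
predicted miRNA response elements (MREs), turning replicate
firefly/Renilla luminescence into normalized repression statistics and
confirmation calls, scoring sequence and thermodynamic features of the
tested sites, and correlating repression depth with prediction scores and
endogenous expression. This vignette records the models, the parameters
that matter, and the design decisions taken where more than one
reasonable convention exists.

## Repression statistics

For one construct, each biological replicate contributes a firefly/Renilla
ratio under miRNA co-transfection and under a control transfection. The
relative reporter expression is

$$R_{0,i} = \frac{(F/R)_{\text{miR},i}}{(F/R)_{\text{control},i}},
\qquad \bar R_0 = \tfrac1n \sum_i R_{0,i},$$

and a construct is *confirmed* as a target when $\bar R_0 < 1$ and a
two-sided one-sample Student $t$-test of the replicate $R_0$ values
against 1 gives $p < \alpha$ (default $\alpha = 0.05$, at least 3
replicates). To compare constructs measured in different experiments,
$R_1 = \bar R_0(\text{target}) / \bar R_0(\text{positive control})$
rescales by a batch-matched reporter perfectly complementary to the
miRNA; positive controls typically sit at $R_0 \in [0.1, 0.2]$ and
targets at $[0.5, 0.95]$, putting most $R_1$ in the 3–7 band. Larger
$R_0$/$R_1$ means weaker inhibition.

Three conventions are worth making explicit:

* **Replicate pairing.** $R_{0,i}$ pairs replicate $i$ of the miRNA
  condition with replicate $i$ of the control, matching a batch-wise
  experimental workflow and removing day effects; an unpaired mode
  (ratio of condition means) is available via `compute_r0(paired = FALSE)`.
* **Test scale and sidedness.** The $t$-test runs on raw (not log) $R_0$
  against 1 and is two-sided, following the assay's published analysis
  convention even though the scientific hypothesis is directional. A
  consequence worth knowing: because confirmation conjoins a two-sided
  $p < \alpha$ with the directional requirement $\bar R_0 < 1$, the
  false-confirmation rate under a true $R_0$ of exactly 1 is $\alpha/2$,
  not $\alpha$. `call_target` treats zero-variance replicates as $p = 0$
  when the common value differs from 1 (and $p = 1$ otherwise), and
  refuses to call constructs with fewer than 3 replicates.
* **Tabulated percentages** round half-up to one decimal
  (`confirmation_ratio`), the convention that reproduces published
  summary tables cell-for-cell.

## Seed sites

The seed is miRNA nucleotides 2–8. On the UTR (5'→3') we classify matches
by the canonical taxonomy, in precedence order: 8mer (reverse complement
of nt 2–8 followed by an A opposite miRNA position 1), 7mer-m8 (the same
heptamer without the A), 7mer-A1 (reverse complement of nt 2–7 plus the
A), and 6mer (the 2–7 core alone); anything else is "else". The scanner
(`find_seed_sites`) reports one maximal-precedence site per 2–7 core
occurrence — a core that extends to an m8 match is not additionally
reported as a 7mer-A1/6mer. Coordinates are 0-based half-open throughout,
sequences are normalized to RNA (T→U) on input, and non-canonical site
classes (centered, 3'-compensatory) are out of scope. Constructs whose
insert contains no core match anywhere are annotated "else"; scanning is
over the whole insert by default rather than a pre-declared MRE window,
since a reporter assay responds to any functional site in the insert.

`scan_sites_brute` re-derives the same answer by classifying every offset
independently and exists purely as a validation oracle.

## Reporter-insert design

Inserts aim at ~500 nt with the MRE in the middle: for a single site the
window allocates equal flanks by a floor/ceil split around the site (a
500-nt window around an 8-nt site carries 246 nt on each side). Windows
overhanging the UTR are shifted inward to preserve the 500-nt length when
the UTR allows it, and truncated to the UTR otherwise — shifting keeps
the native sequence context instead of re-centering on a shorter
fragment. Sites clustered within 300 nt (greedy left-to-right grouping on
the span from first start to last end) are cloned together with exactly
240 nt of flank on each side; the "approximately" in both numbers is
resolved to exact defaults, both configurable. Fragments whose DNA
rendering contains an internal NheI (GCTAGC) or XhoI (CTCGAG) recognition
site are excluded, since those enzymes do the cloning.

## Sequence and thermodynamic features

Per confirmed target, `compute_features` assembles:

* **AU% in windows of 50/100/200/300 nt and over the whole insert.** A
  numeric window takes w/2 nt immediately 5' and 3' of the matched span,
  excluding the match itself (the window arithmetic only sums to the
  stated size that way); clamped windows renormalize over the residues
  actually present. "Whole" includes the match.
* **Local AU content**: flanking residues in 30-nt windows score 1 if
  A/U, weighted $1/d$ by their 1-based distance from the site boundary,
  normalized by the total included weight. For 8mer/7mer-A1 sites the A
  opposite position 1 belongs to the site, so the downstream window
  starts after it. Defined only for the four canonical seed types.
* **Secondary-structure ΔG** (`structure_dg`): minimum free energy over
  pseudoknot-free structures at 37 °C under an embedded nearest-neighbor
  model, computed per AU window and for the whole insert.
* **Duplex ΔG** (`duplex_dg`): hybridization energy of the miRNA against
  the MRE plus 10 nt of flank, intermolecular pairs only.
* **Seed-pairing stability (SPS)**: by definition,
  `duplex_dg(seed, reverse_complement(seed))`.

Multi-site constructs average site-level features over their sites (most
constructs are single-MRE by design); the construct's seed type is the
highest-precedence type among its sites.

### The energy model

One parameter block (`thermo_params`) drives both ΔG operators:
Watson–Crick and GU wobble stacks from a Turner-style 37 °C table;
tabulated hairpin initiation for loops of 3–9 nt with logarithmic
extrapolation beyond (slope 1.0785 kcal/mol); affine bulge/internal-loop
penalties $3.0 + 0.5 \cdot \text{unpaired}$ kcal/mol; a linear
multibranch penalty of 3.4 kcal/mol per loop plus 0.4 per helix; duplex
initiation +4.09 kcal/mol and a +0.45 terminal penalty per AU/GU duplex
end; dangling ends free; minimum hairpin loop 3 nt; internal loops capped
at 30 unpaired nt in the folding DP (a standard cap that keeps folding a
500-nt insert at $O(n^3)$; the cap is far above any loop reachable in the
enumeration sizes used for validation). The folding recurrence is
Zuker-style (hairpin/stack/internal/multibranch decomposition with
external loop assembly, implemented in C++); the duplex recurrence runs
over monotone pair matchings with the affine gap cost folded into a
running minimum.

Two things this model deliberately is not: it is not parameter-for-
parameter identical to any external folding tool (no coaxial stacking,
dangles, or special loop corrections), and it does not compute ensemble
or accessibility quantities. Correctness is defined against exhaustive
enumeration under the same energy function — `structure_dg_enum`
enumerates every legal structure, `duplex_dg_enum` every monotone
co-pairing, and the test suite and acceptance script verify exact
agreement (1,000 scanner instances, 500 duplex instances at length ≤ 8,
200 folding instances at length ≤ 12; sizes chosen so enumeration stays
exact yet fast). Users who prefer a full-parameter implementation can
substitute whole-insert energies through `attach_external_dg`. Under the
embedded table the seed duplexes of the three classically assayed miRNAs
order as expected — the miR-1 seed (GGAAUGU, one AU-rich half) is more
than 1 kcal/mol less stable than the seeds of miR-122 and miR-124 —
while absolute SPS values shift with parameterization, which is why only
the ordering is asserted.

## Association analyses

Pearson correlations report $r$, $n$ after listwise deletion, and the
two-sided $p$ from $t = r\sqrt{(n-2)/(1-r^2)}$; zero-variance inputs
yield a flagged missing result rather than an error. Seed-type
comparisons use the one-sided two-sample Kolmogorov–Smirnov statistic
$D^+ = \sup_x[F_a(x) - F_b(x)]$ with asymptotic
$p = \exp(-2 D^{+2} n_a n_b/(n_a+n_b))$, oriented so the stronger seed
class is tested as stochastically smaller in $R_1$ (more repressed) —
the direction of the biological hypothesis. Pairwise p-values are
reported raw, as in the original analysis, with a Holm-adjusted column
alongside for reference; groups with fewer than 5 observations are
flagged low-reliability. Expression tables are filtered at an
FPKM-like detection threshold of 0.004 before joining on gene id, and
correlations against abundance default to the log scale (the
conventional scale for expression data; `log_transform = FALSE` restores
raw-scale correlation). Fold changes are
$\text{abundance}_{\text{miR}}/\text{abundance}_{\text{control}}$ over
genes detected in both conditions, all confirmed targets included
whether or not their levels decreased.

## What the synthetic generator emulates

Real measurements from this kind of screen are rarely publishable in
replicate-level form, so `simulate_scenario` regenerates the *statistical
structure* the analyses assume, deterministically from one seed:

* 22-nt uniform-random miRNAs; UTRs of 2,000 nt with planted,
  non-overlapping seed sites and a background patched free of accidental
  2–7 core matches (a planted-site round trip through the scanner is
  enforced);
* per-construct true $R_0$ drawn around seed-type means
  (8mer 0.55 < 7mer-m8 0.65 < 7mer-A1 0.75 < 6mer 0.85 < else 1.0,
  between-construct spread 0.08, clipped to the 0.5–0.95 target band),
  with a 20% planted non-target fraction — the means encode the
  "more seed pairing, more repression" hierarchy and the observed target
  $R_0$ band;
* replicate $R_0 = \text{true } R_0 \times \mathrm{lognormal}(0, 0.10)$.
  Multiplicative lognormal noise is the natural choice for a ratio of
  positive luminescence readings (positivity, right skew); the
  measurement tables carry the noise entirely in the ratio, with Renilla
  drawn lognormally around a batch mean. Batches of 20 constructs each
  carry a positive control with true $R_0 \sim U(0.1, 0.2)$;
* expression tables built by a bivariate-normal construction,
  $\log(\text{abundance}) = \mu + \sigma(r z_{R_1} + \sqrt{1-r^2}\,\varepsilon)$,
  so the planted Pearson correlation with $R_1$ is exact in expectation;
  a configurable fraction of genes is pushed below the detection
  threshold to exercise filtering.

What it does **not** emulate: real UTR base composition and repeat
structure, 3'-UTR isoform heterogeneity, position effects of MREs within
full-length transcripts, transfection dose–response, correlated noise
across constructs measured on the same day, or sequencing counting
noise. Passing parameter-recovery tests therefore demonstrates that the
pipeline's statistics recover what was planted under its own noise
model — not that the model captures every property of laboratory data.
Published correlation coefficients between repression and features on
the original material are consequently not reproduction targets here.

## Validation scales and determinism

The test suite and the acceptance script run the oracle equivalences at
the sizes above, the confirmation-call calibration and power at 1,000
constructs (true $R_0$ of 1.0 and 0.6), seed-hierarchy recovery over 100
cohorts of 40 per group (planted means 3/4/5/6, sd 1), and
expression-correlation recovery over 200 cohorts of 120 genes (planted
$r$ of 0.3 and 0). All randomness flows from a single integer seed; the
command-line pipeline writes byte-identical outputs for identical seeds.

## Known limitations

The energy operators are documented approximations, not drop-in
replacements for a full folding package; local AU weighting follows the
plain $1/d$ scheme without per-seed-type positional nuances; multi-MRE
feature averaging is a pragmatic convention; and the confirmation rule
inherits the directional-conjunction asymmetry described above. The
association module reports raw pairwise p-values by design — apply the
Holm column when many seed-type contrasts are read simultaneously.
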