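---
title: "Scoring lipid specificity and phosphoregulation of PX domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring lipid specificity and phosphoregulation of PX domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Phox homology (PX) domains are the only membrane-reader superfamily known
to recognise, between its members, all seven phosphatidylinositol
phosphates (PIPs), the lipids that mark eukaryotic organelle membranes.
Phosphorylation of a PX domain's membrane-binding surface places a
negative charge directly at the lipid interface and can switch membrane
binding off — a "PIP-stop". `pxreg` quantifies the two axes of this
biology and their relationship: how *selective* a domain is for its PIP
ligands, and how *frequently* its membrane-binding surface is reported
phosphorylated.

## The Lipid Specificity Index

Each PIP is denoted by its inositol-ring phosphate positions ("3", "45",
"345", ...). Ligands fall into two classes: **mono** (one terminal
phosphate: 3, 4, 5) and **poly** (more than one: 34, 35, 45, 345). For a
domain with ligand set $L$:

* a single ligand gives LSI $= 10$ (absolute specificity);
* no discernible membrane binding gives LSI $= 0$;
* otherwise, with $c(L)$ the predominant class and $n_\mathrm{in}$,
  $n_\mathrm{out}$ the in-/out-of-class ligand counts,

$$\mathrm{LSI} = 10 - (n_\mathrm{in} - 1) - 2\,n_\mathrm{out}.$$

**Predominance rule.** The predominant class is the class holding the
majority of the set's members, with ties resolved to poly. This was a
genuinely open design point; the majority/tie-to-poly rule is the unique
simple rule that reproduces all 64 determined published panel scores,
including the tie cases (SNX20 {3,5,35,45} → 5; SNX21 and yeast Snx4
{3,45} → 8; Vps17 → 2) and the mono-majority case (NOXO1γ {4,5,35} → 7).
Under this rule every non-empty ligand set scores in 1–10 (the package
asserts this by brute force over all 127 subsets), 10 is attained exactly
by singletons, and adding a ligand never increases the score. No clamping
is applied; an out-of-range value would raise an error instead.

Undetermined profiles ("nd", e.g. PXDC1) score `NA` and are excluded from
summary counts and association statistics. Ligand codes are
canonicalized to ascending digit order at parse time.

## Membrane-binding Sites

Membrane-docking propensity scores (MODA-style) are consumed as inputs,
one non-negative score per residue. A residue is *membrane-interactive*
when its score strictly exceeds 30 (`flag_membrane_residues()`; a score
of exactly 30 is below the calling threshold). "Several proximal"
interactive residues mark a probable membrane interaction site; we
operationalise this as **at least 3 flagged residues within any 7-residue
span** (`find_proximal_clusters()`), both parameters user-settable. The
defaults read "several" as ≥ 3 and size the span to a short loop;
overlapping qualifying spans merge into maximal clusters.

The three consensus membrane-binding elements — Site 1 (β1–β2 insertion
loop), Site 2 (β3–α1, near the conserved YS motif) and Site 3 (the
proline-rich-element–α2 loop) — are supplied as alignment-column windows
and resolved per domain through a gapped FASTA alignment
(`map_windows_to_residues()`). All coordinates are 1-based; intervals
are half-open `[start, end)` throughout (this matches phosphosite
database conventions and removes off-by-one ambiguity; window columns in
which a domain is entirely gapped yield an empty interval with a
warning). The published alignment-column boundaries are not printed in
the source material, so real-data analyses must supply their own windows
via the JSON configuration; the synthetic generator ships
self-consistent windows.

## The PIP-Stop Score

Phosphosite records (protein, 1-based position, S/T/Y residue type,
supporting citations, source database) are merged per (protein,
position): citation identifier sets are unioned, so a study counted by
two databases contributes once. Sources that report only a citation
*count* (a bare integer) are merged by taking the maximum count across
such sources and adding it to the identifier-union size; these records
are flagged `has_anonymous`. Conflicting residue types at one position
are an error; residue types outside S/T/Y are rejected at parse time
with a warning.

Each merged phosphosite falling in Site 1, 2 or 3 contributes a
citation-binned weight — 1 citation → 1, 2–4 → 2, ≥ 5 → 3 — and the
domain's PIP-Stop Score (PSS) is the sum (`compute_pss()`). Out-of-Site
phosphosites contribute nothing but are retained for the enrichment
analysis. The weights saturate at 3, which also makes any display cap on
citation superscripts irrelevant to scoring. PSS is idempotent under
record duplication and additive under residue removal; the test suite
asserts both on randomized fixtures.

The published per-domain PSS values depend on the phosphoproteomic
database snapshots current at the time of that analysis and cannot be
recomputed from the printed material; the packaged panel therefore
carries them as reference annotations (`pss_printed`), and the package
recomputes PSS only from user-supplied or synthetic records.

## The specificity–regulation association

`site_enrichment()` partitions citation totals by in-/out-of-Site;
a zero-citation input yields an *undefined* (`NA`/null) fraction, never
zero, to avoid fabricating signal. `phospho_density()` reports distinct
phosphosites per residue (as %) for a region versus the full protein.
`specificity_regulation_table()` tabulates domains per (LSI, PSS) cell
with PSS capped at 15 for display — the data behind the published bubble
plots — stratified by residue-type subset and organism where available.

The published account of the LSI–PSS relationship is a qualitative skew;
we operationalise it as a **Spearman rank correlation with a two-sided
permutation p-value** (`association_stat()`, default 10,000 label
permutations, mandatory seed). Pairs are canonically ordered before
permutations are drawn, making the result exactly invariant to the order
of panel rows; the p-value uses the add-one estimator
$(1 + \#\{|\rho^\ast| \ge |\rho|\})/(B + 1)$. A constant score vector
leaves the correlation undefined (`NA`). `px_regulation()` bundles the
whole pipeline and returns a classed object with `print`, `summary`,
`coef` and `plot` methods.

## The synthetic-data generator

`sim_config()`/`simulate_panel()` generate panels with the statistical
structure the analysis assumes, so every stage is testable without
database downloads:

* ligand sets: a size drawn from configurable weights over 1–7 (uniform
  by default), then codes sampled uniformly without replacement;
* phosphorylation: per-residue Poisson events at rate $\lambda_0$
  outside the Sites and $\lambda_0 + \beta \cdot \mathrm{LSI}/10$
  inside, so $\beta > 0$ couples regulation to specificity and
  $\beta = 0$ is the null model. Defaults $\lambda_0 = 0.02$,
  $\beta = 0.5$ put roughly 2 background and 5–12 in-Site events on a
  120-residue domain — a site-concentrated pattern of the kind the real
  panel shows;
* citations: $1 + \mathrm{Geometric}(p = 0.3)$ per observed phosphosite
  (heavy-tailed, mean ≈ 3.3), residue types S/T/Y at 0.50/0.25/0.25;
* score profiles: uniform background in (5, 25) with all residues of
  each Site window raised to (40, 70), so default cluster calling
  recovers exactly three clusters centred on the windows;
* geometry: 120-residue domains with Sites at [20, 28), [55, 63) and
  [75, 90) — loop placements typical of a PX domain fold.

All randomness flows through R's RNG seeded once per panel;
`generate_panel()` writes byte-identical files for a fixed seed and
serializes the ground truth (true LSI, true rates, realized event
counts) next to the outputs so tests never re-derive it.

What the generator does **not** emulate: real alignment gap structure
(site intervals are shared across synthetic domains), kinase identities,
inter-database coverage biases, and protein regions outside the domain.
Passing recovery tests therefore demonstrate the pipeline's statistical
correctness, not the biological conclusions on real data.

## Validation scale and numerical choices

The packaged human (50 rows, 49 determined) and yeast (15 rows) panels
rescore exactly, 64/64, in well under a second. Property suites run at:
all 127 ligand subsets (plus all single-ligand extensions) against an
independent brute-force oracle; 1,000 random profiles against an
exhaustive cluster-window scan; ≥ 1,000 randomized PSS
idempotence/additivity cases; power and false-positive calibration of
the permutation test at 200 domains with 10,000 permutations over 100
(coupled, $\beta = 0.5$) and 500 (null, $\beta = 0$) replicates with
fixed seeds — chosen as the smallest sizes at which the binomial
uncertainty of the estimated rates is well inside the asserted bands
(power ≥ 0.9; false-positive rate in [0.02, 0.08] at $\alpha = 0.05$).

Degenerate inputs are handled explicitly rather than coerced: empty
panels and record sets return empty results; empty files parse to empty
collections with a warning; undefined fractions and correlations are
`NA`/null, never 0; a profile claiming membrane binding with no ligands,
duplicate domain identifiers, ragged alignments and negative scores are
errors that name the offending row or domain.

## Known limitations

* The predominance rule is a reconstruction validated against the
  printed panel only; if the original choice used binding-strength data,
  sets not represented in the panel could in principle score differently.
* Published aggregate statistics of the phosphoproteomic corpus (total
  citations, in-Site citation share, phosphosite densities, pS/pT/pY
  splits) are functions of proprietary-era database snapshots; `pxreg`
  computes the same quantities on whatever records it is given rather
  than attempting to reproduce those numbers.
* MAI (membrane affinity) is carried purely as an annotation; no
  affinity modelling is attempted.
* The CLI and readers assume UTF-8 text and the documented column
  layouts; they are deliberately strict.
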