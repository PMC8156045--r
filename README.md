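# pxreg — lipid specificity and phosphoregulation of PX domains

Phox homology (PX) domains are the membrane-reader superfamily able to
recognise all seven phosphatidylinositol phosphates (PIPs), the lipid
codes that mark eukaryotic organelles. Phosphorylation of a PX domain's
PIP-binding surface ("PIP-stops") electrostatically blocks membrane
engagement and is a widespread regulatory mechanism, concentrated in the
most lipid-selective domains. `pxreg` is for structural bioinformaticians
and membrane-trafficking researchers who want to score that relationship
on their own (or synthetic) panels.

## What it computes

**Lipid Specificity Index (LSI).** PIPs are coded by phosphate positions
("3", "45", "345", ...) and classed as *mono* (one terminal phosphate)
or *poly* (more than one). For a ligand set with predominant class
(majority; ties to poly) containing `n_in` in-class and `n_out`
out-of-class ligands:

    LSI = 10 − (n_in − 1) − 2·n_out

with LSI = 10 for a single-PIP binder and 0 for a domain with no
membrane binding.

**PIP-Stop Score (PSS).** Phosphosite records are merged across database
sources (citation sets unioned); each phosphosite inside one of the
three consensus membrane-binding elements (Site 1: β1–β2 loop, Site 2:
β3–α1, Site 3: PRE–α2) contributes a citation-binned weight — 1 citation
→ 1, 2–4 → 2, ≥ 5 → 3 — and PSS is the sum. Sites are called from
per-residue membrane-docking scores (> 30, ≥ 3 flagged residues within a
7-residue span) and resolved through a gapped alignment.

**Association.** Spearman rank correlation between LSI and PSS with a
seeded two-sided permutation p-value, plus citation enrichment in Sites
and the (LSI, capped-PSS) bubble table.

## Worked example

```r
library(pxreg)

# the packaged human/yeast domain panel rescoring check
reproduce_table1()
#> 64/64 published LSI values reproduced

compute_lsi(c("3", "34", "45", "345"))$lsi   # poly-majority branch
#> [1] 6

# a synthetic panel with specificity-coupled phosphorylation
cfg <- sim_config(n_domains = 60, seed = 42)
sim <- simulate_panel(cfg)
fit <- px_regulation(sim$panel, sim$phosphosites, sim$site_windows,
                     n_permutations = 10000, seed = 42)
summary(fit)
#> PX domain specificity-regulation analysis
#>   domains: 60 (60 determined; 9 at LSI 10, 0 at LSI 0)
#>   mean PSS: 16.55
#>   citations: 2099 total, 1688 in Sites (80.4%); 515/637 residues in Sites
#>   Spearman rho = 0.810, permutation p = 9.999e-05 (n = 60, 10000 permutations)
```

The enrichment line says 80.4% of phosphorylation citations fall inside
the three membrane-binding Sites (which cover only 26% of the domain),
and the permutation test confirms the positive LSI–PSS coupling the
generator planted (rho = 0.81, p ≈ 1e-4). `plot(fit)` draws the bubble
plot; `coef(fit)` returns the correlation and p-value.

A thin command-line front end ships at `inst/scripts/pxreg.R`
(subcommands `lsi`, `sites`, `pss`, `analyze`, `simulate`,
`reproduce-table1`).

See `vignettes/pxreg-methods.Rmd` for the model, parameter and design
discussion.

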