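---
title: "Cleavage-site inference and spectral-count abundance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleavage-site inference and spectral-count abundance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagehead)
```

# Scope

`phagehead` analyses bottom-up (GeLC-MS/MS) peptide evidence from purified
phage particles to answer two questions: *where does the prohead protease
cleave its substrate proteins*, and *how many copies of each protein does
the virion contain*. It operates strictly downstream of the database search
engine: its input is an identified-peptide table (protein, peptide,
coordinates, spectral count, gel slice, identification probabilities), not
spectra. Spectrum scoring, FDR estimation and PTM localization are out of
scope, as are homology searches for the protease itself.

# The evidence model for cleavage sites

Trypsin cleaves after K/R, by default not before proline (the proline rule
is configurable because search engines differ on it). A peptide whose two
termini both match tryptic specificity — or coincide with the protein's own
termini — is uninformative about in-vivo proteolysis. A *semi-tryptic*
peptide has exactly one non-tryptic terminus, and that terminus marks a
bond broken before digestion, i.e. an in-vivo cleavage:

* a semi-tryptic N-terminus at residue $r$ is evidence of a cut after
  residue $r-1$;
* a semi-tryptic C-terminus at residue $r$ is evidence of a cut after $r$.

Two pseudo-signals are excluded at classification time: peptides starting
at residue 2 of a Met-initiated protein (N-terminal Met excision by the
host methionine aminopeptidase, flagged `nme`), and peptides that simply
reach a protein terminus.

Evidence is aggregated per (protein, boundary) into `support_spectra`
(summed counts) and `support_peptides` (distinct peptide forms). The
protease family considered here cleaves C-terminal to glutamate at a
P3-P2-P1 motif; `motif_preset()` ships the A-X-E model and its looser
relatives (S/A/G-X-E, S/A/G/T-X-E, and an E-anchored model with an
I/L/A/S/T P3 set for T4-style data).

**Acceptance rule.** A boundary is accepted as an observed cleavage site if
it matches the motif and has ≥ 1 supporting spectrum, or lacks a motif
match but is supported by ≥ 2 distinct semi-tryptic peptides. Boundaries
with a single spectrum and no motif are retained in a `low_confidence` tier
rather than dropped: single semi-tryptic spectra can arise from in-source
fragmentation, but discarding them silently would hide genuine
non-canonical cuts. Both thresholds are arguments of `accept_sites()`.

**Side assignment.** A cut in the N-terminal half of the chain (fraction
configurable, default 0.5) is treated as an N-side propeptide boundary,
otherwise C-side. The mature span runs from just after the most C-terminal
N-side cut to the most N-terminal C-side cut; sub-cuts inside a removed
propeptide are recorded but do not move the boundary. This follows the
observed biology: multiple cuts within a long propeptide produce smaller
fragments that clear the capsid, while the maturation boundary is the most
C-terminal of the N-side cuts.

**Inferred sites.** When coverage of a protein begins at residue $r > 1$
and no semi-tryptic peptide captured the boundary, the maturation cut is
inferred among motif-conforming positions in the interval (last observed
upstream cut, $r-1$]: the candidate closest to the coverage start (longest
propeptide consistent with coverage) is proposed. When a gel model is
available, candidates whose mature mass falls inside the protein's
peak-slice mass window take precedence over proximity; a tie is broken
toward the more C-terminal candidate. Inferred sites carry
`status = "inferred"` and are never mixed silently with observed ones —
downstream SC/M values computed on an inferred mature mass are labelled
`"inferred-basis"`.

# Masses

Chain masses are sums of standard *average* residue masses plus one water;
average rather than monoisotopic because the masses being compared to are
SDS-PAGE-scale (a `monoisotopic` switch exists for MS-level work). The
initiator Met is retained unless the caller removes it explicitly. kDa
values are rounded half-up to one decimal only at report time
(`mass_kda()`); internal arithmetic keeps full precision. Published tables
may compute a cell from an unrounded mass, so a reported quotient can
differ from the quotient of reported operands in the last digit; the
package always reproduces the quotient of its actual inputs.

# Abundance: SC/M and copy-number calibration

For protein $i$ with total spectral count $SC_i$ and mass $M_i$ (kDa),
$SC/M_i = SC_i / M_i$ is a relative-abundance statistic: spectral counts
grow with both copy number and protein length, so normalizing by mass
leaves a quantity roughly proportional to copies. Where a protein is
processed, the mature mass is the denominator of record. Report rounding is
2 decimals (`scm_report()`), matching the precision of published virion
tables.

Copy numbers are calibrated with a median ratio: for reference proteins of
known stoichiometry, $k = \mathrm{median}(\text{copies}_r / (SC/M)_r)$ and
$\widehat{\text{copies}}_i = k \cdot (SC/M)_i$. The median (not a
regression) is deliberate: the portal protein is a standard reference but
is systematically under-detected (12 copies at SC/M near 1), and a median
over references ignores such outliers. Estimates are order-of-magnitude.
Tier labels follow the same logic: `high` at or above the SC/M of the
lowest-SC/M high-copy reference (a stoichiometric anchor such as the tail
sheath), `trace` at SC/M ≤ 1, else `mid_low`.

Quality filtering precedes everything: peptide probability ≥ 0.95, protein
probability ≥ 0.999, ≥ 3 distinct peptides per protein — the standard
export filters for Scaffold-style reports. Filtering is monotone by
construction: tightening any threshold can only remove proteins.

Peptides shared between paralogous proteins are assigned to every mapping
and flagged; spectral counts are **not** split between paralogs, matching
how published per-protein totals are reported. This overcounts shared
evidence when paralogs are near-identical — a known caveat.

# Start-site reassignment

A peptide that translates in-frame upstream of a gene's annotated start is
proteogenomic evidence of a mis-annotated start. `reassign_start()` scans
in-frame codons upstream (bounded by `max_extension_codons`, default 30),
requires the peptide to translate exactly within the extension, and
proposes the nearest in-frame ATG at or upstream of the peptide's first
residue — allowing the peptide to begin at codon 2 of the proposed ORF,
because the new initiator Met may itself be removed by the host
aminopeptidase. A stop codon between the proposed ATG and the annotated
start is reported as `broken-frame`; absence of a qualifying ATG as
`no-start-found`. The proposal is always congruent with the annotated start
modulo 3 and always begins with ATG.

# The synthetic generator

`sim_config()` defaults describe the data regime the package is built for:
~100 detected virion proteins; lognormal lengths with median ~350
residues; copy numbers log-uniform on 1–600 plus three designated
references at 1560 (major-capsid-like), 264 (sheath-like) and 12
(portal-like) copies; one protein in six processed, with N-side propeptides
of 20–260 residues and occasional C-side events; 10 gel slices (6 emulates
a mutant lane) with log-spaced mass windows over 7–260 kDa and 8%
multiplicative migration noise.

The observation model is the assumption the abundance statistic rests on,
made explicit: the expected total spectral count of a protein is
$c \cdot \text{copies} \cdot M$ with $c$ = 0.05 spectra per (copy · kDa)
by default (chosen so a median protein draws a few dozen spectra, the
regime of a single MudPIT run); counts are Poisson, distributed over
digest peptides with each missed cleavage reducing detectability by a
factor 0.3. Boundary (semi-tryptic) peptides at planted cuts are emitted at
`semi_peptide_rate` times the per-peptide rate, so evidence vanishes as
that rate goes to zero; released propeptides are observed at a reduced rate
in the slice matching their own mass. Identification probabilities include
a 5% sub-threshold fraction to exercise the filters.

A single seeded random stream drives generation; one seed produces
bit-identical proteomes and reports. (All generation happens in one pass,
so per-protein sub-streams were unnecessary for reproducibility.)

What the generator does **not** emulate: fragment spectra, retention time,
ionization efficiency, peptide-level detectability bias beyond length
cutoffs (6–45 residues), shared peptides between paralogs, in-source
fragmentation, and chimeric identifications. Passing recovery tests on this
generator therefore demonstrates the correctness of the inference logic
under the stated statistical model — not robustness to every artifact of
real MS data.

**Recovery scoring.** `end_to_end_recovery()` reports precision over all
accepted sites and recall over *detectable* planted sites — those supported
by at least 3 semi-tryptic spectra in the raw report — since no
evidence-based method can recover a site that produced no evidence. Copy
recovery is the Spearman correlation between calibrated estimates and true
copies. Validation in the test suite uses 20 seeded simulations at the
default size for site recovery, 10 seeds for copy recovery, and 1,000
random proteins for digest-oracle equivalence; these sizes give stable
statistics while keeping the suite fast.

# Numerical conventions and degenerate inputs

* Residue coordinates are 1-based inclusive; "ATE-130" means the motif ends
  at residue 130 and cleavage occurs after it. Genomic coordinates are
  1-based inclusive.
* Rounding at report time is half-up (published tables do not use
  round-half-even).
* Peak-slice ties resolve to the lowest slice index and are flagged;
  all-zero profiles return `NA` with a flag.
* Gel-window membership uses a default ±15% fractional tolerance: slice
  boundaries transect smeared bands, so strict membership would be
  overconfident.
* An empty site list is an error for `build_pfm()`; window positions
  clipped at protein termini are skipped per column and the column is
  renormalized over contributing sites.
* The empty sequence has the mass of water; unknown residues are errors
  naming the residue and position (opt-in tolerance maps `X` to the mean
  residue mass).

# Known limitations

* Cleavage-site heterogeneity (ragged processing) is summarised, not
  modelled; boundaries are point estimates with support counts.
* Side assignment by chain position can mislabel a genuinely C-side cut in
  the N-terminal half of an unusually organised protein; the fraction is
  configurable per run.
* Copy estimates inherit every bias of spectral counting (length-dependent
  detectability, saturation at very high abundance) and should be read as
  order-of-magnitude.
* Reproducing published mature masses end-to-end requires the source
  genome record, which is not redistributable with the package; the
  translate→cut→mass chain is validated on synthetic CDS instead, and the
  corresponding check in the test suite reports the missing record
  honestly rather than substituting a stand-in.
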