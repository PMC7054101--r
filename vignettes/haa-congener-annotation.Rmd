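---
title: "Identifying HAA congeners from tandem mass spectra with haaMS"
author: "haaMS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying HAA congeners from tandem mass spectra with haaMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haaMS)
```

## The analytical problem

3-(3-hydroxyalkanoyloxy)alkanoic acids (HAAs) are the lipid moiety of
rhamnolipid biosurfactants: two 3-hydroxy fatty acids joined by an ester
bond. The acyltransferase RhlA condenses the two chains and thereby fixes
the congener spectrum — which chain lengths (n, m) and double-bond counts
occur, and in what proportions. Because chain length determines the
surfactant's physical behaviour (critical micelle concentration, foaming,
emulsification), congener profiling is the central readout when RhlA
variants are screened.

The measurement this package models is HPLC-MS/MS in negative-mode
electrospray ionization. Intact HAAs appear as deprotonated molecules
[M-H]⁻; collision-induced dissociation is dominated by cleavage of the
ester bond, releasing each constituent hydroxy fatty acid as its own
deprotonated free acid. A congener Cn:d-Cm:e is therefore identified by
three m/z values: the precursor and two complementary chain fragments.
Orthogonal GC-EI-MS of hydrolyzed, methylated, trimethylsilylated chains
confirms chain length (the [M-15]⁺ methyl-loss ion) and the hydroxy
position (a diagnostic TMS-oxycarbenium fragment, m/z 175 for 3-OH).

`haaMS` implements this inference chain as testable, reusable code:
mass arithmetic, combinatorial candidate enumeration, fragment-evidence
ranking, GC confirmation, congener-profile statistics, and a rule-based
gene-synteny classifier that separates genuine *rhlA* loci from the
sequence-similar transacylase gene *phaG*. A synthetic-data module
generates every input the pipeline consumes, so all stages can be tested
without instrument data.

## Mass model

All masses derive from a pinned monoisotopic atomic mass table
(C 12 exact, H 1.00782503, O 15.99491462, Si 27.97692654). A 3-hydroxy
fatty acid with n carbons and d double bonds has composition
CnH(2n−2d)O3; ester condensation of two chains subtracts one water:

$$\mathrm{HAA}(n_1{:}d_1,\ n_2{:}d_2) = \mathrm{C}_{N}\mathrm{H}_{2N-2D-2}\mathrm{O}_5,
\qquad N = n_1+n_2,\ D = d_1+d_2.$$

Deprotonation is modeled as the neutral monoisotopic mass minus the
proton mass 1.007276 Da; the electron mass is absorbed in that
convention. Nominal (integer) masses use C 12, H 1, O 16, Si 28 and
serve the unit-resolution instruments (triple quadrupole, EI).

```{r}
f <- haaFormula(chainSpec(13), chainSpec(14, 1))
formulaString(f)
mzDeprotonated(f, digits = 4)
predictFragments(parseCongener("C13-C14:1"), digits = 4)
```

### Reporting precision and rounding

Internal arithmetic is kept at full double precision; only display values
are rounded. Display rounding is half-up at the reporting precision with
one guard digit (`mzRound()`): the value is first rounded half-up at one
extra decimal, then at the reporting precision. This mirrors how
tabulated theoretical m/z values quoted at 4 decimals behave when they
derive from a 5-decimal intermediate. The convention matters for exactly
one of the reference values this package reproduces: the HAA 27:1 anion,
whose exact value 453.35855 sits on the 4-decimal rounding boundary.
Plain half-up at 4 decimals would print 453.3585; the guard-digit rule
prints 453.3586, the value quoted with the published spectrum.

A related arithmetic fact is documented in the tests rather than hidden:
rounding the monoisotopic [M-H]⁻ to an integer agrees with the nominal
[M-H]⁻ only while the cumulative hydrogen mass excess stays below 0.5 Da,
which holds up to 68 hydrogens (i.e. through the C36:1 composition) and
first breaks for fully saturated C36.

## Candidate enumeration

`enumerateCongeners()` scans total compositions N:D and resolves each
in-tolerance composition into unordered chain pairs with
`chainSplits()`. The default constraint space is chains of 4–18 carbons,
at most one double bond per chain and two per molecule — the envelope of
congeners observed across published HAA profiles (C4–C10 through
C14:1–C18:1). Per-chain polyunsaturation has not been reported, hence
the cap of 1; all bounds are configuration
(`enumerationConstraints()`), not code.

Two tolerance modes exist and exactly one is active per query: ppm
(default 5 ppm, the accuracy criterion for high-resolution Orbitrap
assignments) and Da (default choice 0.5 Da when set, for unit-resolution
data). Positional isomers — which chain carries the free carboxyl — are
deliberately one object with a `positionalNote`, because ester-cleavage
MS/MS cannot distinguish them.

```{r}
head(enumerateCongeners(453.3592), 3)
```

## Spectrum annotation and the evidence hierarchy

`annotateSpectrum()` composes enumeration and fragment matching. Each
candidate's predicted fragments are matched to the nearest unclaimed peak
within tolerance (single assignment, ties to the lower m/z). Evidence is
ranked `both_chains` > `one_chain` > `precursor_only`; ranking within a
level uses precursor mass accuracy, then the canonical name, so output
order is deterministic. Intensity is carried through for reporting but
never used for ranking — mass accuracy is the identification criterion.
Only the both-chains case is demonstrated practice, so anything below
the (configurable) evidence floor is retained but flagged `ambiguous`.

```{r}
s <- msSpectrum(453.3592, data.frame(mz = c(229.1810, 241.1811),
                                     intensity = c(100, 80)))
ann <- annotateSpectrum(s)
ann[1, c("congener", "evidence", "frag1Error", "frag2Error", "positionalNote")]
```

Two further behaviours matter in practice. First, a unit-resolution
product-ion spectrum can demonstrate co-isolated congeners: a precursor
at m/z 301 with fragments 159, 131 and 187 yields both-chains evidence
for C8-C8 *and* C6-C10 simultaneously. Second, free fatty acids
CnH(2n−2d)O2 co-elute with HAAs and are flagged
(`flagFattyAcidInterference()`) whenever a precursor is isobaric with
one, because unspecific detectors cannot rule out that false annotation.

## GC-EI-MS confirmation

The derivatization bookkeeping is `hfaFormula(chain) + CH2 + C3H8Si`
(methyl ester plus TMS ether). Chain length follows from [M-15]⁺
(homologs spaced 14 Da, −2 per double bond); the 3-hydroxy position from
the m/z 175 diagnostic, with `positionDiagnosticMz()` generalizing to
other positions by CH2 increments. Matching is at unit resolution
(default window ±0.3 Da, quadrupole scan data). Double-bond *position*
is never assigned — EI of these derivatives does not localize it.

One degeneracy is handled explicitly: the [M-15]⁺ ion of the shortest
admitted chain (C4) coincides with the 3-OH diagnostic at m/z 175. Peaks
are therefore single-assignment — the peak claimed as the diagnostic is
not reused as a chain ion — which makes the round trip from synthetic
peak lists unique for every chain, including C4 (a genuine C4 derivative
produces two ions at 175).

## Profile statistics

A `CongenerProfile` maps canonical congener names to percent fractions.
The summary statistics are:

* **Average chain length (ACL)** — the fraction-weighted mean of the
  per-molecule mean chain length (n+m)/2. On the packaged reference
  dataset this reproduces five of the seven published column averages
  exactly at one decimal (pPA2 10.5, pFLU 11.6, pDAD 11.8, pHAL 13.8,
  pAMB 13.7); for the remaining two columns the published row is
  internally inconsistent with its own printed fractions (it computes
  11.0 vs 10.8 for pANA and 13.9 vs 14.0 for pBUG, presumably because
  the original averages were taken over unrounded raw data).
* **Main congeners** — fractions at or above a threshold, default 10%,
  inferred from the highlighting convention of the reference table
  (a 10.0% entry is highlighted, an 8.9% entry is not).
* **Novelty categories** — relative to a reference congener list:
  `length_gap_ge4` (chains differing by ≥4 carbons), `new_unsaturation`
  (an unsaturated chain, compared as an exact (n, d) pair, absent from
  all reference congeners), `odd_chain` (any odd chain length). The
  per-exact-chain rule is stricter than the loose prose grouping
  sometimes seen in the literature, where a congener may be called a
  "new monounsaturation" even though its unsaturated chain occurs in a
  known congener; the strict rule is reproducible and is the one
  implemented.
* **Odd-chain share** — summed fraction of entries with at least one
  odd chain, optionally restricted to congeners absent from the
  reference list.

The packaged dataset (`congenerFractionData()`) holds 53 distinct
congeners for seven RhlA expression plasmids, 23 flagged novel, and is
audited by the test suite against the package's own mass rules.

```{r}
p <- referenceProfiles()
round(averageChainLength(p$pPA2), 1)
mainCongeners(p$pHAL)
```

## Gene-synteny classification

Sequence similarity alone cannot separate RhlA from the transacylase
PhaG (≈44% identity in pseudomonads), but their gene neighborhoods can:
*rhlA* sits in glycolipid synthesis operons (with *rhlB*, or with
*rhlC*/transporter genes), while *phaG* sits in a conserved context of
uracil-DNA glycosylase, 3-hydroxyisobutyryl-CoA hydrolase and RsuA genes
upstream and a tRNA gene downstream. `classifyLocus()` freezes that
expert criterion as an ordered rule list:

1. *rhlB* within the window **on the same strand** → `rhlA_glycolipid_operon`
   (operons are co-oriented; strand agreement is required).
2. *rhlC* or a transporter within the window and no *rhlB* anywhere in
   it → `rhlA_transporter_synteny`. This pattern exists in genomes whose
   RhlA activity is plausible but unconfirmed, so the class is reported
   distinctly and the caller decides how much weight it carries.
3. UDG, 3-HIB-CoA hydrolase and RsuA upstream plus tRNA downstream →
   `phaG`. Upstream/downstream are taken strand-aware relative to the
   candidate.
4. Otherwise `unsupported`.

Rules are evaluated in order and exactly one fires; the returned trace
names it. The window is a gene count (default 5 — published operon
figures show at most five relevant flanking genes) because the original
criterion never quantifies colocalization distance; a gene-count window
is this package's construction. The product-string → label vocabulary is
configuration (`defaultSynonymTable()`), not code, so new annotation
dialects extend the table rather than the classifier.

```{r}
classifyLocus(generateNeighborhood("phaG_context"))
```

## Synthetic data: what it emulates and what it does not

The generators define the study conditions the tests run under:

* **Mass error** — Gaussian in ppm (multiplicative), σ = 1 ppm by
  default, matching how instrument accuracy is quoted (an instrument
  with a <5 ppm criterion typically performs near 1 ppm). σ = 0 gives
  the exact theoretical values to full precision.
* **Intensity noise** — log-normal with σ(log) = 0.3, intensities
  proportional to congener fraction. No published intensity model
  exists for these spectra; this is a stated construction, and nothing
  downstream ranks by intensity.
* **Fragment detection probability** (default 1) and free-fatty-acid
  **interferent peaks** (default 0) stress the evidence hierarchy and
  the interference flag.
* **One spectrum per congener** — the LC dimension separates congeners;
  co-elution of isobaric congeners is emulated explicitly with
  `mergeSpectra()`.
* **Gene neighborhoods** — deterministic toy layouts of the four
  synteny patterns, exportable as GFF3.

Seeds are mandatory for every stochastic draw, and identical
configurations produce byte-identical serialized outputs. What passing
tests on these data do **not** show: robustness to chimeric spectra,
in-source fragmentation, isotope-pattern overlap, retention-time
modeling, or annotation dialects far from the synonym table — real-data
features the generators deliberately do not model.

## Verification at a glance

The test suite pins the atomic masses, reproduces the published worked
examples (the HAA 27:1 precursor/fragment masses and their ppm
deviations; the m/z 301 product-ion spectrum resolving C8-C8 and
C6-C10; the m/z 175 diagnostic), audits the packaged dataset, and runs
property-based checks: fragment complementarity
(f₁ + f₂ = precursor + 17.0033 Da) for every both-chains annotation
across the full default congener space (~500 congeners), equality of
precursor enumeration with a brute-force split oracle for all
compositions up to 36 carbons, and a seed-fixed Monte-Carlo study of
1,000 single-congener spectra at σ = 1 ppm annotated at 5 ppm, requiring
the generating congener to rank first with both-chains evidence in at
least 99% of trials. These problem sizes keep the whole suite at a few
minutes on one CPU while covering the entire default chain space.
`scripts/acceptance.R` recomputes the headline reference values from
scratch against the installed package.

## Known limitations

* Adducts other than [M-H]⁻, multiple charging and isotope patterns are
  out of scope; spectra are assumed deisotoped and singly charged.
* Positional isomers are never split; the annotation carries the joint
  flag instead.
* The novelty categorization is only as good as the reference congener
  list; enlarging the reference can only remove categories (a tested
  monotonicity property).
* The synteny rules encode one published criterion; they are a
  screening aid, not a substitute for experimental confirmation of
  acyltransferase activity.
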