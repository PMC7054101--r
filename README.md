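# haaMS

Identification and profiling of 3-(3-hydroxyalkanoyloxy)alkanoic acid
(HAA) congeners from mass spectra.

HAAs — two 3-hydroxy fatty acids joined by an ester bond — are the lipid
precursors of rhamnolipid biosurfactants. The RhlA acyltransferase that
condenses the two chains determines which congeners Cn:d–Cm:e a strain
produces, and the congener spectrum in turn determines the surfactant's
properties. `haaMS` is for analytical chemists and strain engineers who
profile those congeners by HPLC-MS/MS and GC-EI-MS and who vet candidate
*rhlA* genes.

## What it computes

In negative-mode electrospray an HAA appears as its deprotonated molecule
and fragments by ester-bond cleavage into the two deprotonated chains:

    [M-H]⁻ of Cn₁:d₁-Cn₂:d₂  =  m(C_N H_{2N-2D-2} O_5) − 1.007276,   N = n₁+n₂, D = d₁+d₂
    fragments                =  m(C_{nᵢ} H_{2nᵢ-2dᵢ} O_3) − 1.007276

with complementarity f₁ + f₂ = precursor + 17.0033 Da. The package
implements, as separately testable modules:

* exact/nominal mass arithmetic for chains, congeners and ions
  (`hfaFormula`, `haaFormula`, `mzDeprotonated`, `ppmDeviation`);
* combinatorial enumeration of chain splits consistent with a precursor
  m/z at ppm or unit-resolution tolerance (`chainSplits`,
  `enumerateCongeners`);
* evidence-ranked MS/MS annotation with free-fatty-acid interference
  flagging (`annotateSpectrum`);
* GC-EI-MS chain confirmation of FAME-TMS derivatives via [M-15]⁺ and
  the m/z 175 3-hydroxy diagnostic (`assignChainFromEI`);
* congener-profile statistics: average chain length, main congeners,
  novelty categories, odd-chain shares (`profileReport`), plus a
  packaged 53-congener reference dataset for seven RhlA plasmids;
* a gene-synteny classifier separating *rhlA* loci from *phaG* loci
  (`classifyLocus`, `readNeighborhood`);
* synthetic-data generators for spectra, profiles, EI peak lists and
  toy gene neighborhoods (`generateMsmsSpectra`, ...).

## Worked example

A high-resolution MS/MS spectrum of an HAA with 27 carbons and one
double bond: precursor measured at m/z 453.3592, fragments at 229.1810
and 241.1811.

```r
library(haaMS)

s <- msSpectrum(453.3592,
                data.frame(mz = c(229.1810, 241.1811), intensity = c(100, 80)))
ann <- annotateSpectrum(s)
ann[1, c("congener", "evidence", "precursorError", "frag1Error", "frag2Error")]
#>    congener    evidence precursorError frag1Error frag2Error
#> 1 C13-C14:1 both_chains       1.436832  0.3550034  0.7519666
```

The top annotation is C13-C14:1 with both chain fragments matched: the
precursor deviates 1.4 ppm from the theoretical 453.35855 (which prints
as 453.3586 at 4 decimals), and the fragments deviate 0.4 and 0.8 ppm
from the theoretical chain masses 229.1809 and 241.1809 — all far inside
the 5 ppm acceptance window. `positionalNote` is set because the two
esterification orders cannot be distinguished. All other 27:1 chain
splits receive only precursor-level evidence and are flagged ambiguous.

Profile statistics on the packaged reference dataset:

```r
p <- referenceProfiles()[["pPA2"]]
round(averageChainLength(p), 1)
#> [1] 10.5
mainCongeners(p)
#> [1] "C10-C10" "C10-C12"
```

The pPA2 (P. aeruginosa RhlA) profile averages 10.5 carbons per chain
and is dominated by C10-C10 (49.5%) and C10-C12 (32.5%).

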