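Package: haaMS
Title: Identification and Profiling of HAA Congeners from Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying 3-(3-hydroxyalkanoyloxy)alkanoic acid
    (HAA) congeners, the lipid precursors of rhamnolipid biosurfactants,
    from negative-mode electrospray tandem mass spectra. Implements exact
    and nominal mass arithmetic for 3-hydroxy fatty acid chains and their
    ester condensates, combinatorial enumeration of chain compositions
    consistent with a precursor m/z at ppm or unit-resolution tolerance,
    ester-cleavage fragment prediction and evidence-ranked spectrum
    annotation, GC-EI-MS chain-length and hydroxy-position assignment of
    methylated trimethylsilylated hydroxy fatty acids, congener-profile
    summary statistics (average chain length, main congeners, novelty
    categories, odd-chain shares), and a rule-based gene-synteny classifier
    separating rhlA acyltransferase loci from phaG transacylase loci. A
    synthetic-data module generates spectra, profiles and toy gene
    neighborhoods with controlled noise so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'congener-space.R'
    'gcms-annotator.R'
    'haaMS-package.R'
    'io.R'
    'mass-core.R'
    'msms-annotator.R'
    'profile-stats.R'
    'synteny.R'
    'synthetic-data.R'
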