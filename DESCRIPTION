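Package: oleoflux
Title: Stoichiometric Yield Analysis for Lipid Production in Oleaginous Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing theoretical lipid yields in oleaginous yeast
    central-carbon metabolism. Encodes small stoichiometric reaction networks
    with exact rational coefficients, computes precursor and cofactor demand
    (acetyl-CoA, malonyl-CoA, NADPH) for arbitrary triacylglycerols, and solves
    minimum-substrate / maximum-mass-yield linear programs with strict cofactor
    balance using an exact rational simplex, including redox-infeasibility
    diagnosis for glycolysis-deficient strains and comparison of
    phosphoketolase/phosphotransacetylase pathway variants. Also implements
    enzyme-assay arithmetic (DTNB phosphotransacetylase specific activity,
    ferric-hydroxamate phosphoketolase readout, Bodipy Fl/OD), batch
    fermentation metrics (lipid yield, lipid content, lipid-free dry cell
    weight, windowed cell-specific productivity), seeded synthetic-data
    generators for both, and a rare-codon replacement rule for coding
    sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
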