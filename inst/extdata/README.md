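# extdata

`ds1_literature_scales.csv` (not distributed): the 91-scale literature
hydrophobicity table used by the PC1 diagnostic in
`tests/testthat/test-acceptance.R`. Expected format is the package's
wide-CSV dialect: first column `residue` with the 20 canonical
one-letter codes, one column per scale, `.` decimal, UTF-8. Place an
export here to enable the diagnostic; without it that single
acceptance test stays red by design.
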