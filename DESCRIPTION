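Package: fufatags
Title: Screening of Furan Fatty Acid Triacylglycerols in LC-HRMS2 Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification of triacylglycerols that carry furan fatty acids
    (FuFA-TAGs) in centroided high-resolution tandem mass spectra. Provides
    monoisotopic formula arithmetic, a fatty-acid building-block library with
    the number-letter-number FuFA nomenclature, combinatorial TAG candidate
    enumeration with protonated and ammoniated precursor masses, in-silico
    prediction of the diagnostic fragment ions (diacyl [M-RCOO]+, acylium
    [FCO]+, furan core and McLafferty ions), ppm-tolerance peak matching
    against mzML, MGF and tab-separated peak lists, the multi-step MS2
    identification filter that assigns FuFA-TAG compositions, reporting of
    relative abundances across replicate runs, indirect content estimation by
    proportional allocation, and a deterministic synthetic-spectrum generator
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mzR,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
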