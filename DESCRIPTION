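Package: excessabs
Title: Dye Self-Aggregation Analysis from UV-Vis Excess Absorbance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies the self-aggregation of dyes in solution from a
    concentration series of UV-Vis absorption spectra. Each spectrum is
    reduced to an integral absorbance over a band window; the deviation from
    the Lambert-Beer reference anchored at the infinite-dilution (monomer)
    slope defines an excess absorbance, whose dependence on total
    concentration is fitted with a non-negative least-squares model over
    integer aggregation numbers n. The minimum-RMSE n yields the aggregation
    number, the equilibrium constant of the nD <-> Dn equilibrium and the
    aggregate integral extinction coefficient, with a speciation-based
    reliability reconstruction and bootstrap uncertainty on the equilibrium
    constant. Includes a synthetic-spectra generator with presets emulating
    sodium fluorescein in water and acetonitrile and methylene blue in water.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
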