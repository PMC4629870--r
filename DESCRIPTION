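Package: thermoslurry
Title: Thermal-Gradient Anaerobic Slurry Simulation and Rate Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates anaerobic sediment slurry incubations across a
    0-80 degree Celsius thermal gradient with coupled substrate pools
    (sulphate, hydrogen, acetate, methylamine, methane, DIC, ammonium,
    metal oxides) and temperature-windowed microbial processes, and
    implements the quantitative analyses used on such experiments:
    radiotracer turnover rates, sulphate removal rates, Arrhenius
    activation energies and Q10 factors with two-regime breakpoint fits,
    in-situ Gibbs free energies of catabolic reactions, a carbon dioxide
    mineralization balance, substrate partitioning of sulphate reduction,
    critical-temperature detection, and 16S rRNA gene-copy to cell-number
    conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
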