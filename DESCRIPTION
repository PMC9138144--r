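Package: GroverMatch
Title: Simulated Quantum Exact and Approximate Multiple Pattern Matching on
    DNA Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classical state-vector simulation of quantum multiple-pattern
    matching on DNA texts. Provides algebraic-normal-form (ANF) synthesis of a
    quantum-addressable memory over two-bit encoded nucleotide substrings, a
    constant-depth exact-match oracle, Grover amplitude amplification with
    iteration scheduling, Hamming-distance approximate filtering of candidate
    start positions, exact and approximate quantum counting via phase
    estimation on the Grover operator, and emulated multi-core scheduling of
    many patterns. Includes an evaluation protocol tallying correctly and
    incorrectly identified pattern indices over repeated measurements, a
    synthetic-text generator with planted occurrences, and gate-count
    accounting for the simulated circuits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
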