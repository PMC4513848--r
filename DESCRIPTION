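Package: vegassim
Title: In Silico Yeast Golden Gate and VEGAS Pathway Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design and simulation toolkit for modular construction of
    multi-gene pathways in Saccharomyces cerevisiae. Models type-IIS
    (offset cutter) restriction digestion and one-pot Golden Gate
    assembly of standardized transcription-unit parts (yeast Golden
    Gate, yGG), simulates homologous-recombination pathway assembly
    into a linearized acceptor vector directed by orthogonal VEGAS
    adapter sequences, designs new orthogonal adapters against a
    background genome by rare k-mer concatenation and similarity
    ranking, and enumerates combinatorial promoter/terminator
    libraries together with variant identification from recovered
    plasmid sequence. A seeded synthetic fixture generator provides
    self-consistent parts, vectors and worked pathway designs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
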