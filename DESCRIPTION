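Package: oligovault
Title: DNA Data Storage Codec, Electrode-Chip Read-Channel Simulator and Decoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for DNA data storage on electrode-array chips. Encodes
    words, pixel-art images, triangle meshes and arbitrary byte streams into
    primer-flanked, indexed oligonucleotide designs protected by a systematic
    Reed-Solomon inner code over GF(2^m) and an XOR outer erasure code.
    Simulates the read channel of an electric-field memory chip: per-electrode
    immobilized pools, log-linear reuse-cycle degradation, cross-electrode
    crossover, per-base substitution/deletion/insertion errors and
    negative-binomial depth sampling, emitting FASTQ with a ground-truth
    sidecar. Decodes via primer-anchored demultiplexing, per-index plurality
    consensus, Reed-Solomon correction with re-encode verification, XOR
    erasure recovery, and a modified-IQR repair of unrecovered coordinates,
    reporting per-index depth, perfect-match and recovery metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
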