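Package: eegmfcc
Title: Fragment-Based Excited-State Calculations for Fluorophore-Nucleic-Acid Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Electrostatically embedded generalized molecular fractionation with
    conjugate caps (EE-GMFCC) for excited-state properties of fluorescent
    RNA-aptamer complexes. Severs nucleic-acid backbones at the C3'-O3' ester
    bond with hydrogen link atoms, enumerates capped-residue, conjugate-cap,
    and two-body fragment species, embeds each fragment QM calculation in the
    point-charge field of the remainder of the system, and assembles excitation
    energies, transition electric dipole moments, oscillator strengths,
    excited-state atomic forces, and ground-state energies from per-fragment
    results. Any quantum chemistry program can act as the per-fragment engine
    through a file-based task contract; a deterministic closed-form mock engine
    makes every assembly formula testable without electronic-structure
    software. Includes a per-ribonucleotide spectral-shift decomposition,
    deviation statistics for benchmarking against truncated full-system QM/MM
    references, and a seeded generator of toy fluorophore-pseudo-RNA complexes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
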