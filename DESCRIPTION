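Package: dalksizer
Title: Donor Graft Punch Sizing for Deep Anterior Lamellar Keratoplasty
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Geometric planning of donor graft size for deep anterior
    lamellar keratoplasty (DALK). Models the recipient cornea as a sphere,
    converts keratometric power to radius of curvature, and computes the
    arc length of Descemet's membrane left on the recipient bed for a
    given trephine diameter via the cosine rule. Recommends the donor
    punch size matching that arc (snapped to available 0.25-mm punch
    steps), assesses the membrane-to-graft mismatch that causes
    Descemet's membrane folds, solves the inverse problem (trephine for
    a target punch), and generates, reads, writes and validates the full
    curvature-by-trephine recommendation table. Includes a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
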