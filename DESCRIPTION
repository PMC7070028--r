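Package: oomat
Title: Maternal mRNA Translation Analysis in Maturing Oocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dissecting dual (repressive and activating)
    control of maternal mRNA translation by 3'UTR-binding proteins during mouse
    oocyte maturation. Provides simulators for RiboTag IP/input count matrices,
    3'UTR sequences with planted cis-elements, dual-channel fluorescent reporter
    time courses and RIP enrichment tables; an IUPAC motif scanner with
    adenosine-replacement mutagenesis design; translational-efficiency and
    differential ribosome-loading analysis built on a conditional negative
    binomial exact test with Benjamini-Hochberg FDR; reporter translation-rate
    fitting with poly(A)/adenylation inference; and integration of RIP
    enrichment with translation classes into target quadrants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
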