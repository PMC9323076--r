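Package: vibdenoise
Title: Waveform-Domain Enhancement of Wood-Borer Vibration Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting wood-boring insect larvae from substrate-borne
    vibrations recorded with a contact probe. Provides a synthetic vibroscape
    generator (sparse borer pulse trains and wind/bird/babble/floor noise
    scenes), a dataset-construction pipeline (WAV input/output, 5-second
    segmentation, spectral subtraction, energy-based clip selection, and
    SNR-controlled mixing), a waveform-mapping denoising network built from a
    strided convolutional encoder/decoder with skip connections and a simple
    recurrent unit (SRU/SRU++) sequence-modeling bottleneck, six training
    objectives, objective quality metrics (SNR, segmental SNR, and the
    LPC-based log-likelihood ratio), a seeded Adam training loop, and a
    command-line interface covering the full synthesize-mix-train-enhance-
    evaluate pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
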