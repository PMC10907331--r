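Package: ecapsim
Title: Simulation of Electrically Evoked Compound Action Potentials in a 2-D Cochlear Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A phenomenological 2-D model of an implanted cochlea for
    simulating electrically evoked compound action potential (eCAP)
    amplitude-growth functions (AGFs). Auditory nerve fibers are modeled as
    stochastic-threshold leaky integrate-and-fire units distributed along an
    unrolled cochlear duct; charge-balanced biphasic pulses are attenuated by
    2 dB/mm with Euclidean distance, fiber spikes are convolved with a
    unitary response and summed into recorded eCAP traces. Asymmetric
    sigmoids are fitted to the AGFs to derive eCAP thresholds and slopes, and
    three inter-phase-gap (IPG) effect metrics of cochlear neural health
    (absolute and relative slope effects, log-log offset) are computed across
    conditions varying neural survival, electrode-neuron distance, IPG and
    recording electrode.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
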