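Package: tapcircuit
Title: Spiking-Neuron Circuit Simulation of Interval Timing in the
    Synchronization-Continuation Tapping Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a medial-premotor-cortex-inspired spiking neural
    circuit that learns and reproduces sub-second time intervals in the
    synchronization-continuation tapping task (SCT). Single cells follow
    the two-variable quadratic integrate-and-reset (Izhikevich) model or a
    rate-based activity equation; interval memory is stored in plastic
    synaptic weights trained by a time-adaptive drift-diffusion rule that
    maps a learned drift rate onto the ramping activity of a
    relative-timing readout cell. Includes the full tapping-task protocol
    (metronome synchronization followed by self-paced continuation),
    firing-rate analysis utilities (kernel rate estimates, ramp slopes,
    produced-interval statistics, scalar-property tables), configuration
    and CSV/JSON run logging, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
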