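Package: topotrack
Title: Decoding Topological Transitions of Tracked Object Configurations
    from Ongoing EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and decoding pipeline for multiple-object tracking
    (MOT) experiments in which the four tracked items are treated as an
    illusory shortest-path polygon. Provides a constrained MOT trajectory
    generator, per-frame computation of the shortest-path polygon and its
    convex-hull topology, detection of flip/concave/convex transition
    events with debounce and boundary filtering, a synthetic 32-channel
    EEG generator with event-locked waveforms on 1/f noise, ERP epoching
    and PCA spatial filtering, a sliding normalized cross-correlation
    event-similarity decoder with permutation-baseline correction and
    time-lag maps, and group-level inference via cluster-based permutation
    tests and pointwise repeated-measures F statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
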