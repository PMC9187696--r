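Package: ieegerp
Title: Evoked-Response Analysis of Intracranial EEG with Cluster-Level Permutation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A pipeline for analysing evoked responses in intracranial EEG
    recorded during naturalistic auditory stimulation. Builds stimulus marker
    tracks (note-onset peak picking on an onset-strength envelope with
    weak-onset exclusion, and dynamic-time-warping transfer of score-annotated
    phrase-boundary times onto audio time), preprocesses multichannel
    recordings (bad-channel exclusion, zero-phase notch and band-pass
    filtering, average re-referencing, anti-aliased decimation), cuts
    peri-stimulus and between-stimulus reference windows, rejects windows
    containing interictal epileptiform discharges by template matching, and
    tests condition differences per cortical subregion with a Mann-Whitney-U
    based cluster-level permutation test. Includes a synthetic session
    generator with known ground truth (1/f background noise, injected evoked
    templates, Poisson spike artifacts) so every stage is testable without
    patient data, and cross-session integration (significant-session counts,
    shading intervals, cluster summary tables).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, signal, jsonlite
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
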