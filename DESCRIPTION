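Package: ldadp
Title: Spike Sorting by Joint Linear Discriminant Analysis and
    Density-Peaks Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sorts extracellular action potentials into putative single
    units by jointly optimizing a supervised linear discriminant (LDA)
    feature subspace and a density-peaks (DP) clustering of the projected
    waveforms. The subspace is initialized by principal components and
    refined each iteration from the current cluster labels; a
    compactness/separation merging step then determines the number of
    units automatically. Includes band-pass filtering and median-based
    spike detection with waveform alignment, evaluation metrics (optimally
    matched sorting accuracy, Davies-Bouldin index, precision/recall
    against partial ground truth), a simulator producing template banks
    with controlled waveform similarity, Poisson spike trains and
    spike-spectrum-matched background noise, and readers/writers for
    delimited waveform matrices and wave_clus-style MAT-files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
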