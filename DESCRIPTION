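Package: sononerf
Title: Neural Reflectivity Fields for Binaural Echolocation Scene Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a neural reflectivity field of a 3D scene from phase-less
    binaural echo spectrograms recorded at known sensor poses, in the style of
    neural radiance fields adapted to broadband FM echolocation. Includes a
    frequency-domain point-scatterer echo simulator with directional
    emitter/ear filters, the dechirped-spectrogram preprocessing pipeline, a
    differentiable acoustic rendering equation over discretized hemispheres
    with analytic backpropagation and Adam training, and voxel-grid scene
    reconstruction (direction-integrated energy volumes, marching-tetrahedra
    isosurfaces, maximum intensity projections, and paired-scene energy
    differencing for prey localization).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
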