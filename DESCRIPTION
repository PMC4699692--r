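Package: volseg
Title: Headless Segmentation Engine for Volumetric Microscopy Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable library for segmentation of 3-D/4-D light- and
    electron-microscopy image stacks. Provides a four-layer volumetric data
    model (image, selection, mask, model) with voxel-size and bounding-box
    bookkeeping, bounded undo and action logging; readers and writers for
    multipage TIFF, NRRD, PNG series and AmiraMesh; preprocessing filters
    (intensity normalization, Perona-Malik anisotropic diffusion, grayscale
    morphology, Frangi vesselness) with region-of-interest restriction;
    scriptable equivalents of interactive tools (brush, magic wand, region
    growing, membrane tracking, shape and line interpolation, thresholding);
    semiautomatic engines (SLIC supervoxels, graph-cut over supervoxel
    adjacency graphs, marker-controlled watershed, distance-transform object
    separation, random-forest voxel and supervoxel classifiers); object
    quantification with property-based filtering; a replayable pipeline
    runner including a 13-step mitotic-cell organelle workflow; and synthetic
    phantom generators with ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    randomForest,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
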