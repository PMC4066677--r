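Package: lacunatex
Title: Gliding-Box Lacunarity Analysis of Porous Scaffold Microarchitecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based three-dimensional texture characterization of porous
    scaffolds and other binary porous media. Provides local (Niblack, Sauvola)
    and global segmentation of grayscale micro-CT slice stacks with automatic
    strategy selection by normalized cross-correlation of Fourier phases,
    reconstruction of binary voxel volumes, porosity, gliding-box lacunarity
    LAC(r) and the porosity-normalized relative lacunarity function
    RLF(r) = -ln(LAC)/ln(n) across box sizes, randomness-scale detection from
    curve shape, and parallel-subvolume heterogeneity comparison. Includes
    seeded synthetic generators (periodic lattices, Bernoulli fields,
    overlapping-sphere foams with pore occlusion, grayscale renderings) so
    every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'geometry.R'
    'io.R'
    'lacunarity.R'
    'lacunatex-package.R'
    'segmentation.R'
    'pipeline.R'
    'synthetic.R'
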