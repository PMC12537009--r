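Package: ribbonphys
Title: Simulation and Analysis of Inner Hair Cell Ribbon-Synapse Physiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis chain used in cellular
    physiology studies of inner hair cell (IHC) ribbon synapses: whole-cell
    voltage-clamp IV extraction and Boltzmann fractional-activation fitting of
    Ca(V)1.3 currents, p/4 leak and liquid-junction-potential correction,
    exocytic membrane-capacitance (delta Cm) and calcium-charge (QCa)
    quantification with Lindau-Neher admittance inversion, single-active-zone
    calcium-imaging fluorescence-voltage (FV) analysis with interleaved voltage
    ramps, 3D two-channel synaptic-puncta segmentation and ribbon-PSD
    juxtaposition scoring, auditory brainstem response (ABR) threshold
    detection, and a gated two-sample/omnibus statistical decision procedure.
    Every raw input the pipeline consumes can be generated synthetically with
    known ground truth, so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    e1071,
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    tiff,
    yaml
Config/testthat/edition: 3
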