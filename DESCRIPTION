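Package: lgmdsim
Title: Emergent Looming Detection in a Model of the Locust Visual Pathway
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the visual pathway of the locust from photoreceptors to
    the Lobula Giant Movement Detector (LGMD), a wide-field neuron selective
    for looming (approaching) objects. The network is built exclusively from
    leaky linear-threshold and leaky integrate-and-fire units: a
    centre/surround lamina, on/off transient detectors in the medulla, four
    directionally selective ensembles, and a retinotopic fan-in whose surround
    geometry sets the angular threshold at which the firing rate peaks.
    Includes a synthetic stimulus generator (looming, receding and uniformly
    expanding objects rendered onto a simulated compound-eye raster),
    phenomenological comparison models (the multiplicative eta model, the
    second-derivative model and a multivariate linear input-output mapping),
    spike-train analysis utilities, and scripted experiment protocols for
    speed, shape, texture and approach-angle sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
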