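Package: dwiphantom
Title: Ground-Truth Diffusion MRI Brain Phantom Simulation
Version: 0.1.0
Authors@R:
    person("Phantom", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Builds realistic multi-shell diffusion-weighted MRI datasets with
    a perfectly known ground truth. A tissue volume-fraction map (white matter,
    cortical and deep grey matter, CSF) and a white-matter streamline
    tractogram are combined through multi-compartment diffusion models
    (zeppelin-cylinder white matter with Gaussian-phase-distribution restricted
    diffusion, isotropic tensors elsewhere) and spin-echo relaxometry, then
    degraded through a simulated acquisition: k-space truncation (Gibbs
    ringing, partial volume), Fermi/Hamming apodization, complex Gaussian
    k-space noise (Rician magnitude statistics) and ideal-rectangle slice
    selection. A synthetic-substrate generator provides brain-like inputs
    (crossing/bending/kissing bundles, grey-matter rim, CSF cavity, deep
    grey-matter blobs) so the full pipeline runs without any external data.
    Validation-side estimators (log-linear tensor fit, mixture-weight
    recovery, streamline-count connectivity matrices) close the loop.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
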