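Package: mtam
Title: Multi-Trait Animal Models via Modified-Cholesky Reparameterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of genetic and residual (co)variance matrices in
    multi-trait animal models using a modified-Cholesky (LDL')
    reparameterization of the trait covariance matrices. The unconstrained
    dependency parameters guarantee positive-definite covariance estimates for
    any parameter value. Inference engines on the collapsed Gaussian
    likelihood include restricted maximum likelihood (REML), a Laplace
    approximation of the hyperparameter posterior with Monte Carlo
    back-transformation to original-scale genetic parameters, and an adaptive
    random-walk Metropolis sampler as an MCMC cross-check. Supporting tools
    cover pedigree-based additive relationship matrices, VanRaden genomic
    relationship matrices, BLUP breeding values from Henderson's mixed model
    equations, trait simulation from G0 (x) A + R0 (x) I, and a replicate
    simulation-study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
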