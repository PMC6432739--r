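Package: chemoviro
Title: Tumor-Virus-Drug Dynamics Under Combined Chemotherapy and
    Oncolytic Virotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and local stability analysis of a compartmental
    model of chemovirotherapy: uninfected tumor cells, virus-infected
    tumor cells, free oncolytic virus, and a chemotherapeutic drug
    delivered by a constant, single-bolus (exponentially decaying), or
    periodic (sinusoidal) infusion schedule.  Provides the
    nondimensionalized model family (no treatment, chemotherapy only,
    virotherapy only, full combination), closed-form drug
    pharmacokinetics for each schedule, a fixed-step fourth-order
    Runge-Kutta integrator, a method-of-steps integrator for the
    delayed variant with virus-infection and drug-response lags,
    steady-state catalogues with numeric refinement, Jacobian and
    Routh-Hurwitz stability machinery, Dulac exclusion of periodic
    orbits for the planar chemotherapy submodel, transcendental
    characteristic equations with critical-delay (Hopf-type crossing)
    computation, and a scenario runner that reproduces the model's
    reference numerical experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
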