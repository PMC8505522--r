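Package: vrankcascade
Title: Multi-Layer Behavioral Network Simulation of Disaster Shock Cascades
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatially explicit agent-based simulation of how a natural-disaster
    shock to food production cascades through a two-layer (production and
    household) economic network via trade and migration. Each location runs a
    circular-flow economy (output, wages, prices, endogenous food budget share);
    gravity-model diffusion with behavioral thresholds moves goods toward
    profitable markets and workers toward higher real incomes. Includes the
    VRank multi-layer vulnerability index, a shock-sweep experiment harness,
    and spatio-temporal analysis tools (baseline-relative indicators,
    distance-by-density heat bins, adjustment-cycle traces).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
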