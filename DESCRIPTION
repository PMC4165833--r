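Package: refugia
Title: Ecological Prioritization and Evaluation of Farmland Goose Refuges
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for allocating farmland subsidies to goose refuges and
    evaluating the resulting scheme. Fields are ranked by a four-criterion
    rank sum (size, connectivity, historic goose use, roost proximity), a
    fixed subsidy budget is allocated greedily down the priority list with
    preferential adjoining of neighbouring fields, the dropping-count
    survey protocol (three 2 m circles per field, stratified-random
    control fields within 2 km of refuges) is simulated on seeded
    synthetic landscapes, and the evaluation statistics are computed:
    refuge/control density comparisons, Spearman distance-decay
    correlations, cumulative priority-fractile coverage of refuge area,
    and the grazing-pressure share captured by refuges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
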