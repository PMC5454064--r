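Package: steprec
Title: Therapy-Content Suggestion Engine for Moderated Online Social Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A standalone, testable re-implementation of the automated
    therapy-content suggestion machinery used in moderated online social
    therapy platforms. Provides a deterministic lexicon-based text analyzer
    (sentiment, five basic emotions, keyword extraction), a valence-partitioned
    content recommender scoring candidates by keyword similarity and emotion
    congruence with seeded random tie-breaking, non-personalized discovery
    rankings (search, browse, popularity and hidden-treasure lists),
    engagement analytics over usage-event logs and moderator-suggestion
    ledgers, a minimal rule-based conversational search assistant, and a
    synthetic fixtures generator so everything is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests: optparse, testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
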