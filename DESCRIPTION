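Package: replynet
Title: Reply Networks and Psycholinguistic Profiles of Threaded Forum Conversations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint social-network and linguistic analysis of
    threaded online forums, motivated by online health communities for
    depression. Builds directed reply-to conversation multigraphs from
    forum threads, characterizes their topology (density, reciprocity,
    clustering, shortest paths, betweenness, power-law degree fits, and
    the Bow-Tie decomposition into SCC/IN/OUT/TENDRILS/TUBES/DISC),
    computes dictionary-based word-category occurrence rates in the LIWC
    tradition, generates Erdos-Renyi, Barabasi-Albert-variant and
    Watts-Strogatz comparison networks, and correlates member-level
    topological and linguistic features. Includes a seeded synthetic
    forum-corpus generator emulating the structure of a large
    depression-support group.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
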