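# two-concept demo lexicon used across test files
demo_lexicon <- function() {
  lexicon(tibble::tibble(
    id = c("DEMO:0000001", "CHEBI:145994"),
    axis = c("DIS", "CHEM"),
    preferred_label = c("covid-19", "remdesivir"),
    synonyms = list("coronavirus disease 2019", character()),
    xrefs = list(character(), character())
  ))
}

# the nine per-axis annotation counts of the three reference collections
collection_axis_counts <- function() {
  list(
    MEDLINE = c(
      BMV = 175386868, CE = 53959676, CL = 173861, CT = 0, CHEM = 2194487,
      DIS = 27828170, GL = 3981568, ORG = 12385979, PG = 3624982
    ),
    ePMC = c(
      BMV = 441873718, CE = 150125656, CL = 872857, CT = 3, CHEM = 5253987,
      DIS = 67832153, GL = 16417448, ORG = 32341398, PG = 10261638
    ),
    `CORD-19` = c(
      BMV = 36199118, CE = 19585865, CL = 203926, CT = 1406, CHEM = 676882,
      DIS = 11350128, GL = 1845734, ORG = 13315914, PG = 2221487
    )
  )
}

collection_doc_counts <- function() {
  c(MEDLINE = 34664562, ePMC = 4722601, `CORD-19` = 389830)
}
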