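#' Reaction registry
#'
#' Canonical ordered list of the 67 unidirectional reaction and transport
#' labels of the model, using the published numbering with `f`/`b` suffixes
#' for the directions of reversible pairs (forward before backward). Labels
#' 54-65 are the ATP-equation counterparts of the base reactions, carrying
#' the adenylate closure factors `S1`/`S2` (see [amp_closure_factor()]).
#' This ordering is the public contract for stoichiometry columns, rate
#' vectors and all diagnostic reports.
#'
#' @return A data.frame with columns `label`, `name` (human readable),
#'   `compartment` (`n`, `g`, `e`, `c`, `v` for the venous balloon, or `x`
#'   for cross-compartment transport), and `pair` (label of the opposite
#'   direction of a reversible pair, `NA` otherwise).
#' @export
reaction_registry <- function() {
  def <- list(
    # label,            name,                                      compartment, pair
    c("1",  "neuronal sodium leak",                         "n", NA),
    c("2",  "astrocytic sodium leak",                       "g", NA),
    c("3",  "neuronal Na,K-ATPase",                         "n", NA),
    c("4",  "astrocytic Na,K-ATPase",                       "g", NA),
    c("5f", "glucose transport e->n",                       "x", "5b"),
    c("5b", "glucose transport n->e",                       "x", "5f"),
    c("6f", "glucose transport e->g",                       "x", "6b"),
    c("6b", "glucose transport g->e",                       "x", "6f"),
    c("7f", "glucose transport c->g",                       "x", "7b"),
    c("7b", "glucose transport g->c",                       "x", "7f"),
    c("8f", "glucose transport c->e",                       "x", "8b"),
    c("8b", "glucose transport e->c",                       "x", "8f"),
    c("9",  "neuronal hexokinase-phosphofructokinase",      "n", NA),
    c("10", "astrocytic hexokinase-phosphofructokinase",    "g", NA),
    c("11", "neuronal phosphoglycerate kinase",             "n", NA),
    c("12", "astrocytic phosphoglycerate kinase",           "g", NA),
    c("13", "neuronal pyruvate kinase",                     "n", NA),
    c("14", "astrocytic pyruvate kinase",                   "g", NA),
    c("15f", "neuronal lactate dehydrogenase (PYR->LAC)",   "n", "15b"),
    c("15b", "neuronal lactate dehydrogenase (LAC->PYR)",   "n", "15f"),
    c("16f", "astrocytic lactate dehydrogenase (PYR->LAC)", "g", "16b"),
    c("16b", "astrocytic lactate dehydrogenase (LAC->PYR)", "g", "16f"),
    c("17f", "lactate transport n->e",                      "x", "17b"),
    c("17b", "lactate transport e->n",                      "x", "17f"),
    c("18f", "lactate transport g->e",                      "x", "18b"),
    c("18b", "lactate transport e->g",                      "x", "18f"),
    c("19f", "lactate transport g->c",                      "x", "19b"),
    c("19b", "lactate transport c->g",                      "x", "19f"),
    c("20f", "lactate transport e->c",                      "x", "20b"),
    c("20b", "lactate transport c->e",                      "x", "20f"),
    c("21", "neuronal TCA cycle influx",                    "n", NA),
    c("22", "neuronal electron transport chain",            "n", NA),
    c("23", "astrocytic TCA cycle influx",                  "g", NA),
    c("24", "astrocytic electron transport chain",          "g", NA),
    c("25", "neuronal NADH shuttle",                        "n", NA),
    c("26", "astrocytic NADH shuttle",                      "g", NA),
    c("27f", "neuronal creatine kinase (PCr->ATP)",         "n", "27b"),
    c("27b", "neuronal creatine kinase (ATP->PCr)",         "n", "27f"),
    c("28f", "astrocytic creatine kinase (PCr->ATP)",       "g", "28b"),
    c("28b", "astrocytic creatine kinase (ATP->PCr)",       "g", "28f"),
    c("29", "oxygen exchange c->n",                         "x", NA),
    c("30", "oxygen exchange c->g",                         "x", NA),
    c("31", "capillary oxygen flow",                        "c", NA),
    c("32", "capillary glucose flow",                       "c", NA),
    c("33", "capillary lactate flow",                       "c", NA),
    c("34", "neuronal ATPase offset (S1)",                  "n", NA),
    c("35", "astrocytic ATPase offset (S2)",                "g", NA),
    c("36", "astrocytic pump offset (S2)",                  "g", NA),
    c("37", "venous balloon inflation",                     "v", NA),
    c("38", "deoxyhemoglobin production",                   "v", NA),
    c("39", "deoxyhemoglobin washout",                      "v", NA),
    c("40", "presynaptic stimulation, neuronal sodium",     "n", NA),
    c("41", "presynaptic stimulation, astrocytic sodium",   "g", NA),
    c("54", "neuronal HK-PFK ATP consumption (S1)",         "n", NA),
    c("55", "astrocytic HK-PFK ATP consumption (S2)",       "g", NA),
    c("56", "neuronal PGK ATP production (S1)",             "n", NA),
    c("57", "astrocytic PGK ATP production (S2)",           "g", NA),
    c("58", "neuronal PK ATP production (S1)",              "n", NA),
    c("59", "astrocytic PK ATP production (S2)",            "g", NA),
    c("60", "neuronal Na,K-ATPase ATP consumption (S1)",    "n", NA),
    c("61", "astrocytic Na,K-ATPase ATP consumption (S2)",  "g", NA),
    c("62", "neuronal ETC ATP production (S1)",             "n", NA),
    c("63", "astrocytic ETC ATP production (S2)",           "g", NA),
    c("64f", "neuronal creatine kinase ATP production (S1)", "n", "64b"),
    c("64b", "neuronal creatine kinase ATP consumption (S1)", "n", "64f"),
    c("65f", "astrocytic creatine kinase ATP production (S2)", "g", "65b"),
    c("65b", "astrocytic creatine kinase ATP consumption (S2)", "g", "65f")
  )
  reg <- data.frame(
    label = vapply(def, `[`, "", 1),
    name = vapply(def, `[`, "", 2),
    compartment = vapply(def, `[`, "", 3),
    pair = vapply(def, `[`, "", 4),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(reg$label))
  reg
}

#' @rdname reaction_registry
#' @export
reaction_labels <- function() reaction_registry()$label
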