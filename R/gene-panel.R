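#' Cellular-energetics candidate gene panel
#'
#' The 37 glycolysis / TCA-cycle / oxidative-phosphorylation genes that make up
#' the default candidate panel interrogated by the scoring pipeline.
#'
#' @return Character vector of 37 gene symbols.
#' @export
#' @examples
#' length(mbs_gene_panel())
mbs_gene_panel <- function() {
  c("ABAT", "ACLY", "ANPEP", "CAT", "CS", "DPYPD", "ERCC2", "FASN",
    "GAD1", "GGCT", "GOT2", "GPX1", "GSR", "GSS", "GSTM1", "HK1",
    "HK2", "IDH1", "IDH2", "IDH3A", "IDH3B", "IDH3G", "LDHA", "LDHB",
    "MDH2", "ME1", "OGDH", "PANK1", "PFKL", "PFKP", "PKM", "PKMYT1",
    "SCD", "SDHA", "SLC2A5", "SLC25A5", "TALDO1")
}

#' Published five-gene score components
#'
#' The five genes retained by the reference MBS together with their risk
#' directions: high expression of ANPEP and PKM, and low expression of ACLY,
#' PANK1 and SLC25A5, each count one molecular risk factor. Cutpoints are
#' cohort-specific and therefore not part of this table.
#'
#' @return A `data.frame` with columns `gene` and `direction`.
#' @export
#' @examples
#' mbs_reference_components()
mbs_reference_components <- function() {
  data.frame(
    gene = c("ACLY", "ANPEP", "PANK1", "PKM", "SLC25A5"),
    direction = c("low_is_risk", "high_is_risk", "low_is_risk",
                  "high_is_risk", "low_is_risk"),
    stringsAsFactors = FALSE
  )
}

#' IPSS-R category levels
#'
#' Ordered levels of the Revised International Prognostic Scoring System used
#' throughout the package.
#'
#' @return Character vector of the five ordered category labels.
#' @export
ipssr_levels <- function() {
  c("very-low", "low", "intermediate", "high", "very-high")
}

# risk-tier labels, ordered from best to worst prognosis
.tier_levels <- c("favourable", "intermediate", "adverse")

.directions <- c("high_is_risk", "low_is_risk")
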