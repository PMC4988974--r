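#' Example paired hub-connectivity table
#'
#' Loads the bundled worked example: normalized intramodular connectivities
#' (K_i) of 17 orthologs shared between a matched module pair of two
#' related medicinal-plant co-expression networks, one transcript per
#' species. Useful for demonstrating [flag_divergent()]: at the default
#' `delta_cut = 0.2` exactly three genes are flagged as divergent hubs.
#'
#' @return A `HubTable` data frame (see [shared_hub_table()]).
#' @export
#' @examples
#' tab <- example_hub_table()
#' attr(flag_divergent(tab), "flagged")$ortholog_id
example_hub_table <- function() {
  path <- system.file("extdata", "shared_hub_connectivity.tsv",
                      package = "conetdiff", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  tab$delta <- tab$K_i_a - tab$K_i_b
  tab$divergent <- FALSE
  class(tab) <- c("HubTable", "data.frame")
  tab
}
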