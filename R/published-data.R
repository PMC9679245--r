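#' Published Lake Michigan lake whitefish diversity table
#'
#' Per-population summary of the published Lake Michigan lake whitefish
#' Rapture baseline: sampling location, region, coordinates, numbers of
#' individuals collected and genotyped, and the genotyped populations'
#' mean expected/observed heterozygosity and inbreeding coefficient.
#' Two locations (ARCA, LUDI) were collected but dropped before genotyping;
#' their diversity columns are missing.
#'
#' @return data.frame with columns `population`, `code`, `region`,
#'   `latitude`, `longitude`, `n_collected`, `n_genotyped`, `he`, `ho`,
#'   `fis`.
#' @export
published_diversity <- function() {
  path <- system.file("extdata", "lake_michigan_diversity.tsv",
                      package = "radpopgen")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA",
                    quote = "")
}

#' Summarize a per-population diversity table
#'
#' Means of the diversity columns over genotyped populations
#' (`n_genotyped > 0`), the total number of genotyped individuals, and the
#' mean number collected per genotyped population.
#'
#' @param tab a data.frame like [published_diversity] (columns
#'   `n_collected`, `n_genotyped`, `he`, `ho`, `fis`).
#' @return list: `n_pops`, `mean_he`, `mean_ho`, `mean_fis`,
#'   `total_genotyped`, `mean_collected`.
#' @export
summarize_diversity_table <- function(tab) {
  g <- tab[tab$n_genotyped > 0, , drop = FALSE]
  list(n_pops = nrow(g),
       mean_he = mean(g$he), mean_ho = mean(g$ho), mean_fis = mean(g$fis),
       total_genotyped = sum(g$n_genotyped),
       mean_collected = mean(g$n_collected))
}

#' Region scope map of the published baseline populations
#'
#' Population code to lake region(s); northeastern populations belong to both
#' the northeastern and eastern scopes.
#'
#' @return named list: code -> character vector of regions.
#' @export
published_scope_map <- function() {
  tab <- published_diversity()
  tab <- tab[tab$n_genotyped > 0, ]
  out <- lapply(tab$region, function(r) {
    if (r == "Northeast and East") c("Northeast", "East") else r
  })
  names(out) <- tab$code
  out
}
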