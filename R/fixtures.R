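#' Bundled fixtures
#'
#' Small objects reconstructed from printed evidence about hepatocyte
#' mitogen signaling, used throughout the test suite and the examples:
#'
#' \describe{
#'   \item{`crosstalk_original`}{Reduced cross-talk model: ligand inputs
#'     HGF, EGF, IL6, Insulin, TNFa, TGFb; IL6 acts through JAK; every
#'     mitogen (and JAK) can activate the MAPK and PI3K modules, which also
#'     activate each other through time-scale-2 cross-talk arcs; DNA
#'     synthesis requires MAPK AND PI3K AND absence of TGFb.}
#'   \item{`crosstalk_v3`}{The refined wiring: the single Insulin and TNFa
#'     arcs into MAPK and PI3K are each replaced by one AND gate requiring
#'     both ligands, capturing their cooperative induction of DNA
#'     synthesis.}
#'   \item{`mapk_toy`}{MAPK cascade with a negative ERK feedback closed
#'     through a dummy at time scale 2; illustrates initial-response
#'     analysis.}
#'   \item{`fig4_observations`}{Eleven discretized DNA-synthesis calls for
#'     ligand combinations (six single ligands plus Insulin+TNFa,
#'     IL6+Insulin, IL6+TNFa, HGF+TGFb, HGF+Insulin+TGFb).}
#'   \item{`table2_contingency`}{Species lists comparing intervention-set
#'     membership (MIS of sizes 1-4 inducing DNA synthesis without
#'     stimulation) against liver-cancer mutation records, with the
#'     exclusion list of cell-cycle inhibitors whose basal activity the
#'     model does not represent.}
#' }
#'
#' @param name fixture name, see above.
#' @return the fixture object: a model, a list of observations, or (for
#'   `table2_contingency`) a list with `mis_species`, `mutated`,
#'   `universe`, `excluded` and the full `table` data frame.
#' @examples
#' m <- fixture("crosstalk_v3")
#' compute_lss(m, lih_scenario(inputs = c(HGF = 1, EGF = 0, IL6 = 0,
#'                                        Insulin = 0, TNFa = 0, TGFb = 0),
#'                             time_scale_mode = "initial"))
#' @export
fixture <- function(name) {
  path <- function(f) system.file("extdata", f, package = "lihnet",
                                  mustWork = TRUE)
  switch(name,
    crosstalk_original = read_model(path("crosstalk_original.lih")),
    crosstalk_v3 = read_model(path("crosstalk_v3.lih")),
    mapk_toy = read_model(path("mapk_toy.lih")),
    fig4_observations = read_observations(path("fig4_observations.tsv")),
    table2_contingency = {
      df <- utils::read.delim(path("table2_species.tsv"),
                              stringsAsFactors = FALSE)
      list(mis_species = df$species[df$in_mis == 1L],
           mutated = df$species[df$mutated == 1L],
           universe = df$species,
           excluded = df$species[df$excluded_basal == 1L],
           table = df)
    },
    stop("unknown fixture '", name, "'; see fixture_names()", call. = FALSE))
}

#' @rdname fixture
#' @export
fixture_names <- function() {
  c("crosstalk_original", "crosstalk_v3", "mapk_toy", "fig4_observations",
    "table2_contingency")
}
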