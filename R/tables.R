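#' Published benchmark distortion tables
#'
#' The bundled summary tables of a 30-dataset benchmark: maximum and average
#' pairwise distortions measured when 10 randomly chosen events from each of
#' 30 twelve-dimensional flow cytometry datasets were projected onto two
#' dimensions by the bit-vector synthesis ("sanjay"), classical MDS ("mds")
#' and Gaussian random projections ("rp"), together with the ratio columns as
#' printed (per-row ratios truncated to the printed precision; `NA` where no
#' ratio column was printed). The underlying datasets are not distributed, so
#' these summaries are the reference points for the ratio arithmetic.
#'
#' @return A tibble with columns `dataset_id`, `statistic` (`"max"` or
#'   `"avg"`), `mds`, `sanjay`, `rp`, `printed_ratio_mds_sanjay`,
#'   `printed_ratio_rp_sanjay`.
#' @export
printed_benchmarks <- function() {
  path <- system.file("extdata", "printed_benchmarks.csv", package = "sanjay",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    dataset_id = readr::col_integer(),
    statistic = readr::col_character(),
    .default = readr::col_double()), progress = FALSE)
}
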