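#' Load design constants from a YAML configuration
#'
#' Builds the paradigm design objects from a YAML file; any field omitted in
#' the file keeps its default.  The packaged default configuration
#' (`system.file("extdata", "default_design.yaml", package = "ftcp")`)
#' reproduces the study design constants.
#'
#' @param path YAML file path (default: the packaged configuration).
#' @return A list with `dimension`, `sweep`, `discrimination`, `training`,
#'   `preproc`, `spectrum`.
#' @export
load_design_config <- function(path = system.file("extdata", "default_design.yaml",
                                                  package = "ftcp")) {
  cfg <- yaml::read_yaml(path)
  take <- function(block, builder) {
    args <- cfg[[block]]
    if (is.null(args)) args <- list()
    # yaml reads numeric vectors as lists; flatten scalars
    args <- lapply(args, function(a) if (is.list(a)) unlist(a) else a)
    do.call(builder, args)
  }
  list(
    dimension = take("dimension", dimension_spec),
    sweep = take("sweep", sweep_design),
    discrimination = take("discrimination", discrimination_design),
    training = take("training", training_design),
    preproc = take("preproc", preproc_config),
    spectrum = take("spectrum", spectrum_config)
  )
}
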