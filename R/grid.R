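#' Processing-stage vocabularies
#'
#' The closed vocabularies of the four processing stages. The benchmark grid
#' is their Cartesian product: 2 normalisations x 7 imputations x
#' 4 transformations x 5 scalings = 280 permutations.
#'
#' @return Named list of character vectors in canonical order.
#' @export
default_stage_options <- function() {
  list(
    normalisation = c("SUM", "PQN"),
    mvi = c("none", "SV", "MN", "MD", "KNN", "BPCA", "RF"),
    transformation = c("none", "glog", "nlog", "IHS"),
    scaling = c("none", "auto", "pareto", "range", "vast")
  )
}

# internal: validate a stage vector against its closed vocabulary and
# return it in canonical order, duplicates removed
check_stage <- function(values, stage) {
  canon <- default_stage_options()[[stage]]
  if (length(values) == 0L) stop("empty vocabulary for stage ", stage,
                                 call. = FALSE)
  bad <- setdiff(values, canon)
  if (length(bad)) {
    stop("unknown ", stage, " method: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  canon[canon %in% values]
}

#' Enumerate the processing-permutation grid
#'
#' Builds every combination of normalisation, missing-value imputation,
#' transformation and scaling from the supplied vocabularies (defaults:
#' [default_stage_options()]). The output order is deterministic and
#' independent of the order in which options are supplied: each stage is
#' first sorted into its canonical vocabulary order, then the Cartesian
#' product is taken with scaling varying fastest.
#'
#' @param options named list with elements `normalisation`, `mvi`,
#'   `transformation`, `scaling`; missing elements fall back to the default
#'   vocabulary.
#' @return A tibble with one row per permutation and columns `perm_id`,
#'   `normalisation`, `mvi`, `transformation`, `scaling`.
#' @export
enumerate_grid <- function(options = default_stage_options()) {
  defaults <- default_stage_options()
  opts <- lapply(names(defaults), function(st) {
    check_stage(options[[st]] %||% defaults[[st]], st)
  })
  names(opts) <- names(defaults)
  grid <- tidyr::expand_grid(
    normalisation = opts$normalisation,
    mvi = opts$mvi,
    transformation = opts$transformation,
    scaling = opts$scaling
  )
  dplyr::mutate(grid,
    perm_id = paste(.data$normalisation, .data$mvi, .data$transformation,
                    .data$scaling, sep = "/"),
    .before = 1
  )
}
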