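#' Read or write a GMA model definition file
#'
#' Structured-text (YAML) model definitions with two sections mirroring
#' the model container: `variables` (list of `id`, `name`, `role`,
#' `baseline`, `enzyme`) and `fluxes` (list of `id`, `rate_constant`,
#' `kinetic_orders` map, `consumes`/`produces` maps, optional
#' `catalyst`).
#'
#' @param path File path.
#' @return `read_gma_model()` returns a [gma_model()];
#'   `write_gma_model()` returns the path invisibly.
#' @export
read_gma_model <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required for model definition files",
         call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  vars <- dplyr::bind_rows(lapply(y$variables, tibble::as_tibble))
  fluxes <- lapply(y$fluxes, function(f) {
    power_law_flux(
      f$id, f$rate_constant,
      kinetic_orders = unlist(f$kinetic_orders) %||% numeric(),
      consumes = unlist(f$consumes),
      produces = unlist(f$produces),
      catalyst = f$catalyst
    )
  })
  gma_model(vars, fluxes, name = y$name %||% "GMA model")
}

#' @rdname read_gma_model
#' @param model A [gma_model()].
#' @export
write_gma_model <- function(model, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required for model definition files",
         call. = FALSE)
  }
  y <- list(
    name = model$name,
    variables = lapply(seq_len(nrow(model$variables)), function(i) {
      as.list(model$variables[i, ])
    }),
    fluxes = lapply(model$fluxes, function(f) {
      out <- list(id = f$id, rate_constant = f$rate_constant,
                  kinetic_orders = as.list(f$kinetic_orders))
      if (!is.null(f$consumes)) out$consumes <- as.list(f$consumes)
      if (!is.null(f$produces)) out$produces <- as.list(f$produces)
      if (!is.null(f$catalyst)) out$catalyst <- f$catalyst
      out
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
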