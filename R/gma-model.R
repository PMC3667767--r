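#' General Mass Action (GMA) power-law models
#'
#' A GMA model represents a metabolic network as a set of ordinary
#' differential equations in which every process rate is a product of a
#' positive rate constant and the influencing variables raised to
#' real-valued exponents (kinetic orders), the formalism of Biochemical
#' Systems Theory. Dependent variables (metabolites) obey ODEs; independent
#' variables (enzyme activities, fixed metabolite pools) are set externally
#' and are held constant within a simulation interval.
#'
#' @param variables A data frame with one row per variable and columns
#'   `id` (unique symbol), `role` (`"dependent"` or `"independent"`),
#'   `baseline` (positive steady-state value in model units), and
#'   optionally `name` (human-readable label, defaults to `id`) and
#'   `enzyme` (logical; marks independent variables that are enzyme
#'   activities rather than fixed metabolite pools; defaults to `TRUE`
#'   for independent variables).
#' @param fluxes A list of flux definitions built with [power_law_flux()].
#' @param name Optional model label used in printing.
#'
#' @return An object of class `gma_model`: a list with elements
#'   `variables` (tibble) and `fluxes` (list), carrying precomputed
#'   stoichiometry and kinetic-order matrices for simulation.
#'
#' @examples
#' vars <- data.frame(
#'   id = c("A", "E"), role = c("dependent", "independent"), baseline = 1
#' )
#' fx <- list(
#'   power_law_flux("in", 1, c(E = 1), produces = c(A = 1), catalyst = "E"),
#'   power_law_flux("out", 1, c(A = 1), consumes = c(A = 1))
#' )
#' m <- gma_model(vars, fx, name = "one-species toy")
#' steady_state_residual(m)
#' @export
gma_model <- function(variables, fluxes, name = "GMA model") {
  variables <- tibble::as_tibble(variables)
  stopifnot(all(c("id", "role", "baseline") %in% names(variables)))
  if (!"name" %in% names(variables)) variables$name <- variables$id
  if (!"enzyme" %in% names(variables)) {
    variables$enzyme <- variables$role == "independent"
  }
  variables$enzyme <- variables$enzyme & variables$role == "independent"
  if (anyDuplicated(variables$id)) {
    stop("variable ids must be unique", call. = FALSE)
  }
  if (!all(variables$role %in% c("dependent", "independent"))) {
    stop("variable role must be 'dependent' or 'independent'", call. = FALSE)
  }
  if (any(!is.finite(variables$baseline)) || any(variables$baseline < 0)) {
    stop("baselines must be finite and non-negative", call. = FALSE)
  }
  if (length(fluxes) == 0) stop("a GMA model needs at least one flux", call. = FALSE)
  nm <- vapply(fluxes, function(f) f$id, character(1))
  if (anyDuplicated(nm)) stop("flux ids must be unique", call. = FALSE)
  names(fluxes) <- nm

  ids <- variables$id
  for (f in fluxes) {
    bad <- setdiff(
      unique(c(names(f$kinetic_orders), names(f$consumes), names(f$produces),
               if (!is.null(f$catalyst)) f$catalyst)),
      ids
    )
    if (length(bad)) {
      stop("flux '", f$id, "' references unknown variable(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    dep_ids <- variables$id[variables$role == "dependent"]
    nondep <- setdiff(c(names(f$consumes), names(f$produces)), dep_ids)
    if (length(nondep)) {
      stop("flux '", f$id, "' consumes/produces non-dependent variable(s): ",
           paste(nondep, collapse = ", "), call. = FALSE)
    }
  }
  # power laws with negative exponents are undefined at 0
  for (f in fluxes) {
    ko <- f$kinetic_orders
    at0 <- names(ko)[ko != 0]
    b <- variables$baseline[match(at0, variables$id)]
    if (any(b <= 0)) {
      stop("variable(s) ", paste(at0[b <= 0], collapse = ", "),
           " have non-positive baseline but nonzero kinetic order in flux '",
           f$id, "'", call. = FALSE)
    }
  }

  m <- structure(
    list(variables = variables, fluxes = fluxes, name = name),
    class = "gma_model"
  )
  attr(m, "matrices") <- build_gma_matrices(variables, fluxes)
  m
}

#' Define a power-law flux
#'
#' One elementary process of a GMA model: rate
#' \eqn{\gamma \prod_i X_i^{f_i}}, with a stoichiometric map from the
#' process to the dependent variables it consumes and produces.
#'
#' @param id Unique flux identifier.
#' @param rate_constant Positive rate constant \eqn{\gamma}.
#' @param kinetic_orders Named numeric vector of exponents \eqn{f_i},
#'   one per influencing variable.
#' @param consumes,produces Named numeric vectors of positive
#'   stoichiometric coefficients over dependent variables (coefficients
#'   default to 1 when a bare character vector is given). At least one of
#'   the two must be non-empty.
#' @param catalyst Optional id of the independent variable (enzyme)
#'   catalysing the process; informational, the kinetic dependence itself
#'   lives in `kinetic_orders`.
#' @return An object of class `gma_flux`.
#' @export
power_law_flux <- function(id, rate_constant, kinetic_orders = numeric(),
                           consumes = NULL, produces = NULL, catalyst = NULL) {
  if (!is.numeric(rate_constant) || length(rate_constant) != 1 ||
      !is.finite(rate_constant) || rate_constant <= 0) {
    stop("rate_constant must be a single positive number", call. = FALSE)
  }
  as_stoich <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) x <- stats::setNames(rep(1, length(x)), x)
    if (is.null(names(x)) || any(names(x) == "")) {
      stop("stoichiometry vectors must be named", call. = FALSE)
    }
    if (any(x <= 0)) stop("stoichiometric coefficients must be > 0", call. = FALSE)
    x
  }
  consumes <- as_stoich(consumes)
  produces <- as_stoich(produces)
  if (is.null(consumes) && is.null(produces)) {
    stop("flux '", id, "': at least one of consumes/produces must be non-empty",
         call. = FALSE)
  }
  if (length(kinetic_orders) &&
      (is.null(names(kinetic_orders)) || any(names(kinetic_orders) == ""))) {
    stop("kinetic_orders must be a named vector", call. = FALSE)
  }
  structure(
    list(id = id, rate_constant = rate_constant,
         kinetic_orders = kinetic_orders,
         consumes = consumes, produces = produces, catalyst = catalyst),
    class = "gma_flux"
  )
}

# Precompute the matrix form used by the integrators:
# flux = exp(log_gamma + KOd %*% log(dep) + KOi %*% log(indep)),
# d(dep)/dt = S %*% flux.
build_gma_matrices <- function(variables, fluxes) {
  dep <- variables$id[variables$role == "dependent"]
  ind <- variables$id[variables$role == "independent"]
  nf <- length(fluxes)
  KOd <- matrix(0, nf, length(dep), dimnames = list(names(fluxes), dep))
  KOi <- matrix(0, nf, length(ind), dimnames = list(names(fluxes), ind))
  Sp <- matrix(0, length(dep), nf, dimnames = list(dep, names(fluxes)))
  Sc <- Sp
  gamma <- numeric(nf)
  for (j in seq_along(fluxes)) {
    f <- fluxes[[j]]
    gamma[j] <- f$rate_constant
    ko <- f$kinetic_orders
    kd <- intersect(names(ko), dep)
    ki <- intersect(names(ko), ind)
    KOd[j, kd] <- ko[kd]
    KOi[j, ki] <- ko[ki]
    if (!is.null(f$produces)) Sp[names(f$produces), j] <- f$produces
    if (!is.null(f$consumes)) Sc[names(f$consumes), j] <- f$consumes
  }
  list(
    dep_ids = dep, indep_ids = ind, flux_ids = names(fluxes),
    gamma = gamma, log_gamma = log(gamma),
    KOd = KOd, KOi = KOi,
    Sprod = Sp, Scons = Sc, S = Sp - Sc,
    dep_baseline = stats::setNames(variables$baseline[match(dep, variables$id)], dep),
    indep_baseline = stats::setNames(variables$baseline[match(ind, variables$id)], ind),
    catalyst = vapply(fluxes, function(f) f$catalyst %||% NA_character_, character(1))
  )
}

gma_matrices <- function(model) attr(model, "matrices")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname gma_model
#' @param model,x A `gma_model`.
#' @export
n_dependent <- function(model) sum(model$variables$role == "dependent")

#' @rdname gma_model
#' @export
n_independent <- function(model) sum(model$variables$role == "independent")

#' @rdname gma_model
#' @export
dependent_ids <- function(model) gma_matrices(model)$dep_ids

#' @rdname gma_model
#' @export
independent_ids <- function(model) gma_matrices(model)$indep_ids

#' @rdname gma_model
#' @export
enzyme_ids <- function(model) {
  model$variables$id[model$variables$enzyme]
}

#' @export
print.gma_model <- function(x, ...) {
  cat("<gma_model> ", x$name, "\n", sep = "")
  cat("  ", n_dependent(x), " dependent and ", n_independent(x),
      " independent variables, ", length(x$fluxes), " power-law fluxes\n",
      sep = "")
  cat("  steady-state residual at baseline: ",
      format(steady_state_residual(x), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Evaluate a single power-law flux
#'
#' Computes \eqn{\gamma \prod_i x_i^{f_i}} for a named state vector. The
#' state must contain every variable the flux references; values must be
#' non-negative, and zero values are only admitted where the kinetic order
#' is non-negative.
#'
#' @param flux A [power_law_flux()] definition.
#' @param state Named numeric vector of variable values.
#' @return The flux value, a non-negative scalar.
#' @export
evaluate_flux <- function(flux, state) {
  ko <- flux$kinetic_orders
  miss <- setdiff(names(ko), names(state))
  if (length(miss)) {
    stop("state is missing variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- state[names(ko)]
  if (any(x < 0)) {
    stop("negative state value(s) for: ",
         paste(names(ko)[x < 0], collapse = ", "), call. = FALSE)
  }
  if (any(x == 0 & ko < 0)) {
    stop("zero state with negative kinetic order for: ",
         paste(names(ko)[x == 0 & ko < 0], collapse = ", "), call. = FALSE)
  }
  unname(flux$rate_constant * prod(x^ko))
}

#' Assemble the ODE right-hand side of a GMA model
#'
#' Returns a derivative function over the dependent variables. For each
#' dependent variable the derivative is the stoichiometry-weighted sum of
#' producing fluxes minus consuming fluxes.
#'
#' @param model A [gma_model()].
#' @return A function `f(dep_state, indep_state = NULL)` returning the
#'   named derivative vector; `indep_state` defaults to the model's
#'   independent-variable baselines and may be given partially (named).
#' @export
gma_derivatives <- function(model) {
  mm <- gma_matrices(model)
  function(dep_state, indep_state = NULL) {
    y <- as.numeric(dep_state[mm$dep_ids])
    if (anyNA(y)) stop("dep_state must cover all dependent variables", call. = FALSE)
    ind <- mm$indep_baseline
    if (!is.null(indep_state)) ind[names(indep_state)] <- indep_state
    v <- gma_flux_values(mm, y, ind)
    stats::setNames(as.numeric(mm$S %*% v), mm$dep_ids)
  }
}

# flux vector at a given dependent/independent state (values clipped at the
# power-law floor to keep fractional exponents defined near zero)
gma_flux_values <- function(mm, dep, indep) {
  lg <- mm$log_gamma +
    as.numeric(mm$KOd %*% log(pmax(dep, 1e-12))) +
    as.numeric(mm$KOi %*% log(pmax(indep, 1e-12)))
  exp(lg)
}

#' Residual of the baseline steady state
#'
#' The Euclidean norm of the dependent-variable derivatives evaluated at
#' the model's baseline state with all independent variables at baseline.
#' Zero iff the baseline is an exact steady state.
#'
#' @param model A [gma_model()].
#' @return Non-negative scalar.
#' @export
steady_state_residual <- function(model) {
  mm <- gma_matrices(model)
  d <- gma_derivatives(model)(mm$dep_baseline)
  sqrt(sum(d^2))
}
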