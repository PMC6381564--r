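#' Named scenario fixtures and JSON scenario loading
#'
#' Three named fixtures reproduce the toolkit's reference experiments at
#' `theta = 2.5`, `beta = 1`, `gamma = 1` (identity scaling, `a = 2.5`),
#' threshold `h2 = 1.6`, treatment `q = 0.5`, initial state
#' `(0.15, 0.895)`:
#' \describe{
#'   \item{`reference-homoclinic`}{`p = 0.496`, near the critical rate; the
#'     trajectory shadows the order-1 homoclinic cycle.}
#'   \item{`reference-periodic`}{`p = 0.3`; an orbitally stable order-1
#'     periodic solution.}
#'   \item{`reference-extinction`}{`p = 0.65`; above the critical rate, the
#'     infection goes extinct.}
#' }
#'
#' @param name a registry name (see above) or a path to a JSON file with
#'   the flat lower-case keys `name`, `a` (or `theta`, `beta`, `gamma`),
#'   `p`, `q`, `h`, `x0`, `y0` and optionally `expected_regime`. Unknown
#'   keys are rejected.
#' @return An object of class `si_scenario`: list `name`, `a`,
#'   `control` ([control_params()]), `x0`, `y0`, `expected_regime`
#'   (possibly NA), and `params` (an [model_params()] or NULL when the
#'   scenario is given directly in scaled form).
#' @examples
#' load_scenario("reference-periodic")
#' @export
load_scenario <- function(name) {
  if (name %in% list_scenarios()) {
    path <- system.file("extdata", "scenarios", paste0(name, ".json"),
                        package = "pulseSI", mustWork = TRUE)
  } else if (file.exists(name)) {
    path <- name
  } else {
    stop("unknown scenario `", name, "`; registry: ",
         paste(list_scenarios(), collapse = ", "), call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("name", "theta", "beta", "gamma", "a", "p", "q", "h",
               "x0", "y0", "expected_regime")
  bad <- setdiff(names(raw), allowed)
  if (length(bad) > 0)
    stop("config error: unknown key(s) in scenario: ",
         paste(bad, collapse = ", "), call. = FALSE)
  need <- c("name", "p", "q", "h", "x0", "y0")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("config error: missing key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  params <- NULL
  if (!is.null(raw$a)) {
    a <- raw$a
    if (!is.numeric(a) || a <= 0)
      stop("config error: `a` must be positive", call. = FALSE)
  } else if (all(c("theta", "beta", "gamma") %in% names(raw))) {
    params <- model_params(raw$theta, raw$beta, raw$gamma)
    a <- scale_model(params)$scaled$a
  } else {
    stop("config error: supply either `a` or all of `theta`, `beta`, `gamma`",
         call. = FALSE)
  }
  structure(list(name = raw$name, a = a, params = params,
                 control = control_params(raw$p, raw$q, raw$h, a = a),
                 x0 = raw$x0, y0 = raw$y0,
                 expected_regime = raw$expected_regime %||% NA_character_),
            class = "si_scenario")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @rdname load_scenario
#' @export
list_scenarios <- function() {
  c("reference-homoclinic", "reference-periodic", "reference-extinction")
}

#' @export
print.si_scenario <- function(x, ...) {
  cat(sprintf("<scenario %s> a = %g, p = %g, q = %g, h2 = %g, start (%g, %g)",
              x$name, x$a, x$control$p, x$control$q, x$control$h2,
              x$x0, x$y0))
  if (!is.na(x$expected_regime))
    cat(" [expected:", x$expected_regime, "]")
  cat("\n")
  invisible(x)
}

#' Write a scenario back to JSON
#'
#' Inverse of [load_scenario()] for file-based scenarios; round-trips
#' through the flat JSON schema unchanged.
#'
#' @param scenario an `si_scenario`.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_scenario <- function(scenario, path) {
  obj <- list(name = scenario$name)
  if (!is.null(scenario$params)) {
    obj$theta <- scenario$params$theta
    obj$beta <- scenario$params$beta
    obj$gamma <- scenario$params$gamma
  } else {
    obj$a <- scenario$a
  }
  obj$p <- scenario$control$p
  obj$q <- scenario$control$q
  obj$h <- scenario$control$h2
  obj$x0 <- scenario$x0
  obj$y0 <- scenario$y0
  if (!is.na(scenario$expected_regime))
    obj$expected_regime <- scenario$expected_regime
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
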