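#' Declare a three-equation mediation SEM
#'
#' Describes the recursive linear system for an intermediate-confounder
#' mediation analysis: an intermediate confounder equation
#' \eqn{L = \gamma_0 + \gamma_x X + \gamma_c' C + \epsilon_l}, a mediator
#' equation \eqn{M = \alpha_0 + \alpha_x X + \alpha_l L + \alpha_c' C +
#' \alpha_{xl} XL + \epsilon_m}, and an outcome equation
#' \eqn{Y = \beta_0 + \beta_x X + \beta_m M + \beta_l L + \beta_c' C +
#' \beta_{mm} M^2 + \beta_{ll} L^2 + \beta_{xl} XL + \beta_{xm} XM +
#' \epsilon_y}.  Which optional terms appear is controlled by `terms_m` and
#' `terms_y`; the minimal system (no interactions, no quadratics) is the
#' classical linear path model.
#'
#' An `lm` (mediator-by-confounder product) term in the outcome equation is
#' rejected: under either parametric identification assumption supported here
#' its coefficient would be constrained to zero, so allowing it would only
#' invite misspecification.
#'
#' @param x,m,y,l Column names of the binary exposure (coded 0/1), continuous
#'   mediator, continuous outcome, and continuous intermediate confounder.
#' @param c Character vector of baseline covariate column names (possibly
#'   empty).
#' @param terms_m Terms of the mediator equation, a subset of
#'   `c("x", "l", "c", "xl")`.  `"x"` and `"l"` are always included.
#' @param terms_y Terms of the outcome equation, a subset of
#'   `c("x", "m", "l", "c", "m2", "l2", "xl", "xm")`.  `"x"`, `"m"` and `"l"`
#'   are always included.
#' @return An object of class `sem_spec`.
#' @examples
#' sem_spec("x", "m", "y", "l", c = c("c1", "c2"))
#' sem_spec("x", "m", "y", "l",
#'          terms_m = c("x", "l", "xl"),
#'          terms_y = c("x", "m", "l", "m2", "l2", "xl"))
#' @export
sem_spec <- function(x, m, y, l, c = character(),
                     terms_m = c("x", "l", "c"),
                     terms_y = c("x", "m", "l", "c")) {
  stopifnot(is.character(x), length(x) == 1,
            is.character(m), length(m) == 1,
            is.character(y), length(y) == 1,
            is.character(l), length(l) == 1,
            is.character(c))
  roles <- c(x, m, y, l)
  if (anyDuplicated(roles) > 0) {
    stop("exposure, mediator, outcome and intermediate confounder columns ",
         "must be distinct", call. = FALSE)
  }
  if (any(c %in% roles)) {
    stop("baseline covariates must be disjoint from the x/m/y/l columns: ",
         paste(intersect(c, roles), collapse = ", "), call. = FALSE)
  }
  if ("lm" %in% terms_y) {
    stop("an L*M product term in the outcome equation is not supported: ",
         "its coefficient is constrained to zero under both available ",
         "identification assumptions", call. = FALSE)
  }
  allowed_m <- c("x", "l", "c", "xl")
  allowed_y <- c("x", "m", "l", "c", "m2", "l2", "xl", "xm")
  bad_m <- setdiff(terms_m, allowed_m)
  bad_y <- setdiff(terms_y, allowed_y)
  if (length(bad_m)) stop("unknown terms_m: ", paste(bad_m, collapse = ", "),
                          call. = FALSE)
  if (length(bad_y)) stop("unknown terms_y: ", paste(bad_y, collapse = ", "),
                          call. = FALSE)
  terms_m <- union(c("x", "l"), terms_m)
  terms_y <- union(c("x", "m", "l"), terms_y)
  if (length(c) == 0) {
    terms_m <- setdiff(terms_m, "c")
    terms_y <- setdiff(terms_y, "c")
  } else {
    terms_m <- union(terms_m, "c")
    terms_y <- union(terms_y, "c")
  }
  structure(
    list(x_name = x, m_name = m, y_name = y, l_name = l, c_names = c,
         terms_m = intersect(allowed_m, terms_m),
         terms_y = intersect(allowed_y, terms_y)),
    class = "sem_spec"
  )
}

#' @export
print.sem_spec <- function(x, ...) {
  cat("<sem_spec>\n")
  cat("  L ~", paste(x$terms_m[x$terms_m %in% c("x")], collapse = " + "),
      if (length(x$c_names)) "+ c" else "", "   [", x$l_name, "]\n")
  cat("  M equation terms:", paste(x$terms_m, collapse = ", "),
      "  [", x$m_name, "]\n")
  cat("  Y equation terms:", paste(x$terms_y, collapse = ", "),
      "  [", x$y_name, "]\n")
  cat("  exposure:", x$x_name,
      " covariates:", if (length(x$c_names)) paste(x$c_names, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' @rdname sem_spec
#' @param spec A `sem_spec` object.
#' @export
is_model4 <- function(spec) {
  stopifnot(inherits(spec, "sem_spec"))
  !any(c("xl") %in% spec$terms_m) &&
    !any(c("m2", "l2", "xl", "xm") %in% spec$terms_y)
}

# zero-constraints each identification assumption places on the fitted spec
assumption_violations <- function(spec, assumption) {
  switch(assumption,
    robins_greenland = intersect("xm", spec$terms_y),
    petersen = intersect(c("xl", "l2"), spec$terms_y),
    stop("unknown identification assumption: ", assumption, call. = FALSE)
  )
}

#' Validate an identification assumption against a model specification
#'
#' The natural direct and indirect effects are only parametrically identified
#' in the presence of an intermediate confounder if either the
#' Robins–Greenland assumption (no individual-level exposure–mediator
#' interaction on the outcome, i.e. `xm` absent) or the Petersen assumption
#' (controlled direct effect constant in the natural mediator value, i.e.
#' `xl` and `l2` absent) holds for the outcome equation.
#'
#' @param spec A [sem_spec()] object.
#' @param assumption `"robins_greenland"`, `"petersen"`, or `"auto"` (resolve
#'   from the spec: prefer whichever assumption the term set satisfies).
#' @return The resolved assumption string, invisibly usable downstream.
#' @export
resolve_assumption <- function(spec, assumption = c("auto", "robins_greenland",
                                                    "petersen")) {
  assumption <- match.arg(assumption)
  if (assumption == "auto") {
    ok_rg <- length(assumption_violations(spec, "robins_greenland")) == 0
    ok_pt <- length(assumption_violations(spec, "petersen")) == 0
    if (ok_rg) return("robins_greenland")
    if (ok_pt) return("petersen")
    stop("the fitted outcome equation contains xm together with xl/l2, so ",
         "neither the Robins-Greenland nor the Petersen assumption holds; ",
         "refit under a constrained spec (see check_identification())",
         call. = FALSE)
  }
  bad <- assumption_violations(spec, assumption)
  if (length(bad)) {
    stop("identification under '", assumption, "' requires the outcome ",
         "equation to exclude: ", paste(bad, collapse = ", "),
         "; refit with a constrained spec", call. = FALSE)
  }
  assumption
}

#' Serialize / deserialize a model specification
#'
#' `sem_spec_to_config()` converts a spec to a plain named list that
#' round-trips losslessly through YAML or JSON; `sem_spec_from_config()`
#' rebuilds the spec from such a list (or from a YAML/JSON file path).
#'
#' @param spec A [sem_spec()] object.
#' @param config A named list with entries `x`, `m`, `y`, `l`, `c`,
#'   `terms_m`, `terms_y`, or a path to a YAML/JSON file containing one
#'   (top-level or under a `spec:` key).
#' @return A list, or a `sem_spec`.
#' @export
sem_spec_to_config <- function(spec) {
  stopifnot(inherits(spec, "sem_spec"))
  list(x = spec$x_name, m = spec$m_name, y = spec$y_name, l = spec$l_name,
       c = as.list(spec$c_names),
       terms_m = as.list(spec$terms_m), terms_y = as.list(spec$terms_y))
}

#' @rdname sem_spec_to_config
#' @export
sem_spec_from_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.null(config$spec)) config <- config$spec
  need <- c("x", "m", "y", "l")
  if (!all(need %in% names(config))) {
    stop("spec config must name columns ",
         paste(setdiff(need, names(config)), collapse = ", "), call. = FALSE)
  }
  sem_spec(x = config$x, m = config$m, y = config$y, l = config$l,
           c = as.character(unlist(config$c)),
           terms_m = if (is.null(config$terms_m)) c("x", "l", "c")
                     else as.character(unlist(config$terms_m)),
           terms_y = if (is.null(config$terms_y)) c("x", "m", "l", "c")
                     else as.character(unlist(config$terms_y)))
}
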