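#' Marginal bioeconomic analysis
#'
#' Fits binomial dummy-variable regressions
#' \deqn{Y = a + \sum_i b_i x_i^+ + \sum_j c_j \, {}^I_n x_j^+ + d \prod_i x_i^+ + U}
#' to factorial scenario tables by ordinary least squares with backward
#' elimination of non-significant terms, and computes the quantities the
#' marginal analysis rests on: predictions at regressor means, marginal
#' effects \eqn{\partial Y / \partial x_i^+} at the means of companion
#' variables, and percent reductions.  The published regressions are
#' shipped verbatim as fixtures ([load_printed_equation()]) so that every
#' printed marginal effect can be reproduced exactly from the printed
#' coefficients.
#'
#' @name bioeconomics
NULL

new_dummy_model <- function(response, intercept, terms, means, tvalues = NULL,
                            r2 = NA_real_, f = NA_real_, df = NA_real_,
                            source = "fitted") {
  structure(list(response = response, intercept = intercept, terms = terms,
                 means = means, tvalues = tvalues, r2 = r2, f = f, df = df,
                 source = source),
            class = "dummy_model")
}

#' @export
print.dummy_model <- function(x, ...) {
  cat("Dummy-variable regression (", x$source, "): ", x$response, " =\n  ",
      format(x$intercept), sep = "")
  for (tm in x$terms)
    cat(if (tm$coef >= 0) " + " else " - ", format(abs(tm$coef)),
        "*", tm$name, sep = "")
  cat("\n  R2 =", x$r2, " F =", x$f, " df =", x$df, "\n")
  invisible(x)
}

term_vars <- function(model) {
  vars <- unique(unlist(lapply(model$terms, `[[`, "vars")))
  vars
}

find_term <- function(model, vars) {
  key <- paste(sort(vars), collapse = ":")
  for (tm in model$terms)
    if (identical(paste(sort(tm$vars), collapse = ":"), key)) return(tm)
  NULL
}

#' Load a published regression equation
#'
#' Returns the printed coefficients, regressor means (including the
#' interaction columns' own printed means), t-values, R2, F and df of one
#' of the six published equations, transcribed at full printed precision.
#'
#' @param id equation number, 1 to 6.
#' @return a `dummy_model` with `source = "printed"`.
#' @examples
#' eq2 <- load_printed_equation(2)
#' marginal_effect(eq2, "Al")   # 676.9 g
#' @export
load_printed_equation <- function(id) {
  fixtures <- printed_fixtures()
  key <- as.character(id)
  if (!key %in% names(fixtures$equations))
    stop("load_printed_equation: unknown equation id ", id,
         " (valid: 1-6)")
  eq <- fixtures$equations[[key]]
  terms <- lapply(eq$terms, function(tm)
    list(name = tm$name, vars = tm$vars, coef = tm$coef))
  means <- stats::setNames(vapply(eq$terms, `[[`, numeric(1), "mean"),
                           vapply(eq$terms, `[[`, character(1), "name"))
  tvals <- stats::setNames(vapply(eq$terms, `[[`, numeric(1), "t"),
                           vapply(eq$terms, `[[`, character(1), "name"))
  new_dummy_model(eq$response, eq$intercept, terms, means, tvals,
                  eq$r2, eq$f, eq$df, source = "printed")
}

printed_fixtures_cache <- new.env(parent = emptyenv())

printed_fixtures <- function() {
  if (is.null(printed_fixtures_cache$fx))
    printed_fixtures_cache$fx <- yaml::read_yaml(
      system.file("extdata", "printed_equations.yaml", package = "cassavabc"))
  printed_fixtures_cache$fx
}

#' Fit the dummy-variable regression with backward elimination
#'
#' Ordinary least squares on the 0/1 design; the least-significant term
#' (largest p-value above `alpha`) is removed one at a time until every
#' remaining term satisfies `p <= alpha`.  The intercept is always
#' retained and term hierarchy is not enforced (an interaction may
#' survive without its parents, as in the published models).
#'
#' @param table a scenario table (or any data.frame with 0/1 dummy
#'   columns and the response).
#' @param response column name of the response.
#' @param terms character vector of candidate terms in formula notation,
#'   e.g. `c("CM", "Al", "P", "Al:P")`.
#' @param alpha significance level for retention (default 0.05).
#' @return a `bc_fit`: the reduced `dummy_model` (with regressor means
#'   taken from the data, interaction columns included), the underlying
#'   `lm` fit, t-values, R2, F and residual df.
#' @export
fit_dummy_regression <- function(table, response, terms, alpha = 0.05) {
  if (!nrow(table)) stop("fit_dummy_regression: empty table")
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  for (v in vars) {
    if (!v %in% names(table))
      stop("fit_dummy_regression: missing column ", v)
    if (!all(table[[v]] %in% c(0, 1)))
      stop("fit_dummy_regression: column ", v, " is not a 0/1 dummy")
  }
  current <- terms
  repeat {
    fml <- stats::reformulate(current, response = response)
    fit <- stats::lm(fml, data = table)
    if (any(is.na(stats::coef(fit)))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      stop("fit_dummy_regression: rank-deficient design; collinear term(s): ",
           paste(bad, collapse = ", "))
    }
    sm <- summary(fit)
    pv <- sm$coefficients[, "Pr(>|t|)"]
    pv <- pv[setdiff(names(pv), "(Intercept)")]
    if (!length(pv) || max(pv) <= alpha) break
    drop <- names(pv)[which.max(pv)]
    current <- setdiff(current, drop)
    if (!length(current)) {
      fml <- stats::reformulate("1", response = response)
      fit <- stats::lm(fml, data = table)
      sm <- summary(fit)
      break
    }
  }
  cf <- stats::coef(fit)
  kept <- setdiff(names(cf), "(Intercept)")
  mm <- stats::model.matrix(fit)
  means <- colMeans(mm[, kept, drop = FALSE])
  tvals <- summary(fit)$coefficients[kept, "t value"]
  terms_out <- lapply(kept, function(nm)
    list(name = nm, vars = strsplit(nm, ":", fixed = TRUE)[[1]],
         coef = unname(cf[nm])))
  fstat <- summary(fit)$fstatistic
  model <- new_dummy_model(response, unname(cf["(Intercept)"]), terms_out,
                           means, tvals, summary(fit)$r.squared,
                           if (is.null(fstat)) NA_real_ else
                             unname(fstat["value"]),
                           fit$df.residual, source = "fitted")
  structure(list(model = model, lm = fit), class = "bc_fit")
}

#' Evaluate a model at supplied term values
#'
#' Interaction terms take their own supplied values (e.g. their printed
#' column means), not products of main-effect values.
#'
#' @param model a `dummy_model` (fitted or printed).
#' @param at named list/vector with a value for every term of the model;
#'   defaults to the model's regressor means.
#' @return the linear predictor value.
#' @examples
#' predict_at(load_printed_equation(6))   # about 195,080 cumulative CGM
#' @export
predict_at <- function(model, at = model$means) {
  at <- unlist(at)
  y <- model$intercept
  for (tm in model$terms) {
    if (!tm$name %in% names(at))
      stop("predict_at: no value supplied for term ", tm$name)
    y <- y + tm$coef * at[[tm$name]]
  }
  y
}

#' Marginal effect of a presence dummy
#'
#' The partial derivative of the response with respect to one dummy: the
#' variable's main coefficient plus, for every interaction containing it,
#' the interaction coefficient times the mean of the companion variables'
#' product.  Two conventions for that companion mean coexist in the
#' published arithmetic and both are available: `"product"` (default)
#' multiplies the printed main-effect means; `"term"` uses the printed
#' column mean of the companion product when that product is itself a
#' term of the model (falling back to the product otherwise).
#'
#' @param model a `dummy_model`.
#' @param var variable name.
#' @param means named means of the companion variables; defaults to the
#'   model's main-effect means.
#' @param companion `"product"` or `"term"` (see Details).
#' @return the marginal effect, in response units.
#' @examples
#' marginal_effect(load_printed_equation(2), "Al")            # 676.9
#' marginal_effect(load_printed_equation(5), "P", companion = "term")
#' @export
marginal_effect <- function(model, var, means = NULL,
                            companion = c("product", "term")) {
  companion <- match.arg(companion)
  if (!var %in% term_vars(model))
    stop("marginal_effect: variable ", var, " not in the model")
  if (is.null(means)) {
    mains <- vapply(model$terms, function(tm) length(tm$vars) == 1L,
                    logical(1))
    nm <- vapply(model$terms[mains], `[[`, character(1), "name")
    means <- as.list(model$means[nm])
  }
  eff <- 0
  for (tm in model$terms) {
    if (!var %in% tm$vars) next
    others <- setdiff(tm$vars, var)
    if (!length(others)) {
      eff <- eff + tm$coef
      next
    }
    fac <- NULL
    if (companion == "term") {
      hit <- find_term(model, others)
      if (!is.null(hit)) fac <- model$means[[hit$name]]
    }
    if (is.null(fac)) {
      miss <- setdiff(others, names(means))
      if (length(miss))
        stop("marginal_effect: no mean supplied for companion variable(s): ",
             paste(miss, collapse = ", "))
      fac <- prod(unlist(means[others]))
    }
    eff <- eff + tm$coef * fac
  }
  eff
}

#' Percent reduction in the predicted response
#'
#' Two modes: `"endpoint"` compares the model evaluated with the on-set
#' variables at 1 against the off-baseline (all at 0), interaction terms
#' taking their implied 0/1 values, and reports
#' `100 (pred_off - pred_on) / pred_off`; `"marginal_vs_intercept"`
#' reports `100 |sum of marginal effects| / intercept`.
#'
#' @param model a `dummy_model`.
#' @param on variables set to 1 (endpoint mode) or whose marginal effects
#'   are summed (marginal mode).
#' @param mode `"endpoint"` or `"marginal_vs_intercept"`.
#' @param companion passed to [marginal_effect()] in marginal mode.
#' @return percent reduction.
#' @examples
#' percent_reduction(load_printed_equation(3), c("Al", "P"))   # ~97%
#' @export
percent_reduction <- function(model, on,
                              mode = c("endpoint", "marginal_vs_intercept"),
                              companion = "product") {
  mode <- match.arg(mode)
  if (!length(on)) return(0)
  unknown <- setdiff(on, term_vars(model))
  if (length(unknown))
    stop("percent_reduction: variable(s) not in the model: ",
         paste(unknown, collapse = ", "))
  if (mode == "endpoint") {
    at_on <- lapply(model$terms, function(tm)
      as.numeric(all(tm$vars %in% on)))
    names(at_on) <- vapply(model$terms, `[[`, character(1), "name")
    at_off <- lapply(at_on, function(x) 0)
    off <- predict_at(model, at_off)
    if (off == 0) stop("percent_reduction: zero baseline prediction")
    100 * (off - predict_at(model, at_on)) / off
  } else {
    if (model$intercept == 0)
      stop("percent_reduction: zero baseline (intercept)")
    tot <- sum(vapply(on, function(v)
      marginal_effect(model, v, companion = companion), numeric(1)))
    100 * abs(tot) / model$intercept
  }
}

half_ulp <- function(x) {
  # half of the printed last-digit unit, inferred from the decimal text
  s <- sub("0+$", "", sub("\\.$", "", format(abs(x), scientific = FALSE)))
  dec <- if (grepl(".", s, fixed = TRUE))
    nchar(strsplit(s, ".", fixed = TRUE)[[1]][2]) else 0L
  0.5 * 10^(-dec)
}

#' Reproduce every published marginal effect from the fixtures
#'
#' Computes each printed marginal effect from its equation's printed
#' coefficients under both companion-mean conventions and compares
#' against the printed value.  The comparison tolerance propagates the
#' printing precision: half a last-digit unit of the printed value plus
#' the effect of rounding each companion mean to its printed digits.
#' Values that disagree beyond that tolerance under both conventions are
#' flagged (`ok = FALSE`), not silently passed.
#'
#' @return data.frame with columns `eq`, `var`, `printed`, `computed`
#'   (product convention), `computed_term` (term-mean convention), `tol`,
#'   and logicals `ok_product`, `ok_term`, `ok`.
#' @export
reproduce_marginals <- function() {
  fx <- printed_fixtures()$printed_derived$marginals
  rows <- lapply(fx, function(m) {
    model <- load_printed_equation(m$eq)
    comp <- marginal_effect(model, m$var, companion = "product")
    comp_t <- marginal_effect(model, m$var, companion = "term")
    tol <- half_ulp(m$value)
    for (tm in model$terms) {
      others <- setdiff(tm$vars, m$var)
      if (m$var %in% tm$vars && length(others))
        tol <- tol + abs(tm$coef) * 0.0005 * length(others)
    }
    okp <- abs(comp - m$value) <= tol
    okt <- abs(comp_t - m$value) <= tol
    data.frame(eq = m$eq, var = m$var, printed = m$value, computed = comp,
               computed_term = comp_t, tol = tol, ok_product = okp,
               ok_term = okt, ok = okp | okt)
  })
  do.call(rbind, rows)
}
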