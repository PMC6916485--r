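#' Linear equation on the raw measurement scale
#'
#' A `linear_equation` is the exported, human-readable form of a fitted
#' (or published) linear model: an intercept, continuous terms written as
#' `coefficient * (x - center) / scale`, and categorical factors written as
#' per-level offsets that sum to zero (effect coding). This is the raw-scale
#' form in which reduced PLS models of SCAR16 severity are reported, e.g.
#' `AOO_adj = 20.6 - 3.9[(%HSP70ub - 43.7)/15.5] + ...`.
#'
#' @param response name of the response variable.
#' @param intercept numeric intercept on the response scale.
#' @param continuous a data frame (or list coercible to one) with columns
#'   `name`, `coefficient`, `center`, `scale`; may be `NULL`.
#' @param categorical a named list; each element is a named numeric vector of
#'   per-level offsets for one factor; may be `NULL`.
#' @param offset_tol tolerance on the absolute sum of each factor's offsets.
#'   Published equations carry rounded coefficients, so the sum-to-zero
#'   constraint only holds approximately; the default admits one rounding unit.
#' @return an object of class `linear_equation`.
#' @export
linear_equation <- function(response, intercept, continuous = NULL,
                            categorical = NULL, offset_tol = 1) {
  stopifnot(is.character(response), length(response) == 1L,
            is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  if (!is.null(continuous)) {
    continuous <- tibble::as_tibble(continuous)
    needed <- c("name", "coefficient", "center", "scale")
    if (!all(needed %in% names(continuous))) {
      stop("continuous terms need columns: ", paste(needed, collapse = ", "))
    }
    if (any(!is.finite(continuous$scale)) || any(continuous$scale <= 0)) {
      stop("continuous term scales must be positive")
    }
    if (anyDuplicated(continuous$name)) stop("duplicated continuous term names")
  }
  if (!is.null(categorical)) {
    if (is.null(names(categorical)) || any(names(categorical) == "")) {
      stop("categorical terms must be a named list of per-level offset vectors")
    }
    for (f in names(categorical)) {
      off <- categorical[[f]]
      if (is.null(names(off)) || !is.numeric(off)) {
        stop("offsets for factor '", f, "' must be a named numeric vector")
      }
      if (abs(sum(off)) > offset_tol) {
        stop("offsets for factor '", f, "' do not sum to ~0 (sum = ",
             signif(sum(off), 4), ")")
      }
    }
  }
  structure(list(response = response, intercept = intercept,
                 continuous = continuous, categorical = categorical),
            class = "linear_equation")
}

#' Evaluate a linear equation at given inputs
#'
#' @param equation a [linear_equation].
#' @param inputs a data frame or named list supplying every continuous term
#'   (numeric) and every categorical factor (level labels) of the equation.
#'   Vectorized over rows.
#' @return numeric vector of predicted responses.
#' @export
evaluate_equation <- function(equation, inputs) {
  stopifnot(inherits(equation, "linear_equation"))
  inputs <- if (is.data.frame(inputs)) tibble::as_tibble(inputs) else
    tibble::as_tibble(as.list(inputs))
  n <- if (ncol(inputs)) nrow(inputs) else 1L
  out <- rep(equation$intercept, n)
  ct <- equation$continuous
  if (!is.null(ct)) {
    for (i in seq_len(nrow(ct))) {
      nm <- ct$name[i]
      if (is.null(inputs[[nm]])) stop("missing input for term '", nm, "'")
      out <- out + ct$coefficient[i] * (inputs[[nm]] - ct$center[i]) / ct$scale[i]
    }
  }
  for (f in names(equation$categorical)) {
    off <- equation$categorical[[f]]
    if (is.null(inputs[[f]])) stop("missing input for factor '", f, "'")
    lev <- as.character(inputs[[f]])
    bad <- setdiff(unique(lev), names(off))
    if (length(bad)) {
      stop("unknown level(s) for factor '", f, "': ", paste(bad, collapse = ", "))
    }
    out <- out + unname(off[lev])
  }
  out
}

#' @export
predict.linear_equation <- function(object, newdata, ...) {
  evaluate_equation(object, newdata)
}

#' @export
print.linear_equation <- function(x, ...) {
  cat("<linear_equation> ", x$response, " = ", format(x$intercept), sep = "")
  ct <- x$continuous
  if (!is.null(ct)) {
    for (i in seq_len(nrow(ct))) {
      cat(sprintf(" %+g[(%s - %g)/%g]", ct$coefficient[i], ct$name[i],
                  ct$center[i], ct$scale[i]))
    }
  }
  for (f in names(x$categorical)) {
    off <- x$categorical[[f]]
    cat(" + [", paste(sprintf("%+g(%s)", off, names(off)), collapse = ", "),
        "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Write / read a linear equation as structured plain text
#'
#' Equations serialize to a small YAML document so that exported models can be
#' versioned alongside the data and reloaded without refitting.
#'
#' @param equation a [linear_equation].
#' @param path file path.
#' @return `write_equation` returns `path` invisibly; `read_equation` returns
#'   the reconstructed [linear_equation].
#' @export
write_equation <- function(equation, path) {
  stopifnot(inherits(equation, "linear_equation"))
  obj <- list(
    response = equation$response,
    intercept = equation$intercept,
    continuous = if (is.null(equation$continuous)) list() else
      lapply(seq_len(nrow(equation$continuous)), function(i)
        as.list(equation$continuous[i, ])),
    categorical = lapply(equation$categorical, as.list)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_equation
#' @export
read_equation <- function(path) {
  obj <- yaml::read_yaml(path)
  cont <- if (length(obj$continuous)) {
    do.call(rbind, lapply(obj$continuous, as.data.frame))
  } else NULL
  cat_terms <- if (length(obj$categorical)) {
    lapply(obj$categorical, unlist)
  } else NULL
  linear_equation(obj$response, obj$intercept, cont, cat_terms)
}

#' Reference reduced models of the SCAR16 cohort
#'
#' The three published reduced PLS equations for the SCAR16 cohort, as
#' [linear_equation] objects:
#' \describe{
#'   \item{`sara_clinical`}{SARA_adj from cognitive dysfunction (CD), ancestry
#'     super-population and increased tendon reflex (TR); intercept 17.2.}
#'   \item{`aoo_biochem`}{AOO_adj (years) from the biochemistry of the mutant
#'     CHIP protein: %HSP70 ubiquitination, %ubiquitin-chain formation, K_D
#'     (uM) and B_max; intercept 20.6.}
#'   \item{`sara_biochem`}{SARA_adj2 from the same four biochemical inputs;
#'     intercept 18.8.}
#' }
#' Continuous inputs use the cohort centers/scales (e.g. %HSP70ub 43.7/15.5).
#' These serve as ground-truth effect structures for the synthetic generator
#' and as the models behind the Monte Carlo desirability profiler.
#'
#' @return named list of three [linear_equation] objects.
#' @export
scar16_reference_equations <- function() {
  biochem_terms <- function(coefs) {
    tibble::tibble(
      name = c("pct_hsp70_ub", "pct_chain", "kd", "bmax"),
      coefficient = coefs,
      center = c(43.7, 69.9, 7.8, 212.0),
      scale = c(15.5, 39.0, 6.0, 16.6)
    )
  }
  list(
    sara_clinical = linear_equation(
      "sara", 17.2,
      categorical = list(
        cd = c(Y = 5.6, N = -5.6),
        ancestry = c(EUR = 4.7, SAS = 0.9, MENA = -1.4, AMR = -1.7, EAS = -3.4),
        tr = c(Y = 2.7, N = -2.7)
      )
    ),
    aoo_biochem = linear_equation(
      "aoo", 20.6, continuous = biochem_terms(c(-3.9, 5.3, 4.9, -7.1))
    ),
    sara_biochem = linear_equation(
      "sara", 18.8, continuous = biochem_terms(c(1.9, 0.2, -2.3, 0.3))
    )
  )
}
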