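# Partial least squares engine: effect-coded design matrices, multi-response
# NIPALS, leave-one-out PRESS factor selection, VIP computation, one-pass
# VIP > cutoff reduction, and export to raw-scale linear equations.

#' Encode predictors into a standardized, effect-coded design matrix
#'
#' Continuous predictors are standardized to mean 0, sample SD 1. Categorical
#' predictors are effect-coded: by default one indicator column per level
#' (`coding = "full"`, so every level receives an exported offset, with the
#' sum-to-zero constraint applied when equations are exported), or `k - 1`
#' sum-contrast columns (+1 / -1, `coding = "sum"`). All coded columns are
#' standardized, and the coding map (levels, raw codes, centers, scales) is
#' retained so fitted models can be written back on the raw scale.
#'
#' @param data data frame of observations.
#' @param predictors column names to encode.
#' @param coding `"full"` or `"sum"`.
#' @return object of class `design_matrix`.
#' @export
encode_design <- function(data, predictors, coding = c("full", "sum")) {
  coding <- match.arg(coding)
  stopifnot(all(predictors %in% names(data)), nrow(data) >= 3)
  cols <- list(); mats <- list(); contrasts <- list()
  for (v in predictors) {
    x <- data[[v]]
    if (is.numeric(x)) {
      if (anyNA(x)) stop("missing values in predictor '", v, "'")
      s <- stats::sd(x)
      if (s == 0) stop("constant predictor '", v, "' (zero scale)")
      cols[[length(cols) + 1L]] <- tibble::tibble(
        col = v, var = v, type = "continuous", level = NA_character_,
        center = mean(x), scale = s)
      mats[[length(mats) + 1L]] <- matrix((x - mean(x)) / s, ncol = 1,
                                          dimnames = list(NULL, v))
    } else {
      x <- as.character(x)
      if (anyNA(x)) stop("missing values in predictor '", v, "'")
      levs <- sort(unique(x))
      if (length(levs) < 2) stop("constant predictor '", v, "' (single level)")
      if (coding == "full") {
        z <- outer(x, levs, `==`) * 1  # n x k indicators
        colnames(z) <- paste0(v, ":", levs)
        contr <- diag(length(levs))
      } else {
        k <- length(levs)
        contr <- rbind(diag(k - 1), rep(-1, k - 1))  # sum-to-zero contrasts
        z <- contr[match(x, levs), , drop = FALSE]
        colnames(z) <- paste0(v, ":", levs[-k])
      }
      dimnames(contr) <- list(levs, colnames(z))
      centers <- colMeans(z)
      scales <- apply(z, 2, stats::sd)
      if (any(scales == 0)) {
        stop("level(s) of '", v, "' constant in the data (zero scale)")
      }
      cols[[length(cols) + 1L]] <- tibble::tibble(
        col = colnames(z), var = v, type = "categorical",
        level = sub(paste0("^", v, ":"), "", colnames(z)),
        center = centers, scale = scales)
      mats[[length(mats) + 1L]] <- sweep(sweep(z, 2, centers), 2, scales, "/")
      contrasts[[v]] <- contr
    }
  }
  structure(list(x = do.call(cbind, mats), columns = do.call(rbind, cols),
                 contrasts = contrasts, coding = coding,
                 predictors = predictors),
            class = "design_matrix")
}

# re-encode raw data onto an existing design's columns (prediction path)
.encode_with <- function(design, data) {
  info <- design$columns
  n <- nrow(data)
  out <- matrix(NA_real_, n, nrow(info), dimnames = list(NULL, info$col))
  for (i in seq_len(nrow(info))) {
    if (info$type[i] == "continuous") {
      raw <- data[[info$var[i]]]
    } else {
      contr <- design$contrasts[[info$var[i]]]
      lev <- as.character(data[[info$var[i]]])
      bad <- setdiff(unique(lev), rownames(contr))
      if (length(bad)) stop("unknown level(s) for '", info$var[i], "': ",
                            paste(bad, collapse = ", "))
      raw <- contr[lev, info$col[i]]
    }
    out[, i] <- (raw - info$center[i]) / info$scale[i]
  }
  out
}

.as_y_matrix <- function(y) {
  if (is.data.frame(y)) y <- as.matrix(y)
  if (is.null(dim(y))) y <- matrix(y, ncol = 1, dimnames = list(NULL, "y"))
  if (is.null(colnames(y))) colnames(y) <- paste0("y", seq_len(ncol(y)))
  storage.mode(y) <- "double"
  y
}

# core NIPALS on pre-centered/scaled matrices; returns loadings and scores.
# allow_short: stop adding factors (rather than erroring) once the residual
# response variance is exhausted -- used by cross-validation.
.nipals <- function(X, Y, a, tol = 1e-10, max_iter = 500, allow_short = FALSE) {
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  W <- P <- matrix(0, p, a); C <- matrix(0, q, a)
  Tm <- U <- matrix(0, n, a); b <- numeric(a)
  a_used <- 0L
  E <- X; F <- Y
  for (k in seq_len(a)) {
    u <- F[, which.max(colSums(F^2))]
    if (sum(u^2) < 1e-12 * n) {
      if (allow_short) break
      stop("factor ", k, ": no residual response variance left")
    }
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(E, u)) / sum(u^2)
      wn <- sqrt(sum(w^2))
      if (wn < 1e-300) stop("factor ", k, ": degenerate weight vector")
      w <- w / wn
      t_ <- drop(E %*% w)
      cc <- drop(crossprod(F, t_))
      cc <- cc / sqrt(sum(cc^2))
      u <- drop(F %*% cc)
      if (sqrt(sum((t_ - t_old)^2)) < tol * max(sqrt(sum(t_^2)), 1)) break
      t_old <- t_
      if (it == max_iter) {
        stop("NIPALS inner loop failed to converge at factor ", k)
      }
    }
    tt <- sum(t_^2)
    if (tt < 1e-12) {
      if (allow_short) break
      stop("factor ", k, ": degenerate score vector (rank exceeded?)")
    }
    p_ <- drop(crossprod(E, t_)) / tt
    b_ <- sum(u * t_) / tt
    W[, k] <- w; P[, k] <- p_; C[, k] <- cc
    Tm[, k] <- t_; U[, k] <- u; b[k] <- b_
    a_used <- k
    E <- E - tcrossprod(t_, p_)
    F <- F - b_ * tcrossprod(t_, cc)
  }
  ix <- seq_len(a_used)
  W <- W[, ix, drop = FALSE]; P <- P[, ix, drop = FALSE]
  C <- C[, ix, drop = FALSE]; Tm <- Tm[, ix, drop = FALSE]
  U <- U[, ix, drop = FALSE]; b <- b[ix]
  dimnames(W) <- dimnames(P) <- list(colnames(X), NULL)
  rownames(C) <- colnames(Y)
  list(W = W, P = P, C = C, T = Tm, U = U, b = b,
       ss = b^2 * colSums(Tm^2), a_used = a_used)
}

#' Fit a partial least squares regression model
#'
#' Multi-response NIPALS with per-factor deflation of both blocks. Responses
#' are centered and scaled internally; coefficients, fitted values and
#' exported equations are reported back on the raw response scale. With as
#' many factors as the rank of a full-rank design, PLS predictions coincide
#' with ordinary least squares.
#'
#' @param design a [encode_design()] object.
#' @param y response vector, matrix or data frame (one column per response).
#' @param n_factors number of latent factors A (must not exceed the design
#'   rank).
#' @param tol,max_iter NIPALS inner-loop convergence tolerance and iteration
#'   bound; non-convergence is an error naming the factor.
#' @return object of class `pls_model`: weights `W`, loadings `P`, response
#'   weights `C`, scores `T`, inner coefficients `b`, explained response
#'   variance per factor `ss`, standardized coefficients `coefficients_std`,
#'   per-column `vip`, fitted values and per-response `r_squared`.
#' @export
fit_pls <- function(design, y, n_factors, tol = 1e-10, max_iter = 500) {
  stopifnot(inherits(design, "design_matrix"), n_factors >= 1)
  Y <- .as_y_matrix(y)
  X <- design$x
  stopifnot(nrow(Y) == nrow(X))
  if (n_factors > min(nrow(X) - 1L, ncol(X))) {
    stop("n_factors exceeds the design dimensions")
  }
  y_center <- colMeans(Y)
  y_scale <- apply(Y, 2, stats::sd)
  if (any(y_scale == 0)) stop("constant response column")
  Ys <- sweep(sweep(Y, 2, y_center), 2, y_scale, "/")
  fit <- .nipals(X, Ys, n_factors, tol, max_iter)
  # coefficients in coded/standardized space: B = W (P'W)^-1 diag(b) C'
  R <- fit$W %*% solve(crossprod(fit$P, fit$W))
  B <- R %*% (diag(fit$b, n_factors, n_factors) %*% t(fit$C))
  dimnames(B) <- list(colnames(X), colnames(Y))
  p <- ncol(X)
  vip <- sqrt(p * drop(fit$W^2 %*% fit$ss) / sum(fit$ss))
  names(vip) <- colnames(X)
  fitted_std <- X %*% B
  fitted <- sweep(sweep(fitted_std, 2, y_scale, "*"), 2, y_center, "+")
  r2 <- 1 - colSums((Y - fitted)^2) / colSums(sweep(Y, 2, y_center)^2)
  structure(list(design = design, y = Y, y_center = y_center,
                 y_scale = y_scale, n_factors = n_factors,
                 W = fit$W, P = fit$P, C = fit$C, T = fit$T, b = fit$b,
                 ss = fit$ss, coefficients_std = B, vip = vip,
                 fitted = fitted, r_squared = r2),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", ncol(x$y), " response(s), ", ncol(x$design$x),
      " coded predictor(s), A = ", x$n_factors, "\n", sep = "")
  cat("  R-squared:", paste(sprintf("%s %.3f", colnames(x$y), x$r_squared),
                            collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  Xn <- .encode_with(object$design, newdata)
  fitted_std <- Xn %*% object$coefficients_std
  sweep(sweep(fitted_std, 2, object$y_scale, "*"), 2, object$y_center, "+")
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a SS_a w_ja^2 / sum_a SS_a)` with normalized weight
#' vectors and `SS_a` the response variance explained by factor `a`; the mean
#' of `VIP^2` over coded predictors is 1 by construction.
#'
#' @param model a `pls_model`.
#' @return named numeric vector, one VIP per coded design column.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  model$vip
}

#' Select the number of PLS factors by leave-one-out cross-validation
#'
#' For each factor count A (0 = intercept-only), refits the model with each
#' observation left out -- re-centering and re-scaling both blocks within the
#' fold -- and accumulates PRESS, the sum of squared leave-one-out prediction
#' errors on the standardized response scale. The first local minimum of
#' PRESS is selected (the smallest A whose PRESS does not improve at A + 1).
#'
#' @param design a [encode_design()] object built on the full data.
#' @param y response vector/matrix/data frame.
#' @param a_max largest factor count to consider (capped by the design size).
#' @return object of class `cv_curve`: `a_selected` and the named `press`
#'   vector.
#' @export
loo_select <- function(design, y, a_max = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  Y <- .as_y_matrix(y)
  X <- design$x
  n <- nrow(X)
  if (is.null(a_max)) a_max <- min(n - 2L, ncol(X))
  a_max <- min(a_max, n - 2L, ncol(X))
  y_sd_full <- apply(Y, 2, stats::sd)
  press <- stats::setNames(numeric(a_max + 1), paste0("A", 0:a_max))
  for (i in seq_len(n)) {
    Xf <- X[-i, , drop = FALSE]; Yf <- Y[-i, , drop = FALSE]
    xc <- colMeans(Xf); xs <- apply(Xf, 2, stats::sd)
    keep <- xs > 0
    Xfs <- sweep(sweep(Xf[, keep, drop = FALSE], 2, xc[keep]), 2, xs[keep], "/")
    yc <- colMeans(Yf); ys <- apply(Yf, 2, stats::sd)
    ys[ys == 0] <- 1
    Yfs <- sweep(sweep(Yf, 2, yc), 2, ys, "/")
    xi <- (X[i, keep] - xc[keep]) / xs[keep]
    # A = 0: fold-mean prediction
    press[1] <- press[1] + sum(((Y[i, ] - yc) / y_sd_full)^2)
    a_fit <- min(a_max, sum(keep), n - 2L)
    if (a_fit < 1) next
    fit <- .nipals(Xfs, Yfs, a_fit, allow_short = TRUE)
    a_fit <- fit$a_used
    if (a_fit < 1) {  # fold with no usable factor: fold mean at every A
      for (a in seq_len(a_max)) press[a + 1] <- press[a + 1] +
          sum(((Y[i, ] - yc) / y_sd_full)^2)
      next
    }
    for (a in seq_len(a_fit)) {
      Ba <- fit$W[, seq_len(a), drop = FALSE] %*%
        solve(crossprod(fit$P[, seq_len(a), drop = FALSE],
                        fit$W[, seq_len(a), drop = FALSE])) %*%
        (diag(fit$b[seq_len(a)], a, a) %*% t(fit$C[, seq_len(a), drop = FALSE]))
      pred <- yc + ys * drop(xi %*% Ba)
      press[a + 1] <- press[a + 1] + sum(((Y[i, ] - pred) / y_sd_full)^2)
    }
    if (a_fit < a_max) {  # rank-deficient fold: carry the deepest fit forward
      for (a in (a_fit + 1):a_max) press[a + 1] <- press[a + 1] +
          sum(((Y[i, ] - pred) / y_sd_full)^2)
    }
  }
  # first local minimum; an improvement below a sliver of the intercept-only
  # PRESS counts as flat so numerically-zero curves do not inflate A
  a_sel <- a_max
  thresh <- 1e-06 * press[1]
  for (a in 0:(a_max - 1)) {
    if (press[a + 2] >= press[a + 1] - thresh) { a_sel <- a; break }
  }
  structure(list(a_selected = a_sel, press = press, a_max = a_max),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat("<cv_curve> selected A =", x$a_selected, "\n")
  print(round(x$press, 4))
  invisible(x)
}

#' VIP / coefficient report table
#'
#' One row per coded design column with its standardized coefficient per
#' response and its VIP -- the data behind a coefficient-vs-VIP scatter plot.
#'
#' @param model a `pls_model`.
#' @return tibble.
#' @export
vip_table <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  info <- model$design$columns
  out <- tibble::tibble(col = info$col, var = info$var, level = info$level,
                        vip = unname(model$vip[info$col]))
  for (r in colnames(model$coefficients_std)) {
    out[[paste0("coef_", r)]] <- unname(model$coefficients_std[info$col, r])
  }
  out
}

#' Export a fitted PLS response as a raw-scale linear equation
#'
#' Rewrites the standardized-space coefficients as
#' `intercept + sum coef * (x - center) / scale + categorical offsets`, with
#' each factor's per-level offsets centered to sum to zero exactly (any
#' non-zero mean offset is absorbed into the intercept, leaving predictions
#' unchanged).
#'
#' @param model a `pls_model`.
#' @param response response column name (default: the first).
#' @return a [linear_equation].
#' @export
export_equation <- function(model, response = NULL) {
  stopifnot(inherits(model, "pls_model"))
  if (is.null(response)) response <- colnames(model$y)[1]
  stopifnot(response %in% colnames(model$y))
  B <- model$coefficients_std[, response]
  sd_y <- model$y_scale[[response]]
  info <- model$design$columns
  intercept <- model$y_center[[response]]
  cont <- NULL
  cats <- list()
  for (v in unique(info$var)) {
    rows <- info[info$var == v, ]
    if (rows$type[1] == "continuous") {
      cont <- rbind(cont, tibble::tibble(
        name = v, coefficient = sd_y * unname(B[rows$col]),
        center = rows$center, scale = rows$scale))
    } else {
      contr <- model$design$contrasts[[v]]
      offs <- vapply(rownames(contr), function(l) {
        sum(sd_y * B[rows$col] * (contr[l, rows$col] - rows$center) / rows$scale)
      }, numeric(1))
      shift <- mean(offs)
      cats[[v]] <- offs - shift
      intercept <- intercept + shift
    }
  }
  linear_equation(response, intercept, continuous = cont,
                  categorical = if (length(cats)) cats else NULL,
                  offset_tol = 1e-8)
}

#' Fit, reduce by VIP, and refit once
#'
#' The full-variable model is fitted with the LOO-selected factor count; coded
#' columns with VIP at or below the cutoff are dropped (a categorical factor
#' is retained if any of its level columns clears the cutoff), and the model
#' is refitted once on the retained predictors with at most the initial
#' factor count. Each response is exported as a raw-scale [linear_equation].
#'
#' @param data data frame of observations.
#' @param predictors predictor column names.
#' @param responses response column names.
#' @param cutoff VIP retention threshold (default 0.8; retention is
#'   strict `VIP > cutoff`).
#' @param a_max cap on the LOO factor search.
#' @param coding passed to [encode_design()].
#' @return object of class `pls_reduction`: the initial and reduced models,
#'   the cross-validation curve, retained/dropped predictors, the VIP table
#'   of the initial fit, exported `equations` and reduced-model `r_squared`.
#' @export
reduce_and_refit <- function(data, predictors, responses, cutoff = 0.8,
                             a_max = NULL, coding = "full") {
  design <- encode_design(data, predictors, coding)
  Y <- .as_y_matrix(as.data.frame(data)[responses])
  cv <- loo_select(design, Y, a_max)
  a_init <- max(cv$a_selected, 1L)
  initial <- fit_pls(design, Y, a_init)
  vtab <- vip_table(initial)
  var_vip <- vapply(split(vtab$vip, vtab$var), max, numeric(1))
  retained <- predictors[predictors %in% names(var_vip)[var_vip > cutoff]]
  dropped <- setdiff(predictors, retained)
  if (!length(retained)) stop("no predictor exceeds the VIP cutoff")
  red_design <- encode_design(data, retained, coding)
  a_red <- min(a_init, ncol(red_design$x), nrow(red_design$x) - 2L)
  reduced <- fit_pls(red_design, Y, a_red)
  equations <- lapply(stats::setNames(responses, responses),
                      function(r) export_equation(reduced, r))
  structure(list(initial = initial, reduced = reduced, cv = cv,
                 retained = retained, dropped = dropped, vip = vtab,
                 equations = equations, r_squared = reduced$r_squared,
                 cutoff = cutoff),
            class = "pls_reduction")
}

#' @export
print.pls_reduction <- function(x, ...) {
  cat("<pls_reduction> retained {", paste(x$retained, collapse = ", "),
      "}, dropped {", paste(x$dropped, collapse = ", "), "}\n", sep = "")
  cat("  A =", x$reduced$n_factors, "; R-squared:",
      paste(sprintf("%s %.3f", names(x$r_squared), x$r_squared),
            collapse = ", "), "\n")
  invisible(x)
}
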